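test_that("the smallest slice of the space is the two benzopyrenes", {
  sp5 <- cached_space(5L, 5L)
  expect_length(sp5, 2L)
  pats <- sort(unname(vapply(sp5, classify_pattern, character(1L))))
  expect_equal(pats, c("a", "b"))
  # benzo[a]pyrene has 9 Kekule structures, benzo[e]pyrene 11
  expect_setequal(vapply(sp5, n_kekule, integer(1L)), c(9L, 11L))
})

test_that("enumeration is duplicate-free, valid and closed under symmetry", {
  sp <- cached_space(5L, 7L)
  codes <- vapply(sp, canonical_code, character(1L))
  expect_false(anyDuplicated(codes) > 0L)
  for (b in sp[seq(1L, length(sp), by = 7L)]) {
    expect_silent(pyrenoid:::validate_benzenoid(b))
    expect_length(find_pyrene_core(b), 1L)
    tb <- transform_benzenoid(b, rotate = 4L, reflect = TRUE)
    expect_identical(canonical_code(tb), canonical_code(b))
  }
  # counts grow monotonically with the ring budget
  n5 <- length(cached_space(5L, 5L))
  n6 <- length(cached_space(5L, 6L))
  n7 <- length(sp)
  expect_true(n5 < n6 && n6 < n7)
  expect_equal(c(n5, n6, n7), c(2L, 12L, 52L))
})

test_that("the sample strain set is the 13 core-annelation isomers", {
  ss <- cached_sample_set()
  expect_length(ss, 13L)
  pats <- table(vapply(ss, classify_pattern, character(1L)))
  expect_equal(pats[c("a", "b", "aa", "bb", "ab", "aab", "abb", "aabb")],
               table(c("a", "b", rep("aa", 2), "bb", rep("ab", 2),
                       rep("aab", 3), "abb", rep("aabb", 2)))[
                 c("a", "b", "aa", "bb", "ab", "aab", "abb", "aabb")])
  # names are deterministic and pinned to motif signatures
  m <- attribute_bays(ss[["abb_s1"]])
  expect_equal(c(m$n_coves, m$n_bays_a, m$n_bays_b), c(1L, 0L, 3L))
  m2 <- attribute_bays(ss[["aab_s1"]])
  expect_equal(c(m2$n_coves, m2$n_bays_a, m2$n_bays_b), c(2L, 0L, 0L))
  for (b in ss) expect_length(find_pyrene_core(b), 1L)
})

test_that("simulated tables are reproducible and follow the generating model", {
  ss <- cached_sample_set()
  t1 <- suppressWarnings(simulate_properties(ss, seed = 42L,
                                             include_smiles = FALSE))
  t2 <- suppressWarnings(simulate_properties(ss, seed = 42L,
                                             include_smiles = FALSE))
  expect_identical(t1, t2)
  t3 <- suppressWarnings(simulate_properties(ss, seed = 43L,
                                             include_smiles = FALSE))
  expect_false(identical(t1$HOMO_eV, t3$HOMO_eV))
  expect_identical(attr(t1, "seed"), 42L)
  # the gap identity holds exactly even under noise
  expect_equal(t1$gap_eV, t1$LUMO_eV - t1$HOMO_eV)

  # zero noise, gap driven by Delta-Clar only: pattern means follow the
  # Delta-Clar ordering with the a/aabb tie
  cf <- sim_default_coefficients()
  cf$gap <- NULL
  cf$HOMO_eV <- c(intercept = -5.7, delta_clar = -0.05, n_LL = 0, n_strain = 0)
  cf$LUMO_eV <- c(intercept = -1.1, delta_clar = 0.05, n_LL = 0, n_strain = 0)
  tab <- suppressWarnings(simulate_properties(ss, coefficients = cf,
                                              noise_sd = sim_default_noise() * 0,
                                              seed = 1L, include_smiles = FALSE))
  means <- aggregate(tab$gap_eV, by = list(pattern = tab$pattern), FUN = mean)
  means <- means[match(c("aa", "aab", "a", "aabb", "ab", "abb", "b", "bb"),
                       means$pattern), ]
  expect_true(all(diff(means$x) >= -1e-12))
  expect_equal(means$x[means$pattern == "a"],
               means$x[means$pattern == "aabb"])

  # zero-noise loop closure: the fitter recovers the generating plane
  # (relative_energy would re-zero per size group, so fit the generated E_rel)
  sm2 <- pattern_summary(tab[, c("id", "E_rel_kcal_mol")],
                         suppressWarnings(pbh_descriptors(ss)))
  fit <- fit_erel_model(sm2)
  expect_equal(c(fit$alpha, fit$beta, fit$gamma), c(0.8, -0.3, 13.4),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})
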