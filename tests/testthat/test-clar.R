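test_that("Kekule enumeration matches the backtracking oracle", {
  fixtures <- lapply(pbh_fixture(), pbh_fixture)
  small <- Filter(function(b) n_rings(b) <= 6L,
                  c(fixtures, cached_sample_set()[c("a_s1", "b_s1", "aa_s2",
                                                    "ab_s1")]))
  for (b in small) {
    cg <- carbon_graph(b)
    mine <- enumerate_kekule(cg)$matchings
    orc <- oracle_matchings(cg)
    expect_equal(length(mine), length(orc), info = b$name)
    expect_identical(sort_sets(mine), sort_sets(orc), info = b$name)
  }
  expect_equal(n_kekule(pbh_fixture("benzene")), 2L)
  expect_equal(n_kekule(pbh_fixture("naphthalene")), 3L)
  expect_equal(n_kekule(pbh_fixture("pyrene")), 6L)
})

test_that("non-Kekulean systems are reported, never skipped", {
  # phenalene-like triangle of three mutually fused rings: 13 atoms
  phenalene <- build_benzenoid(data.frame(q = c(0, 1, 0), r = c(0, 0, 1)),
                               name = "phenalene")
  expect_equal(carbon_graph(phenalene)$n_atoms, 13L)
  expect_length(enumerate_kekule(phenalene)$matchings, 0L)
  expect_error(clar_number(phenalene), "non-Kekulean")
  expect_error(clar_counts(phenalene), "non-Kekulean")
})

test_that("Clar numbers and structures match the independent oracle", {
  skip_if_not_installed("igraph")
  mols <- c(lapply(c("naphthalene", "phenanthrene", "triphenylene",
                     "pyrene"), pbh_fixture),
            cached_sample_set()[c("a_s1", "aa_s2", "aab_s3", "aabb_s2")])
  for (b in mols) {
    orc <- oracle_clar(b)
    expect_equal(clar_number(b), orc$clar_number, info = b$name)
    expect_identical(sort_sets(enumerate_clar(b)), sort_sets(orc$sets),
                     info = b$name)
  }
  expect_equal(clar_number(pbh_fixture("triphenylene")), 3L)
  expect_equal(clar_number(pbh_fixture("pyrene")), 2L)
  expect_length(enumerate_clar(pbh_fixture("naphthalene")), 2L)
  expect_length(enumerate_clar(pbh_fixture("phenanthrene")), 1L)
  expect_identical(enumerate_clar(pbh_fixture("phenanthrene"))[[1L]],
                   c(1L, 3L))  # sextets on both terminal rings
})

test_that("linear acenes have Clar number 1 with k migrating placements", {
  for (k in 2:6) {
    b <- acene(k)
    expect_equal(clar_number(b), 1L, info = k)
    expect_length(enumerate_clar(b), k)
    cc <- clar_counts(b)
    expect_equal(cc$n_fix, 0L, info = k)
    expect_equal(cc$n_mig, 1L, info = k)
  }
  expect_equal(clar_counts(pbh_fixture("benzene"))$delta_clar, 1L)
})

test_that("fixed plus migrating sextets always sum to the Clar number", {
  for (b in cached_sample_set()) {
    cc <- clar_counts(b)
    expect_equal(cc$n_tot, cc$n_fix + cc$n_mig, info = b$name)
    expect_equal(cc$delta_clar, cc$n_fix - cc$n_mig, info = b$name)
  }
})

test_that("exhaustive per-isomer Clar counts match oracle-frozen values", {
  # frozen from the dual-route computation (package kernel == igraph oracle)
  frozen <- list(
    a_s1 = c(2, 0, 2, -2), b_s1 = c(3, 3, 0, 3),
    aa_s1 = c(2, 0, 2, -2), aa_s2 = c(3, 3, 0, 3),
    bb_s1 = c(4, 4, 0, 4),
    ab_s1 = c(3, 2, 1, 1), ab_s2 = c(3, 1, 2, -1),
    aab_s1 = c(3, 0, 3, -3), aab_s2 = c(3, 1, 2, -1), aab_s3 = c(4, 4, 0, 4),
    abb_s1 = c(4, 3, 1, 2),
    aabb_s1 = c(4, 2, 2, 0), aabb_s2 = c(4, 1, 3, -2))
  ss <- cached_sample_set()
  for (nm in names(frozen)) {
    cc <- clar_counts(ss[[nm]])
    expect_equal(c(cc$n_tot, cc$n_fix, cc$n_mig, cc$delta_clar),
                 frozen[[nm]], info = nm)
  }
})

test_that("the additive pattern model gives the pattern-level assignment", {
  expected <- list(aa = c(2, 0, 2, -2), aab = c(3, 1, 2, -1),
                   a = c(2, 1, 1, 0), aabb = c(4, 2, 2, 0),
                   ab = c(3, 2, 1, 1), abb = c(4, 3, 1, 2),
                   b = c(3, 3, 0, 3), bb = c(4, 4, 0, 4))
  for (p in names(expected)) {
    cc <- pattern_delta_clar(p)
    expect_equal(c(cc$n_tot, cc$n_fix, cc$n_mig, cc$delta_clar),
                 expected[[p]], info = p)
    expect_equal(cc$n_tot, cc$n_fix + cc$n_mig, info = p)
  }
  # Delta-Clar across the canonical pattern ordering
  ord <- c("aa", "aab", "a", "aabb", "ab", "abb", "b", "bb")
  expect_equal(vapply(ord, function(p) pattern_delta_clar(p)$delta_clar,
                      integer(1L)),
               setNames(c(-2L, -1L, 0L, 0L, 1L, 2L, 3L, 4L), ord))
})

test_that("enumerate mode reports isomer disagreement and deviations", {
  # reset the memoization so the warnings are observable here
  cache <- pyrenoid:::.pattern_clar_cache
  rm(list = ls(cache), envir = cache)
  expect_warning(res <- pattern_delta_clar("aa", method = "enumerate"),
                 "differ between isomers")
  expect_equal(res$delta_clar, -2L)  # additive-consistent representative
  expect_identical(res$representative, "aa_s1")
  expect_s3_class(attr(res, "per_isomer"), "data.frame")

  # benzo[a]pyrene: no isomer matches the additive model
  w <- capture_warnings(res_a <- pattern_delta_clar("a", method = "enumerate"))
  expect_true(any(grepl("no isomer of pattern 'a'", w)))
  expect_equal(c(res_a$n_fix, res_a$n_mig, res_a$delta_clar), c(0L, 2L, -2L))

  # unique, consistent pattern: clean result
  res_bb <- pattern_delta_clar("bb", method = "enumerate")
  expect_equal(res_bb$delta_clar, 4L)
})
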