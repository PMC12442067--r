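test_that("relative energies re-zero within size groups and convert units", {
  rec <- data.frame(id = c("m1", "m2", "m3", "m4"),
                    n_rings = c(5L, 5L, 6L, 6L),
                    Etot = c(-100, -99.99, -120, -120),
                    Etot_unit = "hartree")
  out <- relative_energy(rec)
  expect_equal(out$E_rel_kcal_mol, c(0, 6.275095, 0, 0))
  expect_equal(round(out$E_rel_kcal_mol[2L], 1), 6.3)

  # translation invariance within a group
  rec2 <- rec
  rec2$Etot[rec2$n_rings == 5L] <- rec2$Etot[rec2$n_rings == 5L] + 3.21
  expect_equal(relative_energy(rec2)$E_rel_kcal_mol, out$E_rel_kcal_mol)

  rec3 <- rec
  rec3$Etot_unit <- c("hartree", "kcal/mol", "hartree", "hartree")
  expect_error(relative_energy(rec3), "mixed")

  # single-member group
  solo <- relative_energy(data.frame(id = "x", n_rings = 7L, Etot = 5,
                                     Etot_unit = "kcal/mol"))
  expect_equal(solo$E_rel_kcal_mol, 0)
})

test_that("gap consistency violations are flagged", {
  rec <- data.frame(HOMO_eV = c(-5.5, -5.5), LUMO_eV = c(-1.2, -1.2),
                    gap_eV = c(4.3, 4.1))
  expect_warning(bad <- check_gap_consistency(rec), "violate")
  expect_equal(bad, 2L)
  expect_silent(check_gap_consistency(rec[1L, , drop = FALSE]))
})

test_that("pattern summaries aggregate by pattern and ignore row order", {
  ss <- cached_sample_set()
  desc <- suppressWarnings(pbh_descriptors(ss))
  # identity pipe: a property equal to delta_clar reproduces the
  # pattern-level assignment in the means
  rec <- data.frame(id = desc$id, HOMO_eV = desc$delta_clar)
  sm <- pattern_summary(rec, desc, properties = "HOMO_eV")
  expect_equal(sm$HOMO_eV_mean, sm$delta_clar)

  perm <- sample(nrow(rec))
  sm2 <- pattern_summary(rec[perm, ], desc, properties = "HOMO_eV")
  expect_equal(sm2, sm)

  # unmatched ids are dropped with a warning naming them
  rec_extra <- rbind(rec, data.frame(id = "ghost", HOMO_eV = 0))
  expect_warning(pattern_summary(rec_extra, desc, properties = "HOMO_eV"),
                 "ghost")
})

test_that("Delta-Clar regressions recover exact lines and flag degeneracy", {
  ss <- cached_sample_set()
  desc <- suppressWarnings(pbh_descriptors(ss))
  rec <- data.frame(id = desc$id, gap_eV = 2 * desc$delta_clar + 1)
  fit <- regress_property_vs_deltaclar(rec, desc, "gap_eV")
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  rec_const <- data.frame(id = desc$id, gap_eV = 3.14)
  expect_message(fit0 <- regress_property_vs_deltaclar(rec_const, desc,
                                                       "gap_eV"),
                 "degenerate")
  expect_true(is.na(fit0$slope))
})

test_that("the pattern-level energy model is recovered exactly on a plane", {
  ss <- cached_sample_set()
  desc <- suppressWarnings(pbh_descriptors(ss))
  rec <- data.frame(id = desc$id,
                    E_rel_kcal_mol = 0.8 * desc$n_strain -
                      0.3 * desc$delta_clar + 13.4)
  sm <- pattern_summary(rec, desc)
  fit <- fit_erel_model(sm)
  expect_equal(fit$alpha, 0.8, tolerance = 1e-10)
  expect_equal(fit$beta, -0.3, tolerance = 1e-10)
  expect_equal(fit$gamma, 13.4, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  expect_error(fit_erel_model(sm[1:3, ]), "at least 4")

  # generic-plane recovery with different coefficients
  rec2 <- data.frame(id = desc$id,
                     E_rel_kcal_mol = 1.7 * desc$n_strain +
                       0.9 * desc$delta_clar - 2)
  fit2 <- fit_erel_model(pattern_summary(rec2, desc))
  expect_equal(c(fit2$alpha, fit2$beta, fit2$gamma), c(1.7, 0.9, -2),
               tolerance = 1e-10)
})

test_that("model predictions order the patterns as strain and Clar dictate", {
  model <- list(alpha = 0.8, beta = -0.3, gamma = 13.4)
  expect_equal(predict_erel(model, 0, 0), 13.4)
  expect_equal(predict_erel(list(alpha = 0, beta = 0, gamma = 7), 5, -3), 7)

  ss <- cached_sample_set()
  desc <- suppressWarnings(pbh_descriptors(ss))
  per_pattern <- aggregate(desc$n_strain, by = list(pattern = desc$pattern),
                           FUN = mean)
  per_pattern$delta_clar <- vapply(per_pattern$pattern, function(p)
    as.numeric(pattern_delta_clar(p)$delta_clar), numeric(1L))
  per_pattern$pred <- predict_erel(model, per_pattern$x,
                                   per_pattern$delta_clar)
  ord <- per_pattern$pattern[order(per_pattern$pred)]
  expect_equal(as.character(ord),
               c("b", "a", "bb", "aa", "ab", "abb", "aab", "aabb"))
})

test_that("property tables read back with schema validation", {
  ss <- cached_sample_set()
  tab <- suppressWarnings(simulate_properties(ss, seed = 7L,
                                              include_smiles = FALSE))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read_property_table(f)
  expect_equal(back$HOMO_eV, tab$HOMO_eV)
  broken <- tab[, setdiff(names(tab), "aIP_eV")]
  write.csv(broken, f, row.names = FALSE)
  expect_error(read_property_table(f), "aIP_eV")
})
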