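test_that("perimeter motifs are classified by fusion-run length", {
  phen <- detect_motifs(pbh_fixture("phenanthrene"))
  expect_equal(phen$n_bays, 1L)
  expect_equal(phen$n_coves, 0L)

  pyr <- detect_motifs(pbh_fixture("pyrene"))
  expect_equal(pyr$n_fissures, 4L)
  expect_equal(pyr$n_bays + pyr$n_coves + pyr$n_fjords, 0L)

  cove <- detect_motifs(pbh_fixture("benzo[c]phenanthrene"))
  expect_equal(cove$n_coves, 1L)

  # [5]helicene: the classic fjord
  hel5 <- build_benzenoid(data.frame(q = c(0, 1, 1, 0, -1),
                                     r = c(0, 0, 1, 2, 2)), name = "hel5")
  expect_equal(detect_motifs(hel5)$n_fjords, 1L)

  expect_equal(detect_motifs(pbh_fixture("benzene"))$runs, list())
})

test_that("motif detection is invariant under lattice symmetry", {
  mols <- c(lapply(c("phenanthrene", "benzo[c]phenanthrene"), pbh_fixture),
            cached_sample_set()[c("abb_s1", "aab_s2")])
  for (b in mols) {
    ref <- detect_motifs(b)
    base <- c(ref$n_fissures, ref$n_bays, ref$n_coves, ref$n_fjords)
    for (rot in 0:5) for (refl in c(FALSE, TRUE)) {
      m <- detect_motifs(transform_benzenoid(b, rotate = rot, reflect = refl))
      expect_equal(c(m$n_fissures, m$n_bays, m$n_coves, m$n_fjords), base,
                   info = sprintf("%s rot %d refl %s", b$name, rot, refl))
    }
  }
})

test_that("bays are attributed to a- vs b-annelation", {
  ss <- cached_sample_set()
  m_a <- attribute_bays(ss[["a_s1"]])
  expect_equal(c(m_a$n_bays_a, m_a$n_bays_b, m_a$n_coves), c(1L, 0L, 0L))
  m_b <- attribute_bays(ss[["b_s1"]])
  expect_equal(c(m_b$n_bays_a, m_b$n_bays_b, m_b$n_coves), c(0L, 2L, 0L))
  m_abb <- attribute_bays(ss[["abb_s1"]])
  expect_equal(c(m_abb$n_coves, m_abb$n_bays_a, m_abb$n_bays_b),
               c(1L, 0L, 3L))

  # a tail-internal phenanthrene-like kink counts as a generic a-bay
  tail_kink <- Filter(function(b) {
    m <- suppressWarnings(attribute_bays(b))
    rep <- annelation_report(b)
    any(vapply(m$runs, function(run) {
      length(run) == 2L &&
        all(vapply(m$walk$carbon_graph$membership[run],
                   function(rr) all(rep$labels[rr] %in% c("attached", "remote")),
                   logical(1L)))
    }, logical(1L)))
  }, cached_space(5L, 8L))
  expect_gt(length(tail_kink), 0L)
  b <- tail_kink[[1L]]
  m <- suppressWarnings(attribute_bays(b))
  expect_gte(m$n_bays_a, 1L)
})

test_that("weights derive from reference strain energies", {
  w <- derive_weights(strain_references())
  expect_equal(w, c(bay_a = 1, bay_b = 0.7, cove = 4.3))
  # the printed reference energies alone pin the b-bay weight at 1 d.p.
  expect_equal(unname(round((3.5 / 2.6) / 2, 1)), 0.7)
  expect_equal(unname(derive_weights(strain_references(),
                                     round_digits = NULL)["bay_b"]),
               (3.5 / 2.6) / 2)

  equal_refs <- data.frame(id = c("x", "y", "z"),
                           E_strain_kcal_mol = c(2, 2, 2),
                           n_bays_a = c(1L, 0L, 0L),
                           n_bays_b = c(0L, 1L, 0L),
                           n_coves = c(0L, 0L, 1L))
  expect_equal(derive_weights(equal_refs),
               c(bay_a = 1, bay_b = 1, cove = 1))
  expect_error(derive_weights(equal_refs[1:2, ]), "missing reference")
})

test_that("n_strain is the weighted motif sum, fjords excluded", {
  expect_equal(n_strain(list(n_bays_a = 0, n_bays_b = 3, n_coves = 1)), 6.4)
  expect_equal(n_strain(list(n_bays_a = 0, n_bays_b = 0, n_coves = 2)), 8.6)
  expect_equal(n_strain(list(n_bays_a = 0, n_bays_b = 0, n_coves = 0)), 0)
  expect_warning(
    v <- n_strain(list(n_bays_a = 1, n_bays_b = 0, n_coves = 0,
                       n_fjords = 2)),
    "fjord")
  expect_equal(v, 1)
})
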