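# Generation of the pyrene-based chemical space and simulated property
# tables.
#
# The space is grown breadth-first: starting from the pyrene core, a new
# hexagon is fused onto any free edge whose two carbon atoms belong to a
# single ring (this is exactly the cata-condensation constraint: fusing
# anywhere else would put an atom into three rings outside the core).
# Every new ring is fused by a single dualist edge, so the non-pyrene part
# is always a tree of rings; lattice self-overlap is allowed and read as
# helicenic winding, never as extra fusion.  Duplicates are removed at every
# size by canonical code, which identifies mirror images.

# fusible free edges of a structure given as a bare adjacency matrix:
# matrix with rows (ring, direction)
fusible_edges <- function(adj) {
  b <- benzenoid_from_adj(adj, validate = FALSE)
  cg <- carbon_graph(b)
  counts <- lengths(cg$membership)
  out <- NULL
  for (i in seq_len(nrow(adj))) for (d in 0:5) {
    if (adj[i, d + 1L] != 0L) next
    s <- edge_slots(d)
    a1 <- cg$ring_atoms[i, s[1L] + 1L]
    a2 <- cg$ring_atoms[i, s[2L] + 1L]
    if (counts[a1] == 1L && counts[a2] == 1L) out <- rbind(out, c(i, d))
  }
  out
}

attach_ring <- function(adj, i, d) {
  n <- nrow(adj)
  adj2 <- rbind(adj, rep(0L, 6L))
  adj2[i, d + 1L] <- n + 1L
  adj2[n + 1L, opp_dir(d) + 1L] <- i
  adj2
}

#' Enumerate the pyrene-based chemical space
#'
#' Exhaustively generates all constitutional isomers consisting of the
#' pyrene core plus purely cata-condensed attached benzene rings, for a
#' given total ring-count range.  Helicenic winding is allowed; mirror
#' images (and helical senses) are identified, matching constitutional
#' isomer counting.
#'
#' @param min_rings,max_rings total ring counts to keep (the pyrene core
#'   contributes 4 rings; `min_rings` must be at least 5).
#' @param core_only restrict attachments to the four core rings (no growth
#'   on attached rings)?
#' @param max_per_core_ring maximum number of rings annelated directly onto
#'   any single core ring (`Inf` = unlimited).  `core_only = TRUE` together
#'   with `max_per_core_ring = 1` yields the 13-molecule strain sample set.
#' @return a named list of `benzenoid` objects, sorted by ring count and
#'   canonical code; names are `pbh<n_rings>_<index>`.
#' @examples
#' length(enumerate_space(5, 5))  # 2: benzo[a]pyrene and benzo[e]pyrene
#' @export
enumerate_space <- function(min_rings = 5L, max_rings = 10L,
                            core_only = FALSE, max_per_core_ring = Inf) {
  min_rings <- as.integer(min_rings); max_rings <- as.integer(max_rings)
  if (min_rings < 5L || min_rings > max_rings || max_rings > 12L)
    stop("need 5 <= min_rings <= max_rings <= 12")
  core <- 1:4
  level <- list(pyrene_core_adj())  # size 4
  kept <- list()
  for (size in 5L:max_rings) {
    seen <- new.env(parent = emptyenv())
    nxt <- list()
    for (adj in level) {
      fe <- fusible_edges(adj)
      if (is.null(fe)) next
      for (k in seq_len(nrow(fe))) {
        i <- fe[k, 1L]; d <- fe[k, 2L]
        if (core_only && !(i %in% core)) next
        if (is.finite(max_per_core_ring) && i %in% core &&
            sum(adj[i, ] > 4L) >= max_per_core_ring) next
        cand <- attach_ring(adj, i, d)
        code <- cpp_canonical_code(cand)
        if (is.null(seen[[code]])) {
          seen[[code]] <- TRUE
          nxt <- c(nxt, list(cand))
        }
      }
    }
    level <- nxt
    if (size >= min_rings) kept[[as.character(size)]] <- level
  }
  out <- list()
  for (size in names(kept)) {
    mats <- kept[[size]]
    if (length(mats) == 0L) next
    codes <- vapply(mats, cpp_canonical_code, character(1L))
    mats <- mats[order(codes)]
    for (k in seq_along(mats)) {
      nm <- sprintf("pbh%s_%d", size, k)
      bb <- benzenoid_from_adj(mats[[k]], name = nm, validate = FALSE)
      out[[nm]] <- bb
    }
  }
  out
}

#' The 13-molecule strain sample set
#'
#' All structures obtainable by fusing at most one benzene ring onto each of
#' the four pyrene core rings (a-ring exterior edges and b-ring K-region
#' edges), excluding bare pyrene: 13 constitutional isomers.  Names follow
#' the pattern plus a sample index, `<pattern>_s<N>`; within a pattern,
#' isomers are numbered by decreasing cove count, then decreasing strain
#' score, then canonical code, which pins the motif signatures
#' (e.g. `aab_s1` is the aab isomer with two coves).
#'
#' @return a named list of 13 `benzenoid` objects, ordered by pattern
#'   (a, b, aa, bb, ab, aab, abb, aabb) and sample index.
#' @examples
#' names(sample_strain_set())
#' @export
sample_strain_set <- function() {
  mols <- enumerate_space(5L, 8L, core_only = TRUE, max_per_core_ring = 1L)
  info <- lapply(mols, function(b) {
    rep <- annelation_report(b)
    m <- attribute_bays(b, report = rep)
    list(pattern = rep$pattern, n_coves = m$n_coves,
         ns = n_strain(m), code = canonical_code(b))
  })
  pat <- vapply(info, `[[`, character(1L), "pattern")
  ord <- order(match(pat, PATTERN_LEVELS),
               -vapply(info, `[[`, numeric(1L), "n_coves"),
               -vapply(info, `[[`, numeric(1L), "ns"),
               vapply(info, `[[`, character(1L), "code"))
  mols <- mols[ord]
  pat <- pat[ord]
  idx <- stats::ave(seq_along(pat), pat, FUN = seq_along)
  nms <- sprintf("%s_s%d", pat, idx)
  for (k in seq_along(mols)) mols[[k]]$name <- nms[k]
  names(mols) <- nms
  mols
}

#' Default simulation coefficients
#'
#' Linear coefficients of each simulated property on the three structural
#' descriptors (pattern-level Delta-Clar, longest linear stretch `n_LL`,
#' strain score `n_strain`), plus an intercept.  Signs follow the observed
#' trends: orbital-gap-like properties rise with Delta-Clar and fall with
#' linear extension, the HOMO does the opposite, and the relative energy
#' follows `0.8 * n_strain - 0.3 * Delta-Clar + 13.4` (kcal/mol).
#'
#' @return a named list of coefficient vectors with entries `intercept`,
#'   `delta_clar`, `n_LL`, `n_strain`.
#' @export
sim_default_coefficients <- function() {
  list(
    HOMO_eV = c(intercept = -5.70, delta_clar = -0.050, n_LL = 0.060, n_strain = 0),
    LUMO_eV = c(intercept = -1.10, delta_clar = 0.050, n_LL = -0.060, n_strain = 0),
    aIP_eV = c(intercept = 6.35, delta_clar = 0.040, n_LL = -0.050, n_strain = 0),
    aEA_eV = c(intercept = 0.55, delta_clar = 0.040, n_LL = -0.050, n_strain = 0),
    E_rel_kcal_mol = c(intercept = 13.4, delta_clar = -0.3, n_LL = 0, n_strain = 0.8)
  )
}

#' Default simulation noise levels
#'
#' Gaussian noise standard deviations per simulated property: 0.05 eV for
#' the orbital-derived quantities (a typical within-pattern spread) and
#' 1 kcal/mol for the relative energy.
#'
#' @return a named numeric vector.
#' @export
sim_default_noise <- function() {
  c(HOMO_eV = 0.05, LUMO_eV = 0.05, aIP_eV = 0.05, aEA_eV = 0.05,
    E_rel_kcal_mol = 1)
}

#' Simulate a molecular property table
#'
#' Builds a property table with the statistical structure the trend analysis
#' assumes: every property is a linear function of the molecule's
#' pattern-level Delta-Clar, its longest linear stretch and its strain
#' score, plus Gaussian noise.  The HOMO-LUMO gap is always `LUMO - HOMO`
#' of the (noisy) orbital energies.  The total energy is the simulated
#' relative energy on top of a deterministic per-size baseline, so relative
#' energies recomputed with [relative_energy()] re-zero to the group
#' minimum.
#'
#' @param structures a list of `benzenoid`s (e.g. from [enumerate_space()]).
#' @param coefficients per-property coefficient vectors, see
#'   [sim_default_coefficients()].
#' @param noise_sd per-property noise standard deviations, see
#'   [sim_default_noise()]; use 0 for exact tables.
#' @param seed integer seed; the same seed reproduces the same table.
#' @param include_smiles add a SMILES column?
#' @return a data frame with columns `id`, `smiles`, `pattern`, `n_rings`,
#'   `n_LL`, `delta_clar`, `n_strain`, `HOMO_eV`, `LUMO_eV`, `gap_eV`,
#'   `aIP_eV`, `aEA_eV`, `Etot`, `Etot_unit`, `E_rel_kcal_mol`; the seed is
#'   recorded in the `"seed"` attribute.
#' @export
simulate_properties <- function(structures,
                                coefficients = sim_default_coefficients(),
                                noise_sd = sim_default_noise(),
                                seed = 1L, include_smiles = TRUE) {
  desc <- pbh_descriptors(structures)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  nmol <- nrow(desc)
  evaluate <- function(cf) {
    cf <- c(cf, intercept = 0, delta_clar = 0, n_LL = 0, n_strain = 0)[
      c("intercept", "delta_clar", "n_LL", "n_strain")]
    cf[["intercept"]] + cf[["delta_clar"]] * desc$delta_clar +
      cf[["n_LL"]] * desc$n_LL + cf[["n_strain"]] * desc$n_strain
  }
  vals <- list()
  for (p in names(coefficients)) {
    sdp <- if (p %in% names(noise_sd)) noise_sd[[p]] else 0
    vals[[p]] <- evaluate(coefficients[[p]]) +
      (if (sdp > 0) rnorm(nmol, 0, sdp) else 0)
  }
  erel <- vals$E_rel_kcal_mol
  if (is.null(erel)) erel <- rep(0, nmol)
  out <- data.frame(
    id = desc$id,
    smiles = if (include_smiles)
      vapply(structures, benzenoid_to_smiles, character(1L)) else NA_character_,
    pattern = desc$pattern, n_rings = desc$n_rings, n_LL = desc$n_LL,
    delta_clar = desc$delta_clar, n_strain = desc$n_strain,
    HOMO_eV = vals$HOMO_eV, LUMO_eV = vals$LUMO_eV,
    gap_eV = vals$LUMO_eV - vals$HOMO_eV,
    aIP_eV = vals$aIP_eV, aEA_eV = vals$aEA_eV,
    Etot = erel - 40000 - 2500 * desc$n_rings,
    Etot_unit = "kcal/mol",
    E_rel_kcal_mol = erel,
    row.names = NULL)
  attr(out, "seed") <- seed
  out
}
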