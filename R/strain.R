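# Perimeter strain motifs and the weighted strain score n_strain.
#
# Concave perimeter regions force H...H steric clashes and out-of-plane
# distortion.  Operationally a motif is a maximal run of consecutive
# degree-3 (fusion) perimeter atoms flanked by hydrogens: run length 1 =
# fissure, 2 = bay, 3 = cove, 4 = fjord.  Bays are attributed to a- or
# b-annelation of the pyrene core; the strain score is
#   n_strain = n_bays_a + 0.7 * n_bays_b + 4.3 * n_coves,
# with the weights derived from frozen-core reference strain energies.

#' Detect perimeter motifs
#'
#' Scans the cyclic H/F perimeter code for maximal fusion-vertex runs and
#' classifies them by length.  Runs longer than 4 (possible only in strongly
#' helicenic systems) are reported in `runs` but counted in none of the four
#' classes, with a warning.
#'
#' @param x a `benzenoid` or a `perimeter_walk`.
#' @return an object of class `motif_counts` with fields `n_fissures`,
#'   `n_bays`, `n_coves`, `n_fjords` and `runs`, a list of integer vectors
#'   of perimeter atom ids (one per run, in walk order).
#' @examples
#' detect_motifs(pbh_fixture("phenanthrene"))$n_bays          # 1
#' detect_motifs(pbh_fixture("benzo[c]phenanthrene"))$n_coves # 1
#' @export
detect_motifs <- function(x) {
  pw <- if (inherits(x, "perimeter_walk")) x else perimeter_walk(x)
  code <- pw$code
  n <- length(code)
  if (all(code == "H"))
    return(structure(list(n_fissures = 0L, n_bays = 0L, n_coves = 0L,
                          n_fjords = 0L, runs = list(), walk = pw),
                     class = "motif_counts"))
  # rotate so the walk starts on an H, making F-runs non-wrapping
  s <- which(code == "H")[1L]
  idx <- ((s - 1L + seq_len(n) - 1L) %% n) + 1L
  rcode <- code[idx]
  ratoms <- pw$atoms[idx]
  rl <- rle(rcode)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- list()
  for (k in which(rl$values == "F"))
    runs <- c(runs, list(ratoms[starts[k]:ends[k]]))
  lens <- lengths(runs)
  if (any(lens > 4L))
    warning("perimeter run(s) of length > 4 detected (helicenic overlap); ",
            "not counted as any motif")
  structure(list(n_fissures = sum(lens == 1L),
                 n_bays = sum(lens == 2L),
                 n_coves = sum(lens == 3L),
                 n_fjords = sum(lens == 4L),
                 runs = runs, walk = pw),
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat(sprintf("<motif_counts> fissures %d, bays %d", x$n_fissures, x$n_bays))
  if (!is.null(x$n_bays_a))
    cat(sprintf(" (a: %d, b: %d)", x$n_bays_a, x$n_bays_b))
  cat(sprintf(", coves %d, fjords %d\n", x$n_coves, x$n_fjords))
  invisible(x)
}

#' Attribute bays to a- vs b-annelation
#'
#' Each bay is assigned to the core-ring letter of the attached (non-core)
#' ring its fusion atoms touch: bays at a ring annelated onto an *a* ring
#' count towards `n_bays_a`, bays at a K-region annelation towards
#' `n_bays_b`.  Bays entirely within the non-pyrene tail (no attached ring
#' involved) follow the generic phenanthrene-like H-H clash and count as
#' a-bays with weight 1.  Conflicting evidence raises an error rather than a
#' silent guess.
#'
#' @param b a `benzenoid` with exactly one pyrene core.
#' @param report optional [annelation_report()] (recomputed when `NULL`).
#' @param motifs optional [detect_motifs()] result (recomputed when `NULL`).
#' @return a `motif_counts` object gaining fields `n_bays_a` and `n_bays_b`.
#' @examples
#' ss <- sample_strain_set()
#' attribute_bays(ss[["b_s1"]])$n_bays_b  # 2
#' @export
attribute_bays <- function(b, report = NULL, motifs = NULL) {
  if (is.null(report)) report <- annelation_report(b)
  if (is.null(motifs)) motifs <- detect_motifs(b)
  cg <- motifs$walk$carbon_graph
  labels <- report$labels
  nb_a <- 0L; nb_b <- 0L
  for (run in motifs$runs) {
    if (length(run) != 2L) next
    rings_touched <- unique(unlist(cg$membership[run]))
    letters <- character(0)
    for (rr in rings_touched) {
      if (labels[rr] != "attached") next
      core_nb <- b$adj[rr, b$adj[rr, ] > 0L]
      core_nb <- core_nb[labels[core_nb] %in% c("a", "b")]
      letters <- c(letters, labels[core_nb])
    }
    letters <- unique(letters)
    if (length(letters) > 1L)
      stop("ambiguous bay attribution: bay touches rings annelated to both ",
           "a and b core rings")
    if (length(letters) == 0L || letters == "a") nb_a <- nb_a + 1L
    else nb_b <- nb_b + 1L
  }
  motifs$n_bays_a <- nb_a
  motifs$n_bays_b <- nb_b
  motifs
}

#' Published motif weights
#'
#' The relative strain weighting 1 : 0.7 : 4.3 for a-bay : b-bay : cove,
#' normalized to the a-bay.
#'
#' @return a named numeric vector with entries `bay_a`, `bay_b`, `cove`.
#' @export
strain_weights <- function() c(bay_a = 1, bay_b = 0.7, cove = 4.3)

#' Reference frozen-core strain energies
#'
#' The packaged reference table for weight derivation: the reported values
#' 2.6 kcal/mol (`a_s1`, one a-bay) and 3.5 kcal/mol (`b_s1`, two b-bays),
#' plus the value implied for the pure-cove reference `aab_s1` (two coves)
#' by the published cove weight: 2 x 4.3 x 2.6 = 22.36 kcal/mol.  The
#' `source` column distinguishes reported from derived entries.
#'
#' @return a data frame with columns `id`, `E_strain_kcal_mol`, `n_bays_a`,
#'   `n_bays_b`, `n_coves`, `source`.
#' @export
strain_references <- function() {
  data.frame(id = c("a_s1", "b_s1", "aab_s1"),
             E_strain_kcal_mol = c(2.6, 3.5, 2 * 4.3 * 2.6),
             n_bays_a = c(1L, 0L, 0L),
             n_bays_b = c(0L, 2L, 0L),
             n_coves = c(0L, 0L, 2L),
             source = c("reported", "reported", "derived"))
}

#' Derive motif weights from reference strain energies
#'
#' Each reference molecule must feature only one motif type.  Its strain
#' energy is divided by the a-bay reference energy and by the number of
#' motifs it accounts for, normalizing the a-bay weight to 1.
#'
#' @param refs a data frame as returned by [strain_references()]; a custom
#'   table may be supplied (e.g. read from CSV with columns `id`,
#'   `E_strain_kcal_mol` and the three motif-count columns).
#' @param round_digits digits to round the weights to (1 reproduces the
#'   published 1 : 0.7 : 4.3); `NULL` disables rounding.
#' @return a named numeric vector with entries `bay_a`, `bay_b`, `cove`.
#' @examples
#' derive_weights(strain_references())  # c(bay_a = 1, bay_b = 0.7, cove = 4.3)
#' @export
derive_weights <- function(refs, round_digits = 1L) {
  needed <- c("E_strain_kcal_mol", "n_bays_a", "n_bays_b", "n_coves")
  if (!all(needed %in% names(refs)))
    stop("reference table needs columns ", paste(needed, collapse = ", "))
  motif_of <- function(row) {
    nz <- c(a = row$n_bays_a > 0L, b = row$n_bays_b > 0L, cove = row$n_coves > 0L)
    if (sum(nz) != 1L)
      stop("reference '", row$id, "' does not feature exactly one motif type")
    names(nz)[nz]
  }
  kinds <- vapply(seq_len(nrow(refs)), function(k) motif_of(refs[k, ]),
                  character(1L))
  for (kind in c("a", "b", "cove"))
    if (!kind %in% kinds) stop("missing reference for motif class '", kind, "'")
  pick <- function(kind) refs[which(kinds == kind)[1L], ]
  ra <- pick("a"); rb <- pick("b"); rc <- pick("cove")
  e_a <- ra$E_strain_kcal_mol / ra$n_bays_a
  w <- c(bay_a = 1,
         bay_b = (rb$E_strain_kcal_mol / e_a) / rb$n_bays_b,
         cove = (rc$E_strain_kcal_mol / e_a) / rc$n_coves)
  if (!is.null(round_digits)) w <- round(w, round_digits)
  w
}

#' Weighted strain score
#'
#' `n_strain = w_bay_a * n_bays_a + w_bay_b * n_bays_b + w_cove * n_coves`.
#' Fissures never enter the score; fjords are excluded from the model and a
#' warning is emitted when any are present.
#'
#' @param counts a `motif_counts` object with attributed bays (see
#'   [attribute_bays()]), or a named list/vector providing `n_bays_a`,
#'   `n_bays_b`, `n_coves` (and optionally `n_fjords`).
#' @param weights motif weights, default [strain_weights()].
#' @return numeric strain score.
#' @examples
#' n_strain(list(n_bays_a = 0, n_bays_b = 3, n_coves = 1))  # 6.4
#' @export
n_strain <- function(counts, weights = strain_weights()) {
  get0n <- function(f) if (is.null(counts[[f]])) 0 else as.numeric(counts[[f]])
  if (get0n("n_fjords") > 0)
    warning("fjord motif(s) present; fjords are excluded from n_strain")
  unname(weights[["bay_a"]] * get0n("n_bays_a") +
         weights[["bay_b"]] * get0n("n_bays_b") +
         weights[["cove"]] * get0n("n_coves"))
}

#' Full strain analysis of a molecule
#'
#' Convenience pipeline: perimeter walk, motif detection, bay attribution
#' and the weighted score.
#'
#' @param b a `benzenoid` with exactly one pyrene core.
#' @param weights motif weights, default [strain_weights()].
#' @return a `motif_counts` object gaining the field `n_strain`.
#' @export
strain_score <- function(b, weights = strain_weights()) {
  m <- attribute_bays(b)
  m$n_strain <- n_strain(m, weights)
  m
}
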