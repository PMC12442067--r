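# Pattern-level statistics: relative energies, summaries, Delta-Clar
# regressions and the linear model for the mean relative energy,
#   E_rel_avg = alpha * n_strain_avg + beta * Delta-Clar + gamma.

HARTREE_TO_KCAL <- 627.5095

#' Structural descriptor table for a set of molecules
#'
#' Computes, per molecule: ring count, annelation pattern, longest linear
#' stretch, pattern-level Delta-Clar, perimeter motif counts and the
#' weighted strain score.
#'
#' @param structures a named list of `benzenoid`s with single pyrene cores.
#' @param weights motif weights for the strain score.
#' @return a data frame with one row per molecule.
#' @examples
#' head(pbh_descriptors(sample_strain_set()), 3)
#' @export
pbh_descriptors <- function(structures, weights = strain_weights()) {
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(b)
      if (nzchar(b$name)) b$name else "", character(1L))
  rows <- lapply(seq_along(structures), function(k) {
    b <- structures[[k]]
    rep <- annelation_report(b)
    m <- attribute_bays(b, report = rep)
    data.frame(id = names(structures)[k],
               n_rings = n_rings(b),
               pattern = rep$pattern,
               n_LL = rep$n_LL,
               delta_clar = pattern_delta_clar(rep$pattern)$delta_clar,
               n_fissures = m$n_fissures,
               n_bays_a = m$n_bays_a,
               n_bays_b = m$n_bays_b,
               n_coves = m$n_coves,
               n_fjords = m$n_fjords,
               n_strain = n_strain(m, weights))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Relative energies within size groups
#'
#' Adds a column `E_rel_kcal_mol`: the energy of each molecule above its
#' lowest-energy constitutional isomer (same `n_rings`), converted to
#' kcal/mol.  Accepted total-energy units are `"hartree"` and `"kcal/mol"`
#' (1 hartree = 627.5095 kcal/mol); tables mixing units are rejected.
#'
#' @param records a data frame with columns `n_rings`, `Etot`, `Etot_unit`.
#' @return `records` with the `E_rel_kcal_mol` column added/replaced.
#' @export
relative_energy <- function(records) {
  needed <- c("n_rings", "Etot", "Etot_unit")
  if (!all(needed %in% names(records)))
    stop("records need columns ", paste(needed, collapse = ", "))
  units <- unique(records$Etot_unit)
  if (length(units) != 1L)
    stop("mixed energy units in table: ", paste(units, collapse = ", "))
  if (!units %in% c("hartree", "kcal/mol"))
    stop("unknown energy unit '", units, "'")
  e <- if (units == "hartree") records$Etot * HARTREE_TO_KCAL else records$Etot
  records$E_rel_kcal_mol <-
    e - stats::ave(e, records$n_rings, FUN = min)
  records
}

#' Flag HOMO/LUMO/gap inconsistencies
#'
#' Checks `gap = LUMO - HOMO` to a tolerance and returns the offending row
#' indices (with a warning naming how many there are).
#'
#' @param records a data frame with columns `HOMO_eV`, `LUMO_eV`, `gap_eV`.
#' @param tol tolerance in eV.
#' @return integer vector of row indices violating the identity.
#' @export
check_gap_consistency <- function(records, tol = 1e-3) {
  bad <- which(abs(records$gap_eV - (records$LUMO_eV - records$HOMO_eV)) > tol)
  if (length(bad))
    warning(length(bad), " record(s) violate gap = LUMO - HOMO beyond ",
            tol, " eV")
  bad
}

#' Read a molecular property table from CSV
#'
#' Expects the schema `id, smiles, n_rings, HOMO_eV, LUMO_eV, gap_eV,
#' aIP_eV, aEA_eV, Etot, Etot_unit` (extra columns pass through).  Gap
#' consistency is checked with [check_gap_consistency()].
#'
#' @param path CSV file path.
#' @return a data frame.
#' @export
read_property_table <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "n_rings", "HOMO_eV", "LUMO_eV", "gap_eV",
              "aIP_eV", "aEA_eV", "Etot", "Etot_unit")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols))
    stop("property table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  check_gap_consistency(rec)
  rec
}

#' Per-pattern property summaries
#'
#' Joins a property table with structural descriptors and summarizes each
#' annelation pattern: count, mean and standard deviation of every numeric
#' property, the pattern's Delta-Clar and its average strain score.
#'
#' @param records a property table (rows identified by `id`).
#' @param descriptors a descriptor table from [pbh_descriptors()].
#' @param properties character vector of property columns to summarize;
#'   defaults to the intersection of the usual six with `names(records)`.
#' @return a data frame with one row per pattern, columns `pattern`, `n`,
#'   `delta_clar`, `n_strain_avg` and `<prop>_mean` / `<prop>_sd` per
#'   property.  Records whose `id` has no descriptor row are dropped with a
#'   warning listing them.
#' @export
pattern_summary <- function(records, descriptors,
                            properties = intersect(
                              c("HOMO_eV", "LUMO_eV", "gap_eV", "aIP_eV",
                                "aEA_eV", "E_rel_kcal_mol"),
                              names(records))) {
  unmatched <- setdiff(records$id, descriptors$id)
  if (length(unmatched))
    warning("dropping ", length(unmatched), " unclassified record(s): ",
            paste(head(unmatched, 5L), collapse = ", "),
            if (length(unmatched) > 5L) ", ..." else "")
  dat <- merge(records[, c("id", properties), drop = FALSE],
               descriptors[, c("id", "pattern", "delta_clar", "n_strain")],
               by = "id")
  pats <- intersect(PATTERN_LEVELS, unique(dat$pattern))
  rows <- lapply(pats, function(p) {
    g <- dat[dat$pattern == p, , drop = FALSE]
    row <- data.frame(pattern = p, n = nrow(g),
                      delta_clar = unique(g$delta_clar)[1L],
                      n_strain_avg = mean(g$n_strain))
    for (pr in properties) {
      row[[paste0(pr, "_mean")]] <- mean(g[[pr]])
      row[[paste0(pr, "_sd")]] <- if (nrow(g) > 1L) sd(g[[pr]]) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Regress pattern-mean properties on Delta-Clar
#'
#' Ordinary least squares of the per-pattern mean of a property against the
#' pattern's Delta-Clar, optionally within subgroups (e.g. per `n_rings` or
#' per `n_LL`).  Subgroups with fewer than 3 patterns, or with a constant
#' property, are reported with `NA` coefficients and a message.
#'
#' @param records a property table.
#' @param descriptors a descriptor table from [pbh_descriptors()].
#' @param property name of the property column.
#' @param split_by optional descriptor column name to split by (`"n_rings"`
#'   or `"n_LL"`).
#' @return a data frame with columns `group`, `slope`, `intercept`,
#'   `r_squared`, `n_patterns`.
#' @export
regress_property_vs_deltaclar <- function(records, descriptors, property,
                                          split_by = NULL) {
  if (!property %in% names(records)) stop("no column '", property, "'")
  dat <- merge(records[, c("id", property)],
               descriptors[, c("id", "pattern", "delta_clar",
                               intersect(split_by, names(descriptors)))],
               by = "id")
  groups <- if (is.null(split_by)) list(`all` = dat)
            else split(dat, dat[[split_by]])
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    means <- aggregate(g[[property]],
                       by = list(delta_clar = g$delta_clar, pattern = g$pattern),
                       FUN = mean)
    names(means)[3L] <- "y"
    if (nrow(means) < 3L || stats::var(means$y) == 0 ||
        stats::var(means$delta_clar) == 0) {
      message("subgroup '", gname, "' degenerate (",
              nrow(means), " pattern mean(s)); skipped")
      return(data.frame(group = gname, slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        n_patterns = nrow(means)))
    }
    fit <- lm(y ~ delta_clar, data = means)
    data.frame(group = gname, slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = summary(fit)$r.squared,
               n_patterns = nrow(means))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Fit the pattern-level relative-energy model
#'
#' Least-squares fit of `E_rel_avg = alpha * n_strain_avg +
#' beta * Delta-Clar + gamma` on the pattern-level points of a
#' [pattern_summary()] table (8 points for the full pattern set; at least 4
#' are required).  Weighting by pattern population is available behind
#' `weight_by_n`.
#'
#' @param summaries a pattern summary with columns `n_strain_avg`,
#'   `delta_clar` and `E_rel_kcal_mol_mean`.
#' @param weight_by_n weight patterns by their molecule counts?
#' @return an object of class `erel_fit` with elements `alpha`, `beta`,
#'   `gamma`, `r_squared` and the underlying `lm` fit.
#' @seealso [predict_erel()]
#' @export
fit_erel_model <- function(summaries, weight_by_n = FALSE) {
  needed <- c("n_strain_avg", "delta_clar", "E_rel_kcal_mol_mean")
  if (!all(needed %in% names(summaries)))
    stop("summaries need columns ", paste(needed, collapse = ", "))
  if (nrow(summaries) < 4L)
    stop("need at least 4 pattern-level points, got ", nrow(summaries))
  w <- if (weight_by_n) summaries$n else NULL
  fit <- lm(E_rel_kcal_mol_mean ~ n_strain_avg + delta_clar,
            data = summaries, weights = w)
  cf <- coef(fit)
  structure(list(alpha = unname(cf["n_strain_avg"]),
                 beta = unname(cf["delta_clar"]),
                 gamma = unname(cf["(Intercept)"]),
                 r_squared = summary(fit)$r.squared,
                 n_points = nrow(summaries),
                 lm = fit),
            class = "erel_fit")
}

#' @export
print.erel_fit <- function(x, ...) {
  cat(sprintf(
    "<erel_fit> E_rel_avg = %.4g * n_strain_avg + %.4g * DeltaClar + %.4g  (R^2 = %.4f, %d points)\n",
    x$alpha, x$beta, x$gamma, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict mean relative energy from the fitted model
#'
#' @param model an `erel_fit` (or any list with `alpha`, `beta`, `gamma`).
#' @param n_strain_avg,delta_clar descriptor values (vectorized).
#' @return predicted E_rel in kcal/mol.
#' @examples
#' m <- list(alpha = 0.8, beta = -0.3, gamma = 13.4)
#' predict_erel(m, 0, 0)  # 13.4
#' @export
predict_erel <- function(model, n_strain_avg, delta_clar) {
  model$alpha * n_strain_avg + model$beta * delta_clar + model$gamma
}
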