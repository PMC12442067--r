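# Pyrene-core detection and annelation-pattern classification.
#
# Pyrene's four rings split into two types: the *a* rings, each fused to two
# other rings, and the *b* rings, fused to three.  Extra benzene rings fused
# onto the core ("annelations") land either on an a ring or on the K-region
# edge of a b ring; the multiset of annelated core-ring letters defines the
# eight patterns a, b, aa, bb, ab, aab, abb, aabb.

PATTERN_LEVELS <- c("a", "b", "aa", "bb", "ab", "aab", "abb", "aabb")

#' Find pyrene cores in a benzenoid
#'
#' A pyrene core is a set of four rings whose induced dualist subgraph is the
#' pyrene rhombus (two mutually fused rings, each fused to both of the other
#' two) and whose carbon union contains the two atoms shared by three rings.
#'
#' @param b a `benzenoid`.
#' @return a list of integer 4-vectors (ring indices); empty if no core.
#' @examples
#' length(find_pyrene_core(pbh_fixture("pyrene")))      # 1
#' length(find_pyrene_core(pbh_fixture("anthracene")))  # 0
#' @export
find_pyrene_core <- function(b) {
  stopifnot(inherits(b, "benzenoid"))
  n <- n_rings(b)
  if (n < 4L) return(list())
  cg <- carbon_graph(b)
  out <- list()
  # candidate b-ring pairs are fused ring pairs with >= 2 common neighbours
  ed <- dualist_edges(b)
  for (k in seq_len(nrow(ed))) {
    i <- ed$i[k]; j <- ed$j[k]
    common <- intersect(which(apply(b$adj, 1L, function(row) any(row == i))),
                        which(apply(b$adj, 1L, function(row) any(row == j))))
    common <- setdiff(common, c(i, j))
    if (length(common) < 2L) next
    for (pair in utils::combn(common, 2L, simplify = FALSE)) {
      core <- sort(c(i, j, pair))
      # induced dualist must be the rhombus: 5 edges, the a rings not fused
      if (dualist_adjacent(b, pair[1L], pair[2L])) next
      ndeg <- vapply(core, function(x) sum(b$adj[x, ] %in% core), integer(1L))
      if (!identical(sort(ndeg), c(2L, 2L, 3L, 3L))) next
      # two atoms shared by exactly these three-ring subsets
      triple <- vapply(cg$membership, function(m)
        length(m) == 3L && all(m %in% core), logical(1L))
      if (sum(triple) != 2L) next
      out <- c(out, list(core))
    }
  }
  unique(out)
}

#' Label rings relative to a pyrene core
#'
#' Within the core, degree-2 rings (in the induced dualist) are `a` and
#' degree-3 rings are `b`; non-core rings fused to a core ring are
#' `attached`; all remaining rings are `remote`.
#'
#' @param b a `benzenoid`.
#' @param core an integer 4-vector as returned by [find_pyrene_core()].
#' @return a character vector of length `n_rings(b)` with values `"a"`,
#'   `"b"`, `"attached"`, `"remote"`.
#' @export
label_core_rings <- function(b, core) {
  stopifnot(inherits(b, "benzenoid"))
  core <- sort(as.integer(core))
  if (length(core) != 4L || !all(core %in% seq_len(n_rings(b))))
    stop("malformed core")
  ndeg <- vapply(core, function(x) sum(b$adj[x, ] %in% core), integer(1L))
  if (!identical(sort(ndeg), c(2L, 2L, 3L, 3L))) stop("malformed core")
  labels <- rep("remote", n_rings(b))
  labels[core[ndeg == 2L]] <- "a"
  labels[core[ndeg == 3L]] <- "b"
  for (i in setdiff(seq_len(n_rings(b)), core))
    if (any(b$adj[i, ] %in% core)) labels[i] <- "attached"
  labels
}

#' Annelation report: core, labels, pattern and longest linear stretch
#'
#' @param b a `benzenoid` containing exactly one pyrene core.
#' @return an object of class `annelation_report` with elements `core`
#'   (ring indices), `labels`, `pattern` (one of the eight codes, or `""`
#'   for bare pyrene) and `n_LL`.
#' @examples
#' ss <- sample_strain_set()
#' annelation_report(ss[["abb_s1"]])$pattern  # "abb"
#' @export
annelation_report <- function(b) {
  cores <- find_pyrene_core(b)
  if (length(cores) == 0L) stop("no pyrene core found")
  if (length(cores) > 1L) stop("multiple pyrene cores found (", length(cores), ")")
  core <- cores[[1L]]
  labels <- label_core_rings(b, core)
  annelated <- vapply(core, function(i) {
    any(labels[b$adj[i, b$adj[i, ] > 0L]] == "attached")
  }, logical(1L))
  letters <- labels[core][annelated]
  pattern <- paste(sort(letters), collapse = "")  # a sorts before b
  structure(list(core = core, labels = labels, pattern = pattern,
                 n_LL = longest_linear_stretch(b)),
            class = "annelation_report")
}

#' @export
print.annelation_report <- function(x, ...) {
  cat(sprintf("<annelation_report> pattern '%s', core rings %s, n_LL = %d\n",
              x$pattern, paste(x$core, collapse = ","), x$n_LL))
  invisible(x)
}

#' Classify a molecule into one of the eight annelation patterns
#'
#' @param b a `benzenoid` with exactly one pyrene core.
#' @return one of `"a"`, `"b"`, `"aa"`, `"bb"`, `"ab"`, `"aab"`, `"abb"`,
#'   `"aabb"` (or `""` when no core ring is annelated, i.e. bare pyrene).
#' @export
classify_pattern <- function(b) annelation_report(b)$pattern

#' Longest linear stretch of rings
#'
#' The maximum number of rings on a dualist path whose consecutive edges all
#' point in the same lattice direction (180-degree, acene-like
#' continuation).  By default the stretch may run through pyrene core rings;
#' set `include_core = FALSE` to confine it to non-core rings.
#'
#' @param b a `benzenoid`.
#' @param include_core may the stretch pass through pyrene core rings?
#'   (Only consulted when the molecule has a pyrene core.)
#' @return integer >= 1.
#' @examples
#' longest_linear_stretch(pbh_fixture("anthracene"))    # 3
#' longest_linear_stretch(pbh_fixture("phenanthrene"))  # 2
#' @export
longest_linear_stretch <- function(b, include_core = TRUE) {
  stopifnot(inherits(b, "benzenoid"))
  allowed <- rep(TRUE, n_rings(b))
  if (!include_core) {
    cores <- find_pyrene_core(b)
    if (length(cores) == 1L) allowed[cores[[1L]]] <- FALSE
  }
  best <- if (any(allowed)) 1L else 0L
  for (i in which(allowed)) for (d in 0:5) {
    # only count from a chain start (no allowed predecessor in direction d)
    prev <- b$adj[i, opp_dir(d) + 1L]
    if (prev > 0L && allowed[prev]) next
    len <- 1L
    cur <- i
    repeat {
      nxt <- b$adj[cur, d + 1L]
      if (nxt == 0L || !allowed[nxt]) break
      len <- len + 1L
      cur <- nxt
    }
    if (len > best) best <- len
  }
  best
}
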