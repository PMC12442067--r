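# Independent oracles, deliberately separate from the package's C++ kernels.

# all perfect matchings by plain R backtracking (Kekule-count oracle)
oracle_matchings <- function(cg) {
  bonds <- cg$bonds
  res <- list()
  rec <- function(cov, cur) {
    u <- which(!cov)[1L]
    if (is.na(u)) {
      res[[length(res) + 1L]] <<- sort(cur)
      return(invisible())
    }
    inc <- which((bonds[, 1L] == u & !cov[bonds[, 2L]]) |
                 (bonds[, 2L] == u & !cov[bonds[, 1L]]))
    for (e in inc) {
      cov2 <- cov
      cov2[bonds[e, ]] <- TRUE
      rec(cov2, c(cur, e))
    }
  }
  if (cg$n_atoms %% 2L == 0L) rec(rep(FALSE, cg$n_atoms), integer(0))
  res
}

# exhaustive Clar oracle: every independent ring subset, matchability via
# igraph's bipartite matching
oracle_clar <- function(b) {
  cg <- carbon_graph(b)
  n <- cg$n_rings
  adjm <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    js <- cg$adj[i, cg$adj[i, ] > 0L]
    adjm[i, js] <- TRUE
  }
  feasible <- function(S) {
    at <- unique(as.vector(cg$ring_atoms[S, , drop = FALSE]))
    keep <- setdiff(seq_len(cg$n_atoms), at)
    if (length(keep) == 0L) return(TRUE)
    bs <- cg$bonds[cg$bonds[, 1L] %in% keep & cg$bonds[, 2L] %in% keep, ,
                   drop = FALSE]
    g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
    if (nrow(bs))
      g <- igraph::add_edges(g, as.vector(t(cbind(match(bs[, 1L], keep),
                                                  match(bs[, 2L], keep)))))
    m <- igraph::max_bipartite_match(g, types = cg$side[keep] == 1L)
    m$matching_size * 2L == length(keep)
  }
  sets <- list()
  best <- -1L
  for (k in 0:n) for (S in utils::combn(n, k, simplify = FALSE)) {
    if (k >= 2L && any(adjm[t(utils::combn(S, 2L))])) next
    if (feasible(S)) {
      if (k > best) { best <- k; sets <- list() }
      if (k == best) sets <- c(sets, list(sort(S)))
    }
  }
  list(clar_number = best, sets = sets)
}

sort_sets <- function(sets) {
  sets <- lapply(sets, function(s) as.integer(sort(s)))
  sets[order(vapply(sets, paste, character(1L), collapse = ","))]
}

# linear acene with k rings
acene <- function(k) {
  build_benzenoid(data.frame(q = seq_len(k) - 1L, r = 0L),
                  name = paste0("acene", k))
}

# random unbranched cata-condensed chain (no immediate turn-backs and no
# peri-forming 60-degree kinks), for property tests
random_chain <- function(n, seed) {
  set.seed(seed)
  repeat {
    dirs <- integer(0)
    d <- sample(0:5, 1L)
    ok <- TRUE
    cells <- matrix(c(0L, 0L), 1L)
    for (k in seq_len(n - 1L)) {
      turn <- sample(c(-1L, 0L, 1L), 1L)  # fused-edge geometry: +-60 or straight
      d <- (d + turn) %% 6L
      dirs <- c(dirs, d)
      nxt <- cells[nrow(cells), ] + c(pyrenoid:::DIR_Q[d + 1L],
                                      pyrenoid:::DIR_R[d + 1L])
      cells <- rbind(cells, nxt)
    }
    key <- paste(cells[, 1L], cells[, 2L])
    if (anyDuplicated(key)) next  # avoid helicene bookkeeping here
    b <- try(build_benzenoid(data.frame(q = cells[, 1L], r = cells[, 2L]),
                             name = sprintf("chain%d_%d", n, seed)),
             silent = TRUE)
    if (!inherits(b, "try-error") && nrow(dualist_edges(b)) == n - 1L)
      return(b)
  }
}

# enumeration caches shared across test files
.space_cache <- new.env(parent = emptyenv())
cached_space <- function(min_rings, max_rings) {
  key <- paste0("s", min_rings, "_", max_rings)
  if (is.null(.space_cache[[key]]))
    .space_cache[[key]] <- enumerate_space(min_rings, max_rings)
  .space_cache[[key]]
}
cached_sample_set <- function() {
  if (is.null(.space_cache$ss)) .space_cache$ss <- sample_strain_set()
  .space_cache$ss
}
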