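#' Benzenoid structures on the hexagon lattice
#'
#' A `benzenoid` is an assembly of fused hexagonal rings.  Rings carry axial
#' lattice coordinates `(q, r)` plus an integer `layer` that disambiguates
#' helicenic winding (two rings may occupy the same lattice cell on different
#' layers).  The authoritative description of the molecule is the *dualist*
#' graph: one node per ring, one edge per fused (shared) hexagon edge, each
#' dualist edge annotated with its lattice direction (0..5, multiples of 60
#' degrees).  Coordinates are derived bookkeeping.
#'
#' @param hexes a data frame or matrix with columns `q`, `r` and optionally
#'   `layer` (default 0), one row per ring.
#' @param name free-text molecule name.
#' @param fuse optional two-column integer matrix of ring index pairs giving
#'   the fused ring pairs explicitly.  When omitted, two rings are taken as
#'   fused iff their cells are lattice-adjacent and they lie on the same
#'   layer (correct for all planar benzenoids).  Explicit fusion pairs are
#'   needed only for helicenic structures in which lattice adjacency and
#'   chemical fusion disagree.
#' @return an object of class `benzenoid`.
#' @examples
#' pyr <- build_benzenoid(data.frame(q = c(0, 1, 0, 1), r = c(0, 0, 1, -1)),
#'                        name = "pyrene")
#' n_rings(pyr)
#' @export
build_benzenoid <- function(hexes, name = "", fuse = NULL) {
  hexes <- as.data.frame(hexes)
  if (nrow(hexes) == 0L) stop("empty hexagon list")
  if (is.null(hexes$layer)) hexes$layer <- 0L
  if (!all(c("q", "r") %in% names(hexes)))
    stop("hexagon list needs columns q and r")
  rings <- data.frame(q = as.integer(hexes$q), r = as.integer(hexes$r),
                      layer = as.integer(hexes$layer))
  if (any(is.na(rings))) stop("hexagon coordinates must be integers")
  key <- paste(rings$q, rings$r, rings$layer)
  if (anyDuplicated(key)) stop("duplicate hexagon in input")

  n <- nrow(rings)
  adj <- matrix(0L, n, 6L)
  add_edge <- function(adj, i, j) {
    d <- axial_direction(rings$q[i], rings$r[i], rings$q[j], rings$r[j])
    if (is.na(d)) stop("fused rings ", i, " and ", j, " are not lattice-adjacent")
    if (adj[i, d + 1L] != 0L || adj[j, opp_dir(d) + 1L] != 0L)
      stop("two rings share more than one hexagon edge")
    adj[i, d + 1L] <- j
    adj[j, opp_dir(d) + 1L] <- i
    adj
  }
  if (is.null(fuse)) {
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (rings$layer[i] != rings$layer[j]) next
        d <- axial_direction(rings$q[i], rings$r[i], rings$q[j], rings$r[j])
        if (!is.na(d)) adj <- add_edge(adj, i, j)
      }
    }
  } else {
    fuse <- matrix(as.integer(fuse), ncol = 2L)
    for (k in seq_len(nrow(fuse))) adj <- add_edge(adj, fuse[k, 1L], fuse[k, 2L])
  }
  new_benzenoid(rings, adj, name)
}

# low-level constructor + invariant checks
new_benzenoid <- function(rings, adj, name = "", validate = TRUE) {
  b <- structure(list(name = as.character(name), rings = rings, adj = adj),
                 class = "benzenoid")
  if (validate) validate_benzenoid(b)
  b
}

validate_benzenoid <- function(b) {
  n <- nrow(b$rings)
  if (n < 1L || n > 12L)
    stop("benzenoid must have between 1 and 12 rings (got ", n, ")")
  # connectivity of the dualist
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in b$adj[i, ]) if (j > 0L && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
  }
  if (!all(seen)) stop("disconnected: dualist graph is not connected")
  cg <- carbon_graph(b)
  # mutual-fusion sanity for atoms in 3 rings
  for (m in cg$membership) {
    if (length(m) > 3L) stop("atom shared by more than 3 rings")
    if (length(m) == 3L) {
      pairs <- combn(m, 2L)
      for (k in seq_len(ncol(pairs)))
        if (!dualist_adjacent(b, pairs[1L, k], pairs[2L, k]))
          stop("atom shared by 3 rings that are not mutually fused")
    }
  }
  if (!all(cg$degree %in% c(2L, 3L))) stop("carbon atom of invalid degree")
  # simply connected: the boundary must be a single cycle
  pw <- try(perimeter_walk_impl(cg), silent = TRUE)
  if (inherits(pw, "try-error")) stop("hole detected: ", attr(pw, "condition")$message)
  invisible(b)
}

dualist_adjacent <- function(b, i, j) any(b$adj[i, ] == j)

# construct from a bare n x 6 direction-indexed adjacency matrix; cells are
# recovered by BFS from ring 1 at the origin, layers by cell-collision order
benzenoid_from_adj <- function(adj, name = "", validate = FALSE) {
  n <- nrow(adj)
  q <- integer(n); r <- integer(n)
  seen <- logical(n); seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (d in 0:5) {
      j <- adj[i, d + 1L]
      if (j > 0L && !seen[j]) {
        q[j] <- q[i] + DIR_Q[d + 1L]
        r[j] <- r[i] + DIR_R[d + 1L]
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  if (!all(seen)) stop("disconnected dualist")
  layer <- integer(n)
  cellkey <- paste(q, r)
  for (i in seq_len(n)) layer[i] <- sum(cellkey[seq_len(i - 1L)] == cellkey[i])
  new_benzenoid(data.frame(q = q, r = r, layer = layer), adj, name,
                validate = validate)
}

#' Number of rings of a benzenoid
#' @param b a `benzenoid`.
#' @return integer ring count.
#' @export
n_rings <- function(b) {
  stopifnot(inherits(b, "benzenoid"))
  nrow(b$rings)
}

#' Dualist edges of a benzenoid
#'
#' @param b a `benzenoid`.
#' @return a data frame with one row per fused ring pair: ring indices
#'   `i < j` and the lattice direction `dir` (0..5) from `i` to `j`.
#' @export
dualist_edges <- function(b) {
  stopifnot(inherits(b, "benzenoid"))
  out <- NULL
  for (i in seq_len(n_rings(b))) for (d in 0:5) {
    j <- b$adj[i, d + 1L]
    if (j > i) out <- rbind(out, c(i, j, d))
  }
  if (is.null(out)) out <- matrix(integer(0), 0L, 3L)
  data.frame(i = out[, 1L], j = out[, 2L], dir = out[, 3L])
}

#' @export
print.benzenoid <- function(x, ...) {
  cg <- carbon_graph(x)
  nH <- sum(cg$degree == 2L)
  cat(sprintf("<benzenoid> %s: %d ring(s), C%dH%d, %d dualist edge(s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_rings(x), cg$n_atoms, nH, nrow(dualist_edges(x))))
  invisible(x)
}

#' Apply a lattice symmetry to a benzenoid
#'
#' Rotates by multiples of 60 degrees, optionally reflects, and translates a
#' structure on the lattice.  The result is the same constitutional isomer
#' (used mainly to exercise invariance properties).
#'
#' @param b a `benzenoid`.
#' @param rotate integer number of 60-degree counter-clockwise rotations.
#' @param reflect reflect across the lattice `q` axis first?
#' @param translate integer axial offset `c(q, r)` applied last.
#' @return a `benzenoid`.
#' @export
transform_benzenoid <- function(b, rotate = 0L, reflect = FALSE,
                                translate = c(0L, 0L)) {
  stopifnot(inherits(b, "benzenoid"))
  qr <- cbind(b$rings$q, b$rings$r)
  if (reflect) qr <- reflect_axial(qr[, 1L], qr[, 2L])
  for (k in seq_len(rotate %% 6L)) qr <- rot60_axial(qr[, 1L], qr[, 2L])
  rings <- data.frame(q = qr[, 1L] + as.integer(translate[1L]),
                      r = qr[, 2L] + as.integer(translate[2L]),
                      layer = b$rings$layer)
  adj <- matrix(0L, n_rings(b), 6L)
  for (i in seq_len(n_rings(b))) for (d in 0:5) {
    j <- b$adj[i, d + 1L]
    if (j > 0L) {
      nd <- if (reflect) dir_reflect(d) else d
      nd <- dir_rotate(nd, rotate %% 6L)
      adj[i, nd + 1L] <- j
    }
  }
  new_benzenoid(rings, adj, b$name, validate = FALSE)
}

#' Carbon graph of a benzenoid
#'
#' Merges the six vertices of every hexagon across fused edges into the
#' molecular carbon skeleton.  Degree-2 atoms carry an implicit hydrogen.
#'
#' @param b a `benzenoid`.
#' @return an object of class `carbon_graph`: atom count, per-ring atom ids,
#'   bond list, per-bond ring counts, per-atom ring membership, degrees, a
#'   bipartition vector and drawing coordinates.
#' @examples
#' cg <- carbon_graph(pbh_fixture("naphthalene"))
#' cg$n_atoms  # 10
#' @export
carbon_graph <- function(b) {
  stopifnot(inherits(b, "benzenoid"))
  n <- n_rings(b)
  parent <- seq_len(6L * n)
  uf_find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  uf_union <- function(a, bb) {
    ra <- uf_find(a); rb <- uf_find(bb)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  slot <- function(i, k) (i - 1L) * 6L + (k %% 6L) + 1L
  for (i in seq_len(n)) for (d in 0:5) {
    j <- b$adj[i, d + 1L]
    if (j > i) {  # each fused edge identifies two vertex pairs
      uf_union(slot(i, d), slot(j, d + 2L))
      uf_union(slot(i, d + 5L), slot(j, d + 3L))
    }
  }
  roots <- vapply(seq_len(6L * n), uf_find, integer(1L))
  atom_of <- match(roots, sort(unique(roots)))
  n_atoms <- max(atom_of)
  ring_atoms <- matrix(atom_of, nrow = n, ncol = 6L, byrow = TRUE)

  # bonds: the six edges of each hexagon, deduplicated across fused edges
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) for (d in 0:5) {
    s <- edge_slots(d)
    a1 <- atom_of[slot(i, s[1L])]
    a2 <- atom_of[slot(i, s[2L])]
    from <- c(from, min(a1, a2)); to <- c(to, max(a1, a2))
  }
  bk <- paste(from, to)
  keep <- !duplicated(bk)
  bond_nrings <- as.integer(table(bk)[bk[keep]])
  bonds <- cbind(from[keep], to[keep])

  membership <- vector("list", n_atoms)
  for (i in seq_len(n)) for (a in unique(ring_atoms[i, ]))
    membership[[a]] <- c(membership[[a]], i)
  degree <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = n_atoms)

  # drawing coordinates on the doubled grid (helicene overlaps coincide)
  coords <- matrix(0L, n_atoms, 2L)
  for (i in seq_len(n)) {
    cx <- 2L * b$rings$q[i] + b$rings$r[i]
    cy <- 3L * b$rings$r[i]
    for (k in 0:5) {
      a <- atom_of[slot(i, k)]
      coords[a, ] <- c(cx + VERTEX_OFF[k + 1L, 1L], cy + VERTEX_OFF[k + 1L, 2L])
    }
  }

  # bipartition by BFS 2-colouring (benzenoid carbon graphs are bipartite)
  side <- rep(NA_integer_, n_atoms)
  nbr <- vector("list", n_atoms)
  for (e in seq_len(nrow(bonds))) {
    nbr[[bonds[e, 1L]]] <- c(nbr[[bonds[e, 1L]]], bonds[e, 2L])
    nbr[[bonds[e, 2L]]] <- c(nbr[[bonds[e, 2L]]], bonds[e, 1L])
  }
  side[1L] <- 0L
  queue <- 1L
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in nbr[[u]]) {
      if (is.na(side[v])) { side[v] <- 1L - side[u]; queue <- c(queue, v) }
      else if (side[v] == side[u]) stop("carbon graph is not bipartite")
    }
  }

  # consistency with the hexagon union: 6n - 2E + (#triple atoms)
  E <- sum(b$adj > 0L) / 2L
  n_triple <- sum(lengths(membership) == 3L)
  if (n_atoms != 6L * n - 2L * E + n_triple)
    stop("internal error: atom count inconsistent with hexagon union")
  if (nrow(bonds) != 6L * n - E)
    stop("internal error: bond count inconsistent with hexagon union")

  structure(list(n_atoms = n_atoms, ring_atoms = ring_atoms, bonds = bonds,
                 bond_nrings = bond_nrings, membership = membership,
                 degree = degree, side = side, coords = coords,
                 n_rings = n, adj = b$adj),
            class = "carbon_graph")
}

#' @export
print.carbon_graph <- function(x, ...) {
  cat(sprintf("<carbon_graph> %d atoms (%d CH), %d bonds, %d rings\n",
              x$n_atoms, sum(x$degree == 2L), nrow(x$bonds), x$n_rings))
  invisible(x)
}

perimeter_walk_impl <- function(cg) {
  bd <- which(cg$bond_nrings == 1L)
  if (length(bd) == 0L) stop("no boundary bonds")
  nbr <- vector("list", cg$n_atoms)
  for (e in bd) {
    a <- cg$bonds[e, 1L]; b <- cg$bonds[e, 2L]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  on_bd <- which(lengths(nbr) > 0L)
  if (any(lengths(nbr)[on_bd] != 2L))
    stop("boundary is not a disjoint union of cycles")
  start <- min(on_bd)
  cyc <- start
  prev <- start
  cur <- min(nbr[[start]])  # deterministic walk direction
  while (cur != start) {
    cyc <- c(cyc, cur)
    nxt <- setdiff(nbr[[cur]], prev)
    if (length(nxt) != 1L) stop("boundary walk failed")
    prev <- cur
    cur <- nxt
  }
  if (length(cyc) != length(on_bd))
    stop("boundary splits into multiple cycles (hole or disconnection)")
  cyc
}

#' Perimeter walk and H/F degree coding
#'
#' Walks the single boundary cycle of a simply connected benzenoid and codes
#' every perimeter atom as `H` (degree 2, carries a hydrogen) or `F` (degree
#' 3 fusion carbon).  Maximal runs of `F` between hydrogens are the concave
#' perimeter motifs: fissure (1), bay (2), cove (3), fjord (4).
#'
#' @param b a `benzenoid` (or a `carbon_graph`).
#' @return an object of class `perimeter_walk` with the cyclic atom sequence,
#'   the H/F code, and the canonical (rotation/reflection-minimal) code
#'   string.
#' @examples
#' perimeter_walk(pbh_fixture("benzene"))$canonical  # "HHHHHH"
#' @export
perimeter_walk <- function(b) {
  cg <- if (inherits(b, "carbon_graph")) b else carbon_graph(b)
  cyc <- perimeter_walk_impl(cg)
  code <- ifelse(cg$degree[cyc] == 2L, "H", "F")
  structure(list(atoms = cyc, code = code,
                 canonical = canonical_cycle_string(code),
                 carbon_graph = cg),
            class = "perimeter_walk")
}

#' @export
print.perimeter_walk <- function(x, ...) {
  cat(sprintf("<perimeter_walk> %d atoms: %s\n", length(x$atoms), x$canonical))
  invisible(x)
}

# lexicographically smallest rotation over both reading directions
canonical_cycle_string <- function(chars) {
  n <- length(chars)
  best <- NULL
  for (dirseq in list(chars, rev(chars))) {
    for (s in seq_len(n)) {
      cand <- paste(dirseq[((s - 1L + seq_len(n) - 1L) %% n) + 1L], collapse = "")
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

#' Canonical constitutional-isomer code
#'
#' Two benzenoids receive the same code iff they are the same constitutional
#' isomer, i.e. equal up to lattice translation, the six rotations and
#' reflection (mirror images and helical senses are identified).  The code is
#' the lexicographic minimum over all 12 lattice symmetries and all start
#' rings of a direction-ordered BFS relabelling of the dualist graph.
#'
#' @param b a `benzenoid`.
#' @return a character scalar.
#' @examples
#' canonical_code(pbh_fixture("pyrene"))
#' @export
canonical_code <- function(b) {
  stopifnot(inherits(b, "benzenoid"))
  cpp_canonical_code(b$adj)
}
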