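# SMILES import/export.
#
# Export writes an aromatic SMILES directly from the carbon graph (every
# atom is an aromatic carbon; ring-closure digits come from DFS back
# edges).  Import parses through ChemmineR/ChemmineOB, perceives the
# hexagonal rings, and re-embeds them on the lattice by propagating ring
# orientations across shared edges; helicenic inputs embed too (colliding
# cells get incremented layers), but inputs that are not pure benzenoids
# are rejected.

#' Export a benzenoid as aromatic SMILES
#'
#' @param b a `benzenoid`.
#' @return a SMILES string (all-aromatic carbon skeleton).
#' @examples
#' benzenoid_to_smiles(pbh_fixture("benzene"))  # "c1ccccc1"
#' @export
benzenoid_to_smiles <- function(b) {
  cg <- if (inherits(b, "carbon_graph")) b else carbon_graph(b)
  n <- cg$n_atoms
  nbr <- vector("list", n)
  for (e in seq_len(nrow(cg$bonds))) {
    a <- cg$bonds[e, 1L]; bb <- cg$bonds[e, 2L]
    nbr[[a]] <- c(nbr[[a]], bb)
    nbr[[bb]] <- c(nbr[[bb]], a)
  }
  nbr <- lapply(nbr, sort)
  # recursive DFS: tree children + back edges (each recorded once)
  parent <- rep(NA_integer_, n)
  order_seen <- rep(NA_integer_, n)
  children <- vector("list", n)
  backs <- list()  # each c(opener, closer), opener seen first
  cnt <- 0L
  dfs <- function(u) {
    cnt <<- cnt + 1L
    order_seen[u] <<- cnt
    for (v in nbr[[u]]) {
      if (is.na(order_seen[v])) {
        parent[v] <<- u
        children[[u]] <<- c(children[[u]], v)
        dfs(v)
      } else if (!identical(parent[u], v) && order_seen[v] < order_seen[u]) {
        backs[[length(backs) + 1L]] <<- c(v, u)
      }
    }
  }
  dfs(1L)
  # ring-closure digit bookkeeping
  open_digit <- list()   # key "u_v" -> digit
  used <- logical(99L)
  digit_token <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
  atom_token <- function(u) {
    out <- "c"
    for (k in seq_along(backs)) {
      be <- backs[[k]]
      if (!u %in% be) next
      key <- paste(be, collapse = "_")
      if (is.null(open_digit[[key]])) {
        d <- which(!used)[1L]
        used[d] <<- TRUE
        open_digit[[key]] <<- d
      } else {
        d <- open_digit[[key]]
        used[d] <<- FALSE
      }
      out <- paste0(out, digit_token(d))
    }
    out
  }
  emit <- function(u) {
    out <- atom_token(u)
    ch <- children[[u]]
    if (length(ch)) {
      for (v in ch[-length(ch)]) out <- paste0(out, "(", emit(v), ")")
      out <- paste0(out, emit(ch[length(ch)]))
    }
    out
  }
  emit(1L)
}

#' Import a planar or helicenic benzenoid from SMILES
#'
#' Parses the SMILES with ChemmineR (which uses ChemmineOB/Open Babel),
#' checks that the molecule is a pure carbon 6-ring fusion system, and
#' embeds the rings back onto the hexagon lattice.  Inputs that are not
#' benzenoids (heteroatoms, non-6-rings, substituents) are rejected with an
#' informative error.
#'
#' @param smiles a SMILES string.
#' @param name molecule name for the result.
#' @return a `benzenoid`.
#' @export
smiles_to_benzenoid <- function(smiles, name = "") {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SMILES import requires the ChemmineR package")
  sdf <- ChemmineR::smiles2sdf(smiles)[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  if (!all(elements %in% c("C", "c")))
    stop("not a benzenoid: non-carbon atom present (",
         paste(unique(setdiff(elements, c("C", "c"))), collapse = ", "), ")")
  bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
  graph_to_benzenoid(nrow(ab), bonds, name = name)
}

# shared import path: carbon connectivity -> hexagon-lattice embedding
graph_to_benzenoid <- function(n_atoms, bonds, name = "") {
  deg <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = n_atoms)
  if (!all(deg %in% c(2L, 3L)))
    stop("not a benzenoid: carbon of degree ", paste(setdiff(deg, 2:3), collapse = "/"))
  nbr <- vector("list", n_atoms)
  for (e in seq_len(nrow(bonds))) {
    nbr[[bonds[e, 1L]]] <- c(nbr[[bonds[e, 1L]]], bonds[e, 2L])
    nbr[[bonds[e, 2L]]] <- c(nbr[[bonds[e, 2L]]], bonds[e, 1L])
  }
  rings <- find_hexagons(n_atoms, nbr)
  if (length(rings) == 0L) stop("not a benzenoid: no hexagonal ring found")
  if (length(rings) > 12L) stop("more than 12 rings are not supported")
  if (!setequal(sort(unique(unlist(rings))), seq_len(n_atoms)))
    stop("not a benzenoid: atoms outside any hexagonal ring")
  embed_rings(rings, nbr, name = name)
}

# all 6-cycles of the carbon graph (in a benzenoid each is a hexagon face);
# returned as cyclic atom sequences
find_hexagons <- function(n_atoms, nbr) {
  rings <- list()
  seen <- new.env(parent = emptyenv())
  walk <- function(path) {
    u <- path[length(path)]
    for (v in nbr[[u]]) {
      if (length(path) == 6L) {
        if (v == path[1L]) {
          key <- paste(sort(path), collapse = "_")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            rings[[length(rings) + 1L]] <<- path
          }
        }
      } else if (!v %in% path && v > path[1L]) {
        walk(c(path, v))
      }
    }
  }
  for (a in seq_len(n_atoms)) walk(a)
  rings
}

embed_rings <- function(rings, nbr, name = "") {
  nr <- length(rings)
  # ring adjacency: two rings fused iff they share a bonded atom pair
  ring_sets <- lapply(rings, identity)
  shared_edge <- function(i, j) {
    common <- intersect(ring_sets[[i]], ring_sets[[j]])
    if (length(common) != 2L) return(NULL)
    if (!common[2L] %in% nbr[[common[1L]]]) return(NULL)
    common
  }
  # local slot assignment per ring: atom -> vertex index 0..5
  slots <- vector("list", nr)  # named int vectors: slots[[i]][as.character(atom)]
  cells <- matrix(NA_integer_, nr, 2L)
  assign_ring <- function(i, anchor_atoms, anchor_slots) {
    # orient the stored cyclic order so the two anchor atoms land on the
    # required consecutive slots, then roll the rest of the cycle onward
    cyc <- rings[[i]]
    p <- which(cyc == anchor_atoms[1L])
    fwd <- cyc[((p - 1L + 0:5) %% 6L) + 1L]
    bwd <- cyc[((p - 1L - 0:5) %% 6L) + 1L]
    seqc <- if (fwd[2L] == anchor_atoms[2L]) fwd
            else if (bwd[2L] == anchor_atoms[2L]) bwd
            else stop("anchor atoms not adjacent in ring cycle")
    s <- setNames(as.integer((anchor_slots[1L] + 0:5) %% 6L), seqc)
    # consecutive slots must step by +1 from anchor_slots[1] to [2]
    if (((anchor_slots[1L] + 1L) %% 6L) != anchor_slots[2L])
      stop("internal: anchor slots not consecutive")
    s
  }
  fuse <- NULL
  done <- logical(nr)
  cells[1L, ] <- c(0L, 0L)
  cyc1 <- rings[[1L]]
  slots[[1L]] <- setNames(0:5, cyc1)
  done[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in seq_len(nr)) {
      if (j == i) next
      common <- shared_edge(i, j)
      if (is.null(common)) next
      # direction of the shared edge in ring i: edge(d) = slots {d, d-1}
      si <- slots[[i]][as.character(common)]
      d <- if (((si[1L] + 5L) %% 6L) == si[2L]) si[1L] else si[2L]
      u <- common[which(si == d)]                 # atom on slot d of ring i
      w <- common[which(si == (d + 5L) %% 6L)]
      if (!done[j]) {
        cells[j, ] <- cells[i, ] + c(DIR_Q[d + 1L], DIR_R[d + 1L])
        # ring i's v_d is ring j's v_{d+2}; v_{d-1} is v_{d+3}
        slots[[j]] <- assign_ring(j, c(u, w), c((d + 2L) %% 6L, (d + 3L) %% 6L))
        done[j] <- TRUE
        queue <- c(queue, j)
      } else {
        # closure consistency (peri systems): placement must agree
        expect_cell <- cells[i, ] + c(DIR_Q[d + 1L], DIR_R[d + 1L])
        sj <- slots[[j]][as.character(c(u, w))]
        if (!all(cells[j, ] == expect_cell) ||
            sj[1L] != (d + 2L) %% 6L || sj[2L] != (d + 3L) %% 6L)
          stop("not embeddable on the hexagon lattice")
      }
      if (i < j) fuse <- rbind(fuse, c(i, j))
    }
  }
  if (!all(done)) stop("ring system is disconnected")
  layer <- integer(nr)
  cellkey <- paste(cells[, 1L], cells[, 2L])
  for (i in seq_len(nr)) layer[i] <- sum(cellkey[seq_len(i - 1L)] == cellkey[i])
  build_benzenoid(data.frame(q = cells[, 1L], r = cells[, 2L], layer = layer),
                  name = name, fuse = unique(fuse))
}
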