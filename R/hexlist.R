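# Plain-text .hexlist serialization.
#
# One molecule per block:
#   > name
#   q r layer          (one integer triple per ring)
#   fuse i j           (optional: explicit fused ring pairs)
# Blocks are separated by blank lines.  When no `fuse` lines are present the
# dualist is inferred from the triples (rings fused iff lattice-adjacent on
# the same layer), which is exact for every planar benzenoid.  The writer
# emits `fuse` lines only when inference would not reconstruct the dualist
# (helicenic seams), so files for planar molecules are bare triples.

#' Read benzenoids from a .hexlist file
#'
#' @param path file path.
#' @return a named list of `benzenoid` objects.
#' @seealso [write_hexlist()]
#' @export
read_hexlist <- function(path) {
  lines <- readLines(path)
  lines <- sub("\\s+$", "", lines)
  out <- list()
  cur_name <- NULL; cur_rows <- NULL; cur_fuse <- NULL
  flush <- function() {
    if (is.null(cur_name)) return()
    if (is.null(cur_rows)) stop("block '", cur_name, "' has no rings")
    hexes <- as.data.frame(do.call(rbind, cur_rows))
    names(hexes) <- c("q", "r", "layer")
    fuse <- if (is.null(cur_fuse)) NULL else do.call(rbind, cur_fuse)
    out[[cur_name]] <<- build_benzenoid(hexes, name = cur_name, fuse = fuse)
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- trimws(sub("^>", "", ln))
      cur_rows <- NULL; cur_fuse <- NULL
    } else if (startsWith(ln, "fuse")) {
      v <- as.integer(strsplit(trimws(sub("^fuse", "", ln)), "\\s+")[[1L]])
      if (length(v) != 2L || any(is.na(v))) stop("bad fuse line: ", ln)
      cur_fuse <- c(cur_fuse, list(v))
    } else {
      v <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
      if (!length(v) %in% c(2L, 3L) || any(is.na(v)))
        stop("bad ring line: ", ln)
      if (length(v) == 2L) v <- c(v, 0L)
      cur_rows <- c(cur_rows, list(v))
    }
  }
  flush()
  out
}

#' Write benzenoids to a .hexlist file
#'
#' The writer re-parses its own output internally, so
#' `read_hexlist(write_hexlist(x, f))` round-trips bit-exactly.
#'
#' @param x a `benzenoid` or a list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hexlist <- function(x, path) {
  if (inherits(x, "benzenoid")) x <- list(x)
  lines <- character(0)
  used <- character(0)
  for (k in seq_along(x)) {
    b <- x[[k]]
    stopifnot(inherits(b, "benzenoid"))
    nm <- if (!is.null(names(x)) && nzchar(names(x)[k])) names(x)[k]
          else if (nzchar(b$name)) b$name else paste0("mol", k)
    if (nm %in% used) nm <- paste0(nm, "_", k)
    used <- c(used, nm)
    lines <- c(lines, paste(">", nm),
               sprintf("%d %d %d", b$rings$q, b$rings$r, b$rings$layer))
    if (!inference_recovers_dualist(b)) {
      ed <- dualist_edges(b)
      lines <- c(lines, sprintf("fuse %d %d", ed$i, ed$j))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

inference_recovers_dualist <- function(b) {
  inferred <- try(build_benzenoid(b$rings, name = b$name), silent = TRUE)
  if (inherits(inferred, "try-error")) return(FALSE)
  identical(inferred$adj, b$adj)
}
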