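#' Draw a benzenoid
#'
#' Simple lattice drawing: one hexagon per ring on the doubled integer grid,
#' rings on higher helicene layers slightly offset and dashed.
#'
#' @param x a `benzenoid`.
#' @param labels label rings with their indices?
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.benzenoid <- function(x, labels = TRUE, ...) {
  cx <- 2 * x$rings$q + x$rings$r
  cy <- 3 * x$rings$r
  off <- 0.18 * x$rings$layer
  xs <- range(c(cx - 2, cx + 2)) ; ys <- range(c(cy - 2.5, cy + 2.5))
  plot.new()
  plot.window(xlim = xs, ylim = ys, asp = 2 / sqrt(3))
  for (i in seq_len(n_rings(x))) {
    vx <- cx[i] + VERTEX_OFF[, 1L] + off[i]
    vy <- cy[i] + VERTEX_OFF[, 2L] + off[i]
    polygon(vx, vy, border = "grey20",
            lty = if (x$rings$layer[i] > 0L) 2L else 1L)
    if (labels) text(cx[i] + off[i], cy[i] + off[i], i, cex = 0.8)
  }
  invisible(x)
}
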