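# Small reference molecules used throughout the documentation and tests.

FIXTURE_HEXES <- list(
  benzene = cbind(q = 0L, r = 0L),
  naphthalene = cbind(q = c(0L, 1L), r = c(0L, 0L)),
  anthracene = cbind(q = 0:2, r = c(0L, 0L, 0L)),
  tetracene = cbind(q = 0:3, r = rep(0L, 4L)),
  phenanthrene = cbind(q = c(0L, 1L, 1L), r = c(0L, 0L, 1L)),
  triphenylene = cbind(q = c(0L, 1L, -1L, 0L), r = c(0L, 0L, 1L, -1L)),
  `benzo[c]phenanthrene` = cbind(q = c(0L, 1L, 1L, 0L), r = c(0L, 0L, 1L, 2L)),
  pyrene = cbind(q = c(0L, 1L, 0L, 1L), r = c(0L, 0L, 1L, -1L))
)

#' Built-in reference structures
#'
#' Returns one of the packaged reference benzenoids: `benzene`,
#' `naphthalene`, `anthracene`, `tetracene`, `phenanthrene`, `triphenylene`,
#' `benzo[c]phenanthrene` or `pyrene`.  These cover the textbook perimeter
#' motifs (phenanthrene's bay, benzo[c]phenanthrene's cove) and the pyrene
#' core itself.
#'
#' @param name fixture name; see Details.  With no argument, the vector of
#'   available names is returned.
#' @return a `benzenoid`, or a character vector of names.
#' @examples
#' pbh_fixture("phenanthrene")
#' @export
pbh_fixture <- function(name) {
  if (missing(name)) return(names(FIXTURE_HEXES))
  if (!name %in% names(FIXTURE_HEXES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(FIXTURE_HEXES), collapse = ", "))
  build_benzenoid(as.data.frame(FIXTURE_HEXES[[name]]), name = name)
}

# the four pyrene core rings in canonical local placement:
# rings 1,2 are the b rings (mutually fused), rings 3,4 the a rings
pyrene_core_adj <- function() {
  build_benzenoid(as.data.frame(FIXTURE_HEXES$pyrene), name = "pyrene")$adj
}
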