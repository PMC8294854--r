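#' Construct a WindowGrid
#'
#' Tiles each chromosome with consecutive nonoverlapping windows of
#' \code{windowSize} bp; the final window of each chromosome is truncated at
#' the chromosome end.  100 kb is the scale at which the ancestry HMM
#' operates.
#'
#' @param seqlen named numeric vector of chromosome lengths in bp.
#' @param windowSize window width in bp (default 1e5).
#' @return A \code{\link{WindowGrid-class}} object.
#' @export
WindowGrid <- function(seqlen, windowSize = 1e5) {
  new("WindowGrid", seqlen = seqlen, windowSize = as.integer(windowSize))
}

#' @describeIn WindowGrid The tiling as a \code{GRanges}, in grid order
#'   (chromosomes in \code{seqlen} order, windows left to right).
#' @param x a \code{WindowGrid}.
#' @export
gridWindows <- function(x) {
  W <- x@windowSize
  chroms <- names(x@seqlen)
  starts <- lapply(chroms, function(chr) seq(1L, x@seqlen[[chr]], by = W))
  s <- unlist(starts)
  chr <- factor(rep(chroms, lengths(starts)), levels = chroms)
  gr <- GRanges(chr, IRanges(s, end = pmin(s + W - 1, x@seqlen[as.character(chr)])))
  GenomeInfoDb::seqlengths(gr) <- x@seqlen
  gr
}

#' @describeIn WindowGrid Chromosome lengths.
#' @export
chromLengths <- function(x) x@seqlen

#' @describeIn WindowGrid Window size in bp.
#' @export
windowSize <- function(x) x@windowSize

setMethod("show", "WindowGrid", function(object) {
  gr <- gridWindows(object)
  cat("WindowGrid:", length(object@seqlen), "chromosomes,",
      length(gr), "windows of", object@windowSize, "bp\n")
})
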