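#' GenotypeTable: diploid biallelic genotypes with per-sample coverage
#'
#' Container for a panel of diploid samples genotyped at biallelic SNPs, with
#' per-sample callable-region intervals.  Genotypes are stored as alternate-
#' allele dosages (0, 1, 2; \code{NA} = missing call).  Coverage intervals
#' describe where each sample has sequence data at all, so invariant sites
#' can enter divergence denominators; coordinates are 0-based half-open at
#' the BED boundary and 1-based inside \code{GRanges}, following Bioconductor
#' convention.
#'
#' @slot samples character vector of sample identifiers (column order of
#'   \code{geno}).
#' @slot sites \code{GRanges} of SNP positions (width 1), with metadata
#'   columns \code{REF} and \code{ALT}; sorted, strictly increasing within
#'   chromosome.
#' @slot geno integer matrix, sites x samples, alt-allele dosage in
#'   \{0, 1, 2, NA\}.
#' @slot coverage named \code{GRangesList}, one element per sample, reduced
#'   intervals where the sample has data.
#'
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(
    samples  = "character",
    sites    = "GRanges",
    geno     = "matrix",
    coverage = "GRangesList"
  )
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (ncol(object@geno) != length(object@samples))
    msg <- c(msg, "ncol(geno) must equal length(samples)")
  if (nrow(object@geno) != length(object@sites))
    msg <- c(msg, "nrow(geno) must equal length(sites)")
  if (!all(names(object@coverage) %in% object@samples) ||
      length(object@coverage) != length(object@samples))
    msg <- c(msg, "coverage must be named by, and cover exactly, samples")
  g <- object@geno
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotypes must be dosages in {0,1,2} or NA")
  if (length(object@sites)) {
    if (!all(c("REF", "ALT") %in% colnames(mcols(object@sites))))
      msg <- c(msg, "sites must carry REF and ALT metadata columns")
    sn <- as.character(seqnames(object@sites))
    pos <- start(object@sites)
    ord <- order(sn, pos)
    if (!identical(ord, seq_along(pos)))
      msg <- c(msg, "sites must be sorted by chromosome then position")
    if (anyDuplicated(paste(sn, pos)))
      msg <- c(msg, "site positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' WindowGrid: nonoverlapping window tiling of a genome
#'
#' Defines the analysis grid: each chromosome of known length is tiled by
#' consecutive nonoverlapping windows of fixed size \code{W}; the last
#' window of a chromosome is truncated at the chromosome end.  The default
#' window size is 100 kb, the scale at which local ancestry is assigned.
#'
#' @slot seqlen named numeric vector of chromosome lengths (bp).
#' @slot windowSize integer window width in bp.
#'
#' @exportClass WindowGrid
setClass("WindowGrid",
  representation(seqlen = "numeric", windowSize = "integer")
)

setValidity("WindowGrid", function(object) {
  msg <- character()
  if (is.null(names(object@seqlen)) || any(!nzchar(names(object@seqlen))))
    msg <- c(msg, "seqlen must be a named vector of chromosome lengths")
  if (any(object@seqlen <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@windowSize) != 1L || object@windowSize <= 0L)
    msg <- c(msg, "windowSize must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' PairWindowCounts: windowed pairwise difference counts
#'
#' A \code{RangedSummarizedExperiment} whose rows are the windows of a
#' \code{\link{WindowGrid}} and whose columns are sample pairs.  Two integer
#' assays: \code{k}, the number of sequence differences between the two
#' samples' pseudo-haplotypes in the window, and \code{n}, the number of
#' compared allele-sites (twice the shared covered bp).  \code{colData}
#' carries \code{sampleA}, \code{sampleB} and, when a population map was
#' supplied, \code{popA}, \code{popB}.
#'
#' The per-window ratio \code{k/n} estimates nucleotide diversity for
#' within-population pairs and d_XY for between-population pairs.
#'
#' @exportClass PairWindowCounts
setClass("PairWindowCounts", contains = "RangedSummarizedExperiment")

setValidity("PairWindowCounts", function(object) {
  msg <- character()
  if (!all(c("k", "n") %in% names(assays(object))))
    return("assays 'k' and 'n' required")
  k <- assay(object, "k"); n <- assay(object, "n")
  if (any(k < 0, na.rm = TRUE) || any(k > n, na.rm = TRUE))
    msg <- c(msg, "require 0 <= k <= n in every window")
  if (!all(c("sampleA", "sampleB") %in% colnames(colData(object))))
    msg <- c(msg, "colData must carry sampleA and sampleB")
  if (length(msg)) msg else TRUE
})

#' EmissionParams: binomial success rates of the three ancestry states
#'
#' Expected per-site difference rates between a focal individual and the
#' donor reference panel under each hidden ancestry state: \code{pSrc}
#' (donor ancestry; approximately the within-donor nucleotide diversity),
#' \code{pNat} (native ancestry; approximately the between-species d_XY),
#' and \code{pHet} (heterozygous ancestry; exactly their arithmetic mean).
#'
#' @slot pSrc,pHet,pNat numeric scalars, 0 < pSrc <= pHet <= pNat < 1 with
#'   pHet = (pSrc + pNat)/2.
#'
#' @exportClass EmissionParams
setClass("EmissionParams",
  representation(pSrc = "numeric", pHet = "numeric", pNat = "numeric")
)

setValidity("EmissionParams", function(object) {
  p <- c(object@pSrc, object@pHet, object@pNat)
  if (length(p) != 3L) return("pSrc, pHet, pNat must be scalars")
  if (any(p <= 0) || any(p >= 1)) return("rates must lie strictly in (0, 1)")
  if (!(object@pSrc <= object@pHet && object@pHet <= object@pNat))
    return("require pSrc <= pHet <= pNat")
  if (abs(object@pHet - (object@pSrc + object@pNat) / 2) > 1e-12)
    return("pHet must equal (pSrc + pNat)/2")
  TRUE
})

#' TransitionModel: HMM transition matrix and initial distribution
#'
#' Row-stochastic 3x3 transition matrix over the hidden states in the fixed
#' order (SRC, HET, NAT), plus the initial-state distribution.  The default
#' constructor \code{\link{symmetricTransitions}} builds the symmetric
#' stay/switch parameterization used throughout.
#'
#' @slot trans 3x3 numeric matrix, rows summing to 1.
#' @slot init length-3 numeric initial distribution.
#'
#' @exportClass TransitionModel
setClass("TransitionModel",
  representation(trans = "matrix", init = "numeric")
)

setValidity("TransitionModel", function(object) {
  if (!identical(dim(object@trans), c(3L, 3L)))
    return("trans must be 3x3")
  if (any(object@trans < 0) || any(object@init < 0))
    return("probabilities must be non-negative")
  if (any(abs(rowSums(object@trans) - 1) > 1e-12))
    return("transition rows must sum to 1 (tolerance 1e-12)")
  if (abs(sum(object@init) - 1) > 1e-12)
    return("initial distribution must sum to 1")
  TRUE
})

#' AncestryPath: per-window decoded ancestry of one individual
#'
#' The Viterbi-decoded hidden-state sequence of a focal individual over the
#' windows of a \code{\link{WindowGrid}}.  \code{state} is the reported call
#' (\code{MISSING} where the window had too few compared sites to be
#' informative); \code{decoded} is the raw Viterbi state at every window,
#' including those masked as missing, so that downstream block bridging can
#' reason about gaps.
#'
#' @slot individual sample identifier.
#' @slot windows \code{GRanges} of grid windows, in grid order.
#' @slot state factor with levels SRC, HET, NAT, MISSING.
#' @slot decoded factor with levels SRC, HET, NAT (no MISSING).
#' @slot logLik named numeric, Viterbi path log-likelihood per chromosome.
#'
#' @exportClass AncestryPath
setClass("AncestryPath",
  representation(
    individual = "character",
    windows    = "GRanges",
    state      = "factor",
    decoded    = "factor",
    logLik     = "numeric"
  )
)

setValidity("AncestryPath", function(object) {
  msg <- character()
  if (length(object@state) != length(object@windows))
    msg <- c(msg, "state must have one entry per window")
  if (length(object@decoded) != length(object@windows))
    msg <- c(msg, "decoded must have one entry per window")
  if (!identical(levels(object@state), c("SRC", "HET", "NAT", "MISSING")))
    msg <- c(msg, "state levels must be SRC, HET, NAT, MISSING")
  if (length(msg)) msg else TRUE
})
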