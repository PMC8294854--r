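#' Symmetric transition model
#'
#' Stay/switch parameterization over the hidden states (SRC, HET, NAT):
#' each state is left with probability \code{tau} per window, split equally
#' between the two other states.  The default \code{tau = 1e-3} per 100 kb
#' window encodes the prior expectation that ancestry blocks span tens of
#' Mb.  An optional distinct leave rate for the heterozygous state is
#' available since heterozygous tracts erode faster under recombination.
#' The initial distribution is uniform.
#'
#' @param tau per-window probability of leaving the current state.
#' @param tauHet optional distinct leave rate for HET (defaults to
#'   \code{tau}).
#' @return A \code{\link{TransitionModel-class}}.
#' @export
symmetricTransitions <- function(tau = 1e-3, tauHet = tau) {
  stopifnot(tau > 0, tau < 1, tauHet > 0, tauHet < 1)
  tr <- rbind(c(1 - tau, tau / 2, tau / 2),
              c(tauHet / 2, 1 - tauHet, tauHet / 2),
              c(tau / 2, tau / 2, 1 - tau))
  dimnames(tr) <- list(c("SRC", "HET", "NAT"), c("SRC", "HET", "NAT"))
  new("TransitionModel", trans = tr, init = rep(1 / 3, 3))
}

#' Construct emission parameters
#'
#' @param pSrc expected per-site difference rate to the donor panel under
#'   donor ancestry (within-donor diversity scale).
#' @param pNat rate under native ancestry (between-species d_XY scale).
#' @return An \code{\link{EmissionParams-class}} with
#'   \code{pHet = (pSrc + pNat)/2}.
#' @export
EmissionParams <- function(pSrc, pNat) {
  new("EmissionParams", pSrc = pSrc, pHet = (pSrc + pNat) / 2, pNat = pNat)
}

setMethod("show", "EmissionParams", function(object) {
  cat(sprintf("EmissionParams: pSrc = %.3g, pHet = %.3g, pNat = %.3g\n",
              object@pSrc, object@pHet, object@pNat))
})

#' Estimate emission parameters from pair counts
#'
#' \code{pSrc} is the genome-wide median of per-window rates over
#' within-panel pairs; \code{pNat} the median of per-window rates between
#' native reference samples and the panel; \code{pHet} their mean.  Medians
#' are robust to windows overlapping real introgression in the reference
#' samples.  Estimates are clipped into \code{clip} so binomial
#' log-likelihoods stay finite.
#'
#' @param counts a \code{\link{PairWindowCounts-class}} containing the
#'   within-panel and native-vs-panel pairs.
#' @param panel character vector of donor reference panel samples (>= 2).
#' @param nativeRef character vector of native reference samples (>= 1),
#'   typically the other focal individuals.
#' @param clip numeric length-2 clipping bounds for the rates.
#'
#' @return An \code{\link{EmissionParams-class}}.
#' @export
estimateEmissionParams <- function(counts, panel, nativeRef,
                                   clip = c(1e-6, 1 - 1e-6)) {
  if (length(panel) < 2L)
    stop("insufficient data: donor panel needs at least two samples")
  if (length(nativeRef) < 1L)
    stop("insufficient data: at least one native reference sample needed")
  cd <- colData(counts)
  r <- pairRates(counts)
  inPanel <- cd$sampleA %in% panel & cd$sampleB %in% panel
  cross <- (cd$sampleA %in% nativeRef & cd$sampleB %in% panel) |
           (cd$sampleB %in% nativeRef & cd$sampleA %in% panel)
  if (!any(inPanel)) stop("no within-panel pairs present in counts")
  if (!any(cross)) stop("no native-vs-panel pairs present in counts")
  pSrc <- median(r[, inPanel], na.rm = TRUE)
  pNat <- median(r[, cross], na.rm = TRUE)
  pSrc <- min(max(pSrc, clip[1L]), clip[2L])
  pNat <- min(max(pNat, clip[1L]), clip[2L])
  if (pNat <= pSrc)
    stop("populations not diverged enough for ancestry assignment ",
         sprintf("(pNat = %.3g <= pSrc = %.3g)", pNat, pSrc))
  EmissionParams(pSrc, pNat)
}

#' Binomial emission log-likelihoods
#'
#' log Binomial(k; n, p_state) for each hidden state, columns in the fixed
#' order (SRC, HET, NAT).  A window with \code{n = 0} carries no
#' information: all three log-likelihoods are 0 (probability 1), so the
#' Viterbi recursion passes through it on transitions alone.
#'
#' @param k,n integer vectors of differences and compared sites, 0 <= k <= n.
#' @param params an \code{\link{EmissionParams-class}}.
#' @return numeric matrix, length(k) x 3, columns SRC, HET, NAT.
#' @export
emissionLogLik <- function(k, n, params) {
  if (any(k > n)) stop("k must not exceed n")
  if (any(k < 0 | n < 0)) stop("k and n must be non-negative")
  p <- c(params@pSrc, params@pHet, params@pNat)
  out <- vapply(p, function(pp) dbinom(k, n, pp, log = TRUE),
                numeric(length(k)))
  out <- matrix(out, ncol = 3L, dimnames = list(NULL, c("SRC", "HET", "NAT")))
  out[n == 0L, ] <- 0
  out
}

# Core log-space Viterbi over one chromosome.  emiss: L x 3 log-likelihood
# matrix.  Ties broken toward the higher state index; with columns ordered
# (SRC, HET, NAT) this prefers NAT > HET > SRC, conservative against false
# introgression calls.
.viterbi <- function(emiss, trans) {
  L <- nrow(emiss)
  if (L == 0L) return(list(states = integer(0), logLik = NA_real_))
  lt <- log(trans@trans)
  delta <- matrix(-Inf, L, 3L)
  psi <- matrix(0L, L, 3L)
  delta[1L, ] <- log(trans@init) + emiss[1L, ]
  if (L > 1L) for (t in 2L:L) {
    for (j in 1:3) {
      cand <- delta[t - 1L, ] + lt[, j]
      best <- max(cand)
      psi[t, j] <- max(which(cand == best))
      delta[t, j] <- best + emiss[t, j]
    }
  }
  states <- integer(L)
  states[L] <- max(which(delta[L, ] == max(delta[L, ])))
  if (L > 1L) for (t in (L - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  list(states = states, logLik = max(delta[L, ]))
}

#' Build the observation track of a focal individual
#'
#' Per window, sums \code{k} and \code{n} over all focal-vs-panel pairs; a
#' single binomial is then applied to the aggregate.  Windows with fewer
#' than \code{minSites} compared allele-sites are flagged missing
#' (uninformative).
#'
#' @param counts a \code{PairWindowCounts} containing the focal x panel
#'   pairs.
#' @param focal focal sample identifier.
#' @param panel donor panel sample identifiers.
#' @param minSites minimum aggregate \code{n} for a window to be
#'   informative (default 100).
#' @param maxPanel optional cap on the number of panel samples aggregated,
#'   limiting pseudo-replication from shared panel haplotypes.
#' @return data.frame: chrom, start, end, k, n, missing — one row per grid
#'   window, in grid order.
#' @export
observationTrack <- function(counts, focal, panel, minSites = 100L,
                             maxPanel = Inf) {
  if (is.finite(maxPanel)) panel <- head(panel, maxPanel)
  cd <- colData(counts)
  sel <- (cd$sampleA == focal & cd$sampleB %in% panel) |
         (cd$sampleB == focal & cd$sampleA %in% panel)
  if (!any(sel)) stop("no focal-vs-panel pairs in counts for ", focal)
  k <- rowSums(assay(counts, "k")[, sel, drop = FALSE])
  n <- rowSums(assay(counts, "n")[, sel, drop = FALSE])
  win <- rowRanges(counts)
  data.frame(chrom = as.character(seqnames(win)), start = start(win) - 1L,
             end = end(win), k = k, n = n, missing = n < minSites)
}

#' Log-space Viterbi decoding of an observation track
#'
#' Runs the Viterbi recursion independently per chromosome, entirely in log
#' space.  Missing windows contribute emission log-likelihood 0 for every
#' state, so the decoded path bridges them on transition probabilities
#' alone; the decoded state at such windows is reported (downstream callers
#' may mask it).  Exact log-likelihood ties are broken toward NAT, then
#' HET, then SRC.
#'
#' @param track data.frame as from \code{\link{observationTrack}} (columns
#'   \code{k}, \code{n}; optional \code{chrom} and logical \code{missing}).
#' @param params an \code{\link{EmissionParams-class}}.
#' @param trans a \code{\link{TransitionModel-class}}.
#' @return list: \code{state} (factor SRC/HET/NAT, one per track row) and
#'   \code{logLik} (named numeric, per chromosome).
#' @export
viterbiDecode <- function(track, params, trans = symmetricTransitions()) {
  if (nrow(track) == 0L) {
    warning("empty observation track")
    return(list(state = factor(character(0), c("SRC", "HET", "NAT")),
                logLik = numeric(0)))
  }
  chrom <- if ("chrom" %in% names(track)) track$chrom else
    rep("chr", nrow(track))
  miss <- if ("missing" %in% names(track)) track$missing else
    rep(FALSE, nrow(track))
  emiss <- emissionLogLik(track$k, track$n, params)
  emiss[miss, ] <- 0
  stateInt <- integer(nrow(track))
  ll <- numeric(0)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    v <- .viterbi(emiss[idx, , drop = FALSE], trans)
    stateInt[idx] <- v$states
    ll[chr] <- v$logLik
  }
  list(state = factor(c("SRC", "HET", "NAT")[stateInt],
                      levels = c("SRC", "HET", "NAT")),
       logLik = ll)
}

#' Decode the local ancestry of one focal individual
#'
#' Composes emission-parameter estimation, observation aggregation and
#' per-chromosome Viterbi decoding into an \code{\link{AncestryPath-class}}.
#' Windows with insufficient data are reported as MISSING in \code{state}
#' while the raw decoded state is retained in \code{decoded}.
#'
#' @inheritParams observationTrack
#' @param nativeRef native reference samples used to estimate \code{pNat}
#'   (usually the other focal individuals).
#' @param grid the \code{\link{WindowGrid-class}} the counts were computed
#'   on.
#' @param trans a \code{\link{TransitionModel-class}}.
#' @param params optional precomputed \code{\link{EmissionParams-class}};
#'   estimated from \code{counts} when \code{NULL}.
#' @return An \code{\link{AncestryPath-class}}.
#' @export
decodeIndividual <- function(counts, focal, panel, nativeRef, grid,
                             trans = symmetricTransitions(),
                             minSites = 100L, maxPanel = Inf,
                             params = NULL) {
  .checkSample2(counts, c(focal, panel, nativeRef))
  if (is.null(params))
    params <- estimateEmissionParams(counts, panel,
                                     setdiff(nativeRef, focal))
  track <- observationTrack(counts, focal, panel, minSites, maxPanel)
  dec <- viterbiDecode(track, params, trans)
  st <- as.character(dec$state)
  st[track$missing] <- "MISSING"
  new("AncestryPath", individual = focal, windows = rowRanges(counts),
      state = factor(st, c("SRC", "HET", "NAT", "MISSING")),
      decoded = dec$state, logLik = dec$logLik)
}

.checkSample2 <- function(counts, samples) {
  cd <- colData(counts)
  known <- unique(c(cd$sampleA, cd$sampleB))
  bad <- setdiff(samples, known)
  if (length(bad))
    stop("sample(s) absent from counts: ", paste(bad, collapse = ", "))
}

#' Decode every individual of a focal population
#'
#' Applies \code{\link{decodeIndividual}} to each member of the focal
#' population, using the remaining focal individuals as native reference
#' for that member's emission parameters.
#'
#' @inheritParams decodeIndividual
#' @param focalPop character vector of focal-population samples.
#' @return named list of \code{\link{AncestryPath-class}} objects.
#' @export
decodePopulation <- function(counts, focalPop, panel, grid,
                             trans = symmetricTransitions(),
                             minSites = 100L, maxPanel = Inf) {
  setNames(lapply(focalPop, function(f)
    decodeIndividual(counts, f, panel, setdiff(focalPop, f), grid,
                     trans, minSites, maxPanel)), focalPop)
}

#' @describeIn AncestryPath-class reported per-window states (with MISSING).
#' @param x an \code{AncestryPath}.
#' @export
pathStates <- function(x) x@state

#' @describeIn AncestryPath-class grid windows of the path.
#' @export
pathWindows <- function(x) x@windows

#' @describeIn AncestryPath-class per-chromosome Viterbi log-likelihood.
#' @export
pathLogLik <- function(x) x@logLik

setMethod("show", "AncestryPath", function(object) {
  tab <- table(object@state)
  cat("AncestryPath for", object@individual, "over",
      length(object@windows), "windows\n  ")
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
})
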