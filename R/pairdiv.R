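#' Count windowed pairwise differences for a set of sample pairs
#'
#' For every sample pair and every window of the grid, counts \code{k}, the
#' integer number of sequence differences, and \code{n}, the number of
#' compared allele-sites.  \code{n} is twice the number of base pairs where
#' both samples have coverage in the window: invariant covered positions
#' contribute to the denominator only, as in divergence estimation from
#' assembled RAD loci.  \code{k} follows a fixed pseudo-haplotype pairing:
#' at each site the two unphased alleles of a sample are sorted (0 before
#' 1), first pseudo-haplotypes are compared to first and second to second,
#' and the per-site contribution is the number of mismatching comparisons.
#' For dosages \code{gA}, \code{gB} this equals \code{|gA - gB|}, keeping
#' \code{k} integral so that a binomial emission model on \code{(k, n)} is
#' well formed.  Sites where either sample lacks a genotype call but both
#' are covered count as equal (enter \code{n}, not \code{k}).
#'
#' @param gt a \code{\link{GenotypeTable}}.
#' @param grid a \code{\link{WindowGrid}} covering every chromosome that
#'   carries sites or coverage; a chromosome absent from the grid is a
#'   coordinate error.
#' @param pairs data.frame with columns \code{sampleA}, \code{sampleB};
#'   default all unordered pairs of samples in \code{gt}.
#' @param popmap optional population map (data.frame as returned by
#'   \code{\link{readPopmap}}); populations are attached to \code{colData}.
#'
#' @return A \code{\link{PairWindowCounts-class}} object (windows x pairs).
#' @export
countAllPairs <- function(gt, grid, pairs = NULL, popmap = NULL) {
  samp <- sampleIds(gt)
  if (is.null(pairs)) {
    if (length(samp) < 2L) stop("need at least two samples")
    cmb <- combn(samp, 2L)
    pairs <- data.frame(sampleA = cmb[1L, ], sampleB = cmb[2L, ],
                        stringsAsFactors = FALSE)
  }
  .checkSample(gt, unique(c(pairs$sampleA, pairs$sampleB)))
  win <- gridWindows(grid)

  cov <- sampleCoverage(gt)
  covChrom <- unique(unlist(lapply(cov, function(g) as.character(seqnames(g)))))
  badChrom <- setdiff(unique(c(covChrom,
                               as.character(seqnames(siteRanges(gt))))),
                      names(chromLengths(grid)))
  if (length(badChrom))
    stop("chromosome(s) absent from window grid: ",
         paste(badChrom, collapse = ", "))

  # Disjoint coverage atoms, split at every sample's interval boundaries and
  # at window boundaries, so each atom is wholly in or out of any sample's
  # coverage and lies inside exactly one window.
  allCov <- unlist(cov, use.names = FALSE)
  GenomeInfoDb::seqlevels(allCov) <- GenomeInfoDb::seqlevels(win)
  atoms <- disjoin(c(granges(allCov), granges(win)))
  atoms <- atoms[countOverlaps(atoms, allCov) > 0L]
  hitWin <- findOverlaps(atoms, win, type = "within", select = "first")
  keep <- !is.na(hitWin)
  atoms <- atoms[keep]; hitWin <- hitWin[keep]

  M <- matrix(vapply(cov[samp], function(g)
    IRanges::overlapsAny(atoms, g, type = "within"),
    logical(length(atoms))), nrow = length(atoms), ncol = length(samp))
  Wmat <- sparseMatrix(i = hitWin, j = seq_along(atoms), x = width(atoms),
                       dims = c(length(win), length(atoms)))

  sites <- siteRanges(gt)
  siteWin <- findOverlaps(sites, win, select = "first")
  Smat <- sparseMatrix(i = siteWin, j = seq_along(sites), x = 1,
                       dims = c(length(win), length(sites)))
  G <- genoMatrix(gt)

  npair <- nrow(pairs)
  kOut <- matrix(0L, length(win), npair)
  nOut <- matrix(0L, length(win), npair)
  ai <- match(pairs$sampleA, samp); bi <- match(pairs$sampleB, samp)
  chunk <- 64L
  for (s in seq(1L, npair, by = chunk)) {
    idx <- s:min(s + chunk - 1L, npair)
    pm <- M[, ai[idx], drop = FALSE] & M[, bi[idx], drop = FALSE]
    nOut[, idx] <- as.matrix(2 * (Wmat %*% pm))
    d <- abs(G[, ai[idx], drop = FALSE] - G[, bi[idx], drop = FALSE])
    d[is.na(d)] <- 0L
    kOut[, idx] <- as.matrix(Smat %*% d)
  }
  storage.mode(kOut) <- "integer"; storage.mode(nOut) <- "integer"

  cd <- DataFrame(sampleA = pairs$sampleA, sampleB = pairs$sampleB)
  if (!is.null(popmap)) {
    cd$popA <- popmap$population[match(cd$sampleA, popmap$sample)]
    cd$popB <- popmap$population[match(cd$sampleB, popmap$sample)]
  }
  se <- SummarizedExperiment(assays = list(k = kOut, n = nOut),
                             rowRanges = win, colData = cd)
  colnames(se) <- paste(pairs$sampleA, pairs$sampleB, sep = ":")
  new("PairWindowCounts", se)
}

#' Count windowed differences for one sample pair
#'
#' @param pair length-2 character vector of sample identifiers.
#' @inheritParams countAllPairs
#' @return A single-column \code{\link{PairWindowCounts-class}}.
#' @seealso \code{\link{countAllPairs}} for the batch form and the counting
#'   rules.
#' @export
countPairDifferences <- function(gt, pair, grid) {
  stopifnot(length(pair) == 2L)
  countAllPairs(gt, grid,
                pairs = data.frame(sampleA = pair[1L], sampleB = pair[2L]))
}

#' Per-window rates k/n of a PairWindowCounts
#'
#' @param counts a \code{PairWindowCounts}.
#' @return numeric matrix (windows x pairs); \code{NA} where \code{n = 0}.
#' @export
pairRates <- function(counts) {
  k <- assay(counts, "k"); n <- assay(counts, "n")
  r <- k / n
  r[n == 0L] <- NA_real_
  r
}

.pairPops <- function(counts, popmap = NULL) {
  cd <- colData(counts)
  if (all(c("popA", "popB") %in% colnames(cd)))
    return(data.frame(popA = cd$popA, popB = cd$popB))
  if (is.null(popmap))
    stop("counts carry no populations; supply a popmap")
  data.frame(popA = popmap$population[match(cd$sampleA, popmap$sample)],
             popB = popmap$population[match(cd$sampleB, popmap$sample)])
}

#' Windowed nucleotide diversity and divergence
#'
#' Per window, pi of a population is the mean over its within-population
#' pairs of \code{k/n} (pairs with \code{n = 0} excluded); d_XY of a
#' population pair is the mean over between-population pairs.  Genome-wide
#' values are coverage-weighted: each pair contributes its whole-genome
#' ratio sum(k)/sum(n), and pairs are averaged.
#'
#' @param counts a \code{\link{PairWindowCounts-class}} covering the needed
#'   pairs.
#' @param popmap population map; may be omitted when \code{counts} already
#'   carries populations.
#' @param populations optional character vector; restricts (and validates)
#'   which populations pi is computed for.  Requesting a population with
#'   fewer than two samples is an error.
#'
#' @return list with elements \code{windows} (data.frame: chrom, start, end,
#'   popA, popB, stat = "pi" or "dxy", value) and \code{genomeWide}
#'   (data.frame: popA, popB, stat, value).
#' @export
windowedPiDxy <- function(counts, popmap = NULL, populations = NULL) {
  pp <- .pairPops(counts, popmap)
  win <- rowRanges(counts)
  r <- pairRates(counts)
  k <- assay(counts, "k"); n <- assay(counts, "n")

  within <- pp$popA == pp$popB
  if (!is.null(populations)) {
    lacking <- setdiff(populations, pp$popA[within])
    if (length(lacking))
      stop("insufficient data: population(s) with fewer than two samples: ",
           paste(lacking, collapse = ", "))
  }

  groupKey <- ifelse(within, pp$popA,
                     paste(pmin(pp$popA, pp$popB), pmax(pp$popA, pp$popB),
                           sep = "\r"))
  res <- list(); gw <- list()
  for (key in unique(groupKey)) {
    sel <- groupKey == key
    isPi <- within[sel][1L]
    popA <- if (isPi) key else strsplit(key, "\r")[[1L]][1L]
    popB <- if (isPi) key else strsplit(key, "\r")[[1L]][2L]
    if (!is.null(populations) && isPi && !popA %in% populations) next
    val <- rowMeans(r[, sel, drop = FALSE], na.rm = TRUE)
    val[is.nan(val)] <- NA_real_
    res[[key]] <- data.frame(
      chrom = as.character(seqnames(win)), start = start(win) - 1L,
      end = end(win), popA = popA, popB = popB,
      stat = if (isPi) "pi" else "dxy", value = val)
    perPair <- colSums(k[, sel, drop = FALSE]) / colSums(n[, sel, drop = FALSE])
    gw[[key]] <- data.frame(popA = popA, popB = popB,
                            stat = if (isPi) "pi" else "dxy",
                            value = mean(perPair, na.rm = TRUE))
  }
  list(windows = do.call(rbind, c(res, list(make.row.names = FALSE))),
       genomeWide = do.call(rbind, c(gw, list(make.row.names = FALSE))))
}

#' Genome-wide pairwise distance matrix
#'
#' Entry (i, j) is the whole-genome per-site difference rate
#' sum(k)/sum(n) over all windows for pair (i, j); the diagonal is 0.  A
#' pair with no compared sites anywhere is \code{NA}, never 0.
#'
#' @param counts a \code{\link{PairWindowCounts-class}} holding every pair
#'   of the samples involved.
#' @return symmetric numeric matrix with sample names on both dimensions.
#' @export
distanceMatrix <- function(counts) {
  cd <- colData(counts)
  samp <- unique(c(cd$sampleA, cd$sampleB))
  D <- matrix(NA_real_, length(samp), length(samp),
              dimnames = list(samp, samp))
  diag(D) <- 0
  K <- colSums(assay(counts, "k")); N <- colSums(assay(counts, "n"))
  rate <- ifelse(N > 0L, K / N, NA_real_)
  for (j in seq_len(ncol(counts))) {
    D[cd$sampleA[j], cd$sampleB[j]] <- rate[j]
    D[cd$sampleB[j], cd$sampleA[j]] <- rate[j]
  }
  D
}

#' Write windowed pair counts as TSV
#'
#' Long-format table \code{chrom, window_start, window_end, sampleA,
#' sampleB, k, n, rate} with BED-style 0-based half-open window coordinates.
#'
#' @param counts a \code{PairWindowCounts}.
#' @param path output file.
#' @export
writePairCounts <- function(counts, path) {
  win <- rowRanges(counts); cd <- colData(counts)
  r <- pairRates(counts)
  long <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
    data.frame(chrom = as.character(seqnames(win)),
               window_start = start(win) - 1L, window_end = end(win),
               sampleA = cd$sampleA[j], sampleB = cd$sampleB[j],
               k = assay(counts, "k")[, j], n = assay(counts, "n")[, j],
               rate = r[, j])
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
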