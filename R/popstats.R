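#' Diversity summaries for a population sample
#'
#' Computes the number of segregating sites S, Watterson's theta
#' (theta_W = S / a1, a1 = sum_{i=1}^{n-1} 1/i), nucleotide diversity pi
#' (sum over sites of 2 j (m - j) / (m (m - 1)) with m the called
#' chromosomes and j the alternate-allele count at the site), observed
#' heterozygosity H (fraction of heterozygous calls among called
#' genotypes), and Tajima's D via the textbook variance constants
#' (a1, a2, b1, b2, c1, c2, e1, e2) at the nominal sample size
#' n = 2 x samples.  With no segregating sites Tajima's D is undefined and
#' returned as \code{NA} (never silently 0).
#'
#' @param gt a \code{\link{GenotypeTable}}.
#' @param samples population members (>= 2).
#' @param L optional covered length in bp; when given, per-site
#'   \code{thetaW_bp} and \code{pi_bp} are included.
#' @return list: S, thetaW, pi, H, tajimaD, n (haplotypes), and per-bp
#'   values when \code{L} is supplied.
#' @export
siteStats <- function(gt, samples = sampleIds(gt), L = NULL) {
  .checkSample(gt, samples)
  if (length(samples) < 2L)
    stop("need at least two samples (four haplotypes)")
  g <- genoMatrix(gt)[, samples, drop = FALSE]
  .siteStatsMatrix(g, L)
}

# g: dosage matrix sites x samples (NA = missing)
.siteStatsMatrix <- function(g, L = NULL) {
  called <- !is.na(g)
  m <- 2L * rowSums(called)
  j <- rowSums(g, na.rm = TRUE)
  seg <- j > 0L & j < m & m >= 2L
  S <- sum(seg)
  n <- 2L * ncol(g)
  a1 <- sum(1 / seq_len(n - 1L))
  thetaW <- S / a1
  ok <- m >= 2L
  pi <- sum(2 * j[ok] * (m[ok] - j[ok]) / (m[ok] * (m[ok] - 1)))
  H <- sum(g == 1L, na.rm = TRUE) / sum(called)
  D <- .tajimaD(S, pi, n)
  out <- list(S = S, thetaW = thetaW, pi = pi, H = H, tajimaD = D, n = n)
  if (!is.null(L)) {
    out$thetaW_bp <- thetaW / L
    out$pi_bp <- pi / L
  }
  out
}

.tajimaD <- function(S, pi, n) {
  if (S == 0L) return(NA_real_)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed Tajima's D, reported as mean +/- sd across windows
#'
#' @inheritParams siteStats
#' @param grid a \code{\link{WindowGrid-class}}.
#' @param mask optional \code{GRanges}; sites inside are excluded (e.g.
#'   inferred introgression tracts, which inflate rare variants).
#' @param minSeg minimum segregating sites for a window to contribute
#'   (default 3).
#' @return list: mean, sd, perWindow (data.frame chrom/start/end/S/D).
#' @export
tajimaDWindowed <- function(gt, samples, grid, mask = NULL, minSeg = 3L) {
  .checkSample(gt, samples)
  g <- genoMatrix(gt)[, samples, drop = FALSE]
  sites <- siteRanges(gt)
  if (!is.null(mask) && length(mask)) {
    drop <- IRanges::overlapsAny(sites, mask)
    g <- g[!drop, , drop = FALSE]; sites <- sites[!drop]
  }
  win <- gridWindows(grid)
  hit <- findOverlaps(sites, win, select = "first")
  perWin <- lapply(seq_along(win), function(w) {
    gs <- g[which(hit == w), , drop = FALSE]
    st <- .siteStatsMatrix(gs)
    data.frame(chrom = as.character(seqnames(win))[w],
               start = start(win)[w] - 1L, end = end(win)[w],
               S = st$S, D = st$tajimaD)
  })
  df <- do.call(rbind, perWin)
  use <- !is.na(df$D) & df$S >= minSeg
  list(mean = mean(df$D[use]), sd = sd(df$D[use]), perWindow = df)
}

#' Folded site-frequency spectrum with projection and masking
#'
#' Sites inside the mask are removed first.  With projection to \code{nProj}
#' chromosomes, a site with \code{m >= nProj} called chromosomes and
#' \code{j} alternate alleles contributes its hypergeometric expectation
#' across draws of \code{nProj} chromosomes: weight P(i alternate alleles in
#' the draw) to folded class min(i, nProj - i); a site with \code{m < nProj}
#' is dropped.  This expected-projection rule is deterministic and
#' conserves per-site mass (each retained site contributes total weight 1).
#' Without projection only fully-called sites contribute, each adding 1 to
#' its minor-allele class.
#'
#' @inheritParams siteStats
#' @param nProj projection size in chromosomes (even, <= 2 x samples);
#'   \code{NULL} for no projection.
#' @param mask optional \code{GRanges} of intervals to exclude.
#' @return object of class \code{radmix_sfs}: \code{counts} (named, classes
#'   0..floor(n/2)), \code{n} (chromosomes), \code{masked}, \code{dropped}.
#' @export
foldedSFS <- function(gt, samples = sampleIds(gt), nProj = NULL, mask = NULL) {
  .checkSample(gt, samples)
  g <- genoMatrix(gt)[, samples, drop = FALSE]
  sites <- siteRanges(gt)
  nMasked <- 0L
  if (!is.null(mask) && length(mask)) {
    drop <- IRanges::overlapsAny(sites, mask)
    nMasked <- sum(drop)
    g <- g[!drop, , drop = FALSE]
  }
  nFull <- 2L * length(samples)
  m <- 2L * rowSums(!is.na(g))
  j <- rowSums(g, na.rm = TRUE)
  if (is.null(nProj)) {
    keep <- m == nFull
    counts <- numeric(floor(nFull / 2) + 1L)
    jm <- pmin(j[keep], nFull - j[keep])
    tab <- table(factor(jm, levels = 0:floor(nFull / 2)))
    counts <- as.numeric(tab)
    nOut <- nFull
    dropped <- sum(!keep)
  } else {
    if (nProj %% 2L != 0L) stop("projection size must be even")
    if (nProj > nFull) stop("projection size exceeds available chromosomes")
    keep <- m >= nProj
    dropped <- sum(!keep)
    counts <- numeric(floor(nProj / 2) + 1L)
    if (!any(keep) && dropped > 0L)
      warning("no site had enough called chromosomes for the projection")
    for (s in which(keep)) {
      w <- dhyper(0:nProj, j[s], m[s] - j[s], nProj)
      cls <- pmin(0:nProj, nProj - (0:nProj))
      for (i in seq_along(w)) counts[cls[i] + 1L] <- counts[cls[i] + 1L] + w[i]
    }
    nOut <- nProj
  }
  names(counts) <- 0:floor(nOut / 2)
  structure(list(counts = counts, n = nOut, masked = nMasked,
                 dropped = dropped), class = "radmix_sfs")
}

#' @export
print.radmix_sfs <- function(x, ...) {
  cat("Folded SFS, projection", x$n, "chromosomes;",
      x$masked, "sites masked,", x$dropped, "dropped\n")
  print(round(x$counts, 3))
  invisible(x)
}

#' Nonparametric bootstrap of a site-frequency spectrum
#'
#' Resamples sites across SFS bins by a multinomial with the observed bin
#' proportions, preserving the (rounded) total; deterministic given the
#' seed.
#'
#' @param sfs a \code{radmix_sfs} from \code{\link{foldedSFS}}.
#' @param reps number of replicates.
#' @param seed RNG seed (required, for reproducibility).
#' @return list of \code{radmix_sfs} replicates.
#' @export
bootstrapSFS <- function(sfs, reps, seed) {
  tot <- round(sum(sfs$counts))
  if (tot <= 0) stop("empty SFS cannot be bootstrapped")
  set.seed(seed)
  draws <- rmultinom(reps, size = tot, prob = sfs$counts / sum(sfs$counts))
  lapply(seq_len(reps), function(r) {
    out <- sfs
    out$counts <- setNames(as.numeric(draws[, r]), names(sfs$counts))
    out
  })
}

#' Write an SFS in dadi-style frequency-spectrum text format
#'
#' Three lines: a header \code{"<n+1> folded"}, the \code{n+1} per-class
#' values (upper folded half zero), and a mask line (1 = masked entry;
#' class 0 and the redundant upper half are masked).
#'
#' @param sfs a \code{radmix_sfs}.
#' @param path output file.
#' @export
writeSFS <- function(sfs, path) {
  n <- sfs$n
  full <- numeric(n + 1L)
  full[seq_along(sfs$counts)] <- sfs$counts
  maskLine <- as.integer(seq(0L, n) > floor(n / 2) | seq(0L, n) == 0L)
  writeLines(c(paste(n + 1L, "folded"),
               paste(format(full, trim = TRUE), collapse = " "),
               paste(maskLine, collapse = " ")), path)
  invisible(path)
}

#' Patterson's ABBA-BABA D statistic with block bootstrap
#'
#' Frequency-weighted four-taxon D over biallelic sites: with derived-allele
#' frequencies p1, p2, p3, p4 (p4 the outgroup),
#' ABBA = sum (1-p1) p2 p3 (1-p4) and BABA = sum p1 (1-p2) p3 (1-p4);
#' D = (ABBA - BABA) / (ABBA + BABA).  The outgroup's major allele is taken
#' as ancestral; sites polymorphic in the outgroup, or uncalled in any
#' taxon, are dropped.  Uncertainty comes from a block bootstrap: sites are
#' grouped into genomic blocks of \code{blockSize} bp, blocks are resampled
#' with replacement, and the one-sided p-value is the fraction of
#' replicates on the opposite side of zero from the observed D.
#'
#' @param gt a \code{\link{GenotypeTable}}.
#' @param P1,P2,P3,outgroup character vectors of samples for each taxon
#'   (P3 is the candidate donor; gene flow P3 -> P2 drives D > 0).
#' @param blockSize bootstrap block length in bp (default 1 Mb).
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list of class \code{radmix_dstat}: D, sd, p, nABBA, nBABA,
#'   nSites, reps.
#' @export
pattersonD <- function(gt, P1, P2, P3, outgroup, blockSize = 1e6,
                       reps = 1000L, seed = 1L) {
  .checkSample(gt, c(P1, P2, P3, outgroup))
  g <- genoMatrix(gt)
  freq <- function(ss) {
    sub <- g[, ss, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  }
  fO <- freq(outgroup)
  # outgroup major allele = ancestral; polymorphic or uncalled outgroup drops
  usable <- !is.na(fO) & (fO == 0 | fO == 1)
  derivedIsAlt <- fO == 0
  f1 <- freq(P1); f2 <- freq(P2); f3 <- freq(P3)
  usable <- usable & !is.na(f1) & !is.na(f2) & !is.na(f3)
  flip <- function(f) ifelse(derivedIsAlt, f, 1 - f)
  p1 <- flip(f1)[usable]; p2 <- flip(f2)[usable]; p3 <- flip(f3)[usable]
  p4 <- rep(0, sum(usable))
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  tot <- sum(abba) + sum(baba)
  if (tot == 0)
    return(structure(list(D = NA_real_, sd = NA_real_, p = NA_real_,
                          nABBA = 0, nBABA = 0, nSites = sum(usable),
                          reps = 0L), class = "radmix_dstat"))
  D <- (sum(abba) - sum(baba)) / tot

  sites <- siteRanges(gt)[usable]
  blk <- paste(as.character(seqnames(sites)),
               (start(sites) - 1L) %/% blockSize)
  aBlk <- tapply(abba, blk, sum); bBlk <- tapply(baba, blk, sum)
  nb <- length(aBlk)
  set.seed(seed)
  Dboot <- vapply(seq_len(reps), function(r) {
    pick <- sample.int(nb, nb, replace = TRUE)
    sa <- sum(aBlk[pick]); sb <- sum(bBlk[pick])
    if (sa + sb == 0) return(NA_real_)
    (sa - sb) / (sa + sb)
  }, 0)
  pval <- if (D > 0) mean(Dboot <= 0, na.rm = TRUE)
          else if (D < 0) mean(Dboot >= 0, na.rm = TRUE) else 1
  structure(list(D = D, sd = sd(Dboot, na.rm = TRUE),
                 p = max(pval, 1 / reps), nABBA = sum(abba),
                 nBABA = sum(baba), nSites = sum(usable), reps = reps),
            class = "radmix_dstat")
}

#' @export
print.radmix_dstat <- function(x, ...) {
  cat(sprintf("Patterson's D = %.3f (s.d. = %.3f; bootstrapped p %s %.3g)\n",
              x$D, x$sd, if (x$p <= 1 / x$reps) "<" else "=", x$p))
  cat(sprintf("  ABBA = %.2f, BABA = %.2f over %d sites\n",
              x$nABBA, x$nBABA, x$nSites))
  invisible(x)
}

#' Rescale coalescent-unit demographic estimates to absolute units
#'
#' A diffusion-based demographic fit reports the population-scaled mutation
#' parameter theta and parameters in units of the reference size N_ref:
#' relative sizes nu and times in units of 2 N_ref generations.  With a
#' per-site per-generation mutation rate \code{mu} and \code{L} bp of
#' queried sequence, N_ref = theta / (4 mu L); absolute sizes are
#' nu * N_ref and times 2 * N_ref * T generations.
#'
#' @param theta population-scaled mutation parameter.
#' @param mu mutation rate per bp per generation.
#' @param L queried sequence length in bp.
#' @param nu named or unnamed numeric vector of relative sizes (optional).
#' @param Tcoal numeric vector of times in coalescent units (optional).
#' @param F inbreeding coefficient, passed through unchanged (optional).
#' @return list: Nref, N (absolute sizes), T_gen (times in generations), F.
#' @export
rescaleDemography <- function(theta, mu, L, nu = NULL, Tcoal = NULL, F = NULL) {
  if (theta <= 0 || mu <= 0 || L <= 0)
    stop("theta, mu and L must be positive")
  if (!is.null(F) && (F < 0 || F > 1)) stop("F must lie in [0, 1]")
  Nref <- theta / (4 * mu * L)
  list(Nref = Nref,
       N = if (is.null(nu)) NULL else nu * Nref,
       T_gen = if (is.null(Tcoal)) NULL else 2 * Nref * Tcoal,
       F = F)
}

#' Total bottleneck duration from already-rescaled epoch times
#'
#' For a two-epoch bottleneck model whose epoch times are already in
#' generations, the total time back to the start of the bottleneck is their
#' sum.
#'
#' @param tB,tF epoch durations in generations (positive).
#' @return total generations.
#' @export
bottleneckTotalTime <- function(tB, tF) {
  if (any(c(tB, tF) <= 0)) stop("epoch times must be positive")
  tB + tF
}
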