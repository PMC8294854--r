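# Small in-code fixtures shared across test files.

# A GenotypeTable on one or more chromosomes with full coverage everywhere.
makeGT <- function(geno, pos, chrom = "c1", chromLen = max(pos) + 100,
                   samples = colnames(geno)) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                  REF = "A", ALT = "T")
  cov <- GenomicRanges::GRanges(unique(chrom),
                                IRanges::IRanges(1, chromLen))
  GenotypeTable(geno, sites, cov, samples = samples)
}

# An AncestryPath from a state vector on a given grid.
makePath <- function(states, grid, individual = "ind1") {
  win <- gridWindows(grid)
  stopifnot(length(states) == length(win))
  dec <- ifelse(states == "MISSING", "NAT", states)
  new("AncestryPath", individual = individual, windows = win,
      state = factor(states, c("SRC", "HET", "NAT", "MISSING")),
      decoded = factor(dec, c("SRC", "HET", "NAT")),
      logLik = c(chr = 0))
}

# Brute-force per-site difference count under the sorted pseudo-haplotype
# pairing rule; the oracle against which vectorized counting is checked.
oracleK <- function(gA, gB) {
  tot <- 0L
  for (i in seq_along(gA)) {
    a <- gA[i]; b <- gB[i]
    if (is.na(a) || is.na(b)) next
    hapA <- c(if (a >= 2) 1L else 0L, if (a >= 1) 1L else 0L)
    hapB <- c(if (b >= 2) 1L else 0L, if (b >= 1) 1L else 0L)
    tot <- tot + sum(sort(hapA) != sort(hapB))
  }
  tot
}

# Exhaustive-path Viterbi oracle: max over all 3^L state paths.
oracleViterbi <- function(emiss, trans) {
  L <- nrow(emiss)
  paths <- as.matrix(expand.grid(rep(list(1:3), L)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(trans@init[s[1]]) + emiss[1, s[1]]
    if (L > 1) for (t in 2:L)
      lp <- lp + log(trans@trans[s[t - 1], s[t]]) + emiss[t, s[t]]
    if (lp > best) best <- lp
  }
  unname(best)
}

# All-pairs brute-force pi and textbook Tajima's D for a complete dosage
# matrix (no missing data), enumerating the 2N pseudo-haplotypes directly.
oracleStats <- function(g) {
  haps <- do.call(cbind, lapply(seq_len(ncol(g)), function(s)
    cbind(as.integer(g[, s] >= 2), as.integer(g[, s] >= 1))))
  n <- ncol(haps)
  pi <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pi <- pi + sum(haps[, i] != haps[, j])
  pi <- pi / choose(n, 2)
  S <- sum(apply(haps, 1, function(r) length(unique(r)) > 1))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0) NA_real_ else
    (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, thetaW = S / a1, pi = pi, D = D)
}
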