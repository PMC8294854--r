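#' Configuration for the synthetic ddRAD-like generator
#'
#' Describes a two-species diploid panel: a donor reference population and
#' a native focal population, diverged at per-site rate \code{d} with
#' within-population diversities \code{piSrc} (donor) and \code{piNat}
#' (native), genotyped over a sparse set of short RAD loci with per-sample
#' locus dropout, with optional planted donor-ancestry tracts in focal
#' individuals and a causal locus driving a dominant binary phenotype.
#'
#' Defaults mirror the study system the package targets: 12 chromosomes,
#' donor diversity 4.5e-4, native diversity 2.3e-4, between-species
#' divergence 2.3e-3, ~300 bp loci at ~310 loci/Mb with 80% per-sample
#' retention.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param nDonor,nFocal diploid sample counts per population.
#' @param piSrc,piNat within-population per-site diversities.
#' @param d between-species per-site divergence; must exceed both
#'   diversities.
#' @param tracts named list (by focal individual) of data.frames with
#'   columns \code{chrom}, \code{start} (1-based bp), \code{length} (bp),
#'   \code{zygosity} ("het" = one haplotype replaced, "hom" = both).
#' @param causalLocus \code{GRanges} of length 1, or \code{NULL}; an
#'   individual whose tract (any zygosity) overlaps it is phenotype 1.
#' @param locusLength,lociPerMb,retention RAD coverage model: locus width
#'   (bp), locus density, and per-sample per-locus retention probability.
#' @param seed mandatory RNG seed.
#' @return list of class \code{radmix_simconfig}.
#' @export
simConfig <- function(chromLengths = setNames(rep(5e6, 12),
                                              sprintf("chr%02d", 1:12)),
                      nDonor = 6L, nFocal = 6L,
                      piSrc = 4.5e-4, piNat = 2.3e-4, d = 2.3e-3,
                      tracts = list(), causalLocus = NULL,
                      locusLength = 300L, lociPerMb = 310,
                      retention = 0.8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!(piSrc > 0 && piNat > 0 && piSrc < d && piNat < d && d < 1))
    stop("require 0 < piSrc, piNat < d < 1")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  if (!is.null(causalLocus)) {
    chr <- as.character(seqnames(causalLocus))
    if (!chr %in% names(chromLengths) ||
        end(causalLocus) > chromLengths[[chr]])
      stop("causal locus outside configured chromosomes")
  }
  for (ind in names(tracts)) {
    tr <- tracts[[ind]]
    bad <- !tr$chrom %in% names(chromLengths) |
      tr$start + tr$length - 1 > chromLengths[tr$chrom]
    if (any(bad)) stop("tract outside chromosome bounds for ", ind)
    if (!all(tr$zygosity %in% c("het", "hom")))
      stop("tract zygosity must be 'het' or 'hom'")
  }
  structure(list(chromLengths = chromLengths, nDonor = as.integer(nDonor),
                 nFocal = as.integer(nFocal), piSrc = piSrc, piNat = piNat,
                 d = d, tracts = tracts, causalLocus = causalLocus,
                 locusLength = as.integer(locusLength),
                 lociPerMb = lociPerMb, retention = retention,
                 seed = as.integer(seed)),
            class = "radmix_simconfig")
}

#' Simulate a two-species diploid genotype panel with planted donor tracts
#'
#' Hierarchical mutation model: a root sequence receives species-ancestor
#' mutations on each of the two species branches at per-site rate
#' (d - (piSrc + piNat)/2) / 2, then every haplotype receives private
#' mutations at rate pi_pop / 2.  In expectation a within-population pair
#' then differs at rate pi_pop per site and a between-species pair at rate
#' d.  Donor tracts replace the designated focal haplotype segment with a
#' freshly drawn donor haplotype (donor species-branch mutations plus new
#' private mutations at the donor rate).  Mutations are placed by Poisson
#' draws on integer positions, without replacement (no recurrent
#' mutation), and only within the RAD locus set — positions outside any
#' locus are never observed by any sample, so nothing is lost by omitting
#' them.  Coverage is the locus set thinned per sample by the retention
#' probability; genotypes at dropped loci are missing.  The phenotype is
#' 1 for focal individuals whose tract overlaps the causal locus
#' (dominant coding).  Fully reproducible from the seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list of class \code{radmix_sim}: \code{gt}
#'   (\code{\link{GenotypeTable}}), \code{truth} (list: \code{tracts}
#'   \code{GRanges} with individual/zygosity, \code{phenotypes} named 0/1
#'   vector over focal individuals), \code{popmap} (data.frame),
#'   \code{grid} (\code{\link{WindowGrid-class}} at 100 kb), \code{config}.
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "radmix_simconfig"))
  set.seed(config$seed)
  donors <- sprintf("DON_%02d", seq_len(config$nDonor))
  focals <- sprintf("NAT_%02d", seq_len(config$nFocal))
  samples <- c(donors, focals)
  lw <- config$locusLength
  rateAnc <- (config$d - (config$piSrc + config$piNat) / 2) / 2

  sitesL <- list(); genoL <- list()
  covKeepL <- list(); lociL <- list()
  for (chr in names(config$chromLengths)) {
    L <- config$chromLengths[[chr]]
    slots <- L %/% lw
    nloci <- min(max(1L, round(config$lociPerMb * L / 1e6)), slots)
    lstart <- sort(sample.int(slots, nloci) - 1L) * lw + 1L
    cpos <- rep(lstart, each = lw) + rep.int(seq_len(lw) - 1L, nloci)
    Ncov <- length(cpos)

    nHapD <- 2L * config$nDonor; nHapF <- 2L * config$nFocal
    cnt <- c(rpois(2L, rateAnc * Ncov),
             rpois(nHapD, config$piSrc / 2 * Ncov),
             rpois(nHapF, config$piNat / 2 * Ncov))
    tot <- sum(cnt)
    drawIdx <- sample.int(Ncov, tot)
    used <- logical(Ncov); used[drawIdx] <- TRUE
    pos <- cpos[drawIdx]
    grp <- rep.int(seq_along(cnt), cnt)
    posBy <- split(pos, factor(grp, levels = seq_along(cnt)))
    donAnc <- posBy[[1L]]; natAnc <- posBy[[2L]]
    privD <- posBy[2L + seq_len(nHapD)]
    privF <- posBy[2L + nHapD + seq_len(nHapF)]

    # haplotype position sets
    hapSets <- vector("list", 2L * length(samples))
    for (s in seq_len(config$nDonor)) {
      hapSets[[2L * s - 1L]] <- c(donAnc, privD[[2L * s - 1L]])
      hapSets[[2L * s]] <- c(donAnc, privD[[2L * s]])
    }
    for (f in seq_len(config$nFocal)) {
      ind <- focals[f]
      base1 <- c(natAnc, privF[[2L * f - 1L]])
      base2 <- c(natAnc, privF[[2L * f]])
      tr <- config$tracts[[ind]]
      if (!is.null(tr)) for (ti in which(tr$chrom == chr)) {
        s0 <- tr$start[ti]; e0 <- tr$start[ti] + tr$length[ti] - 1
        haps <- if (tr$zygosity[ti] == "hom") 1:2 else 1L
        donIn <- donAnc[donAnc >= s0 & donAnc <= e0]
        for (h in haps) {
          candIdx <- which(!used & cpos >= s0 & cpos <= e0)
          nPriv <- min(rpois(1L, config$piSrc / 2 * length(candIdx)),
                       length(candIdx))
          tp <- if (nPriv > 0L) {
            pick <- candIdx[sample.int(length(candIdx), nPriv)]
            used[pick] <- TRUE
            cpos[pick]
          } else integer(0)
          if (h == 1L) {
            base1 <- c(base1[!(base1 >= s0 & base1 <= e0)], donIn, tp)
          } else {
            base2 <- c(base2[!(base2 >= s0 & base2 <= e0)], donIn, tp)
          }
        }
      }
      di <- config$nDonor + f
      hapSets[[2L * di - 1L]] <- base1
      hapSets[[2L * di]] <- base2
    }

    sitePos <- sort(unique(unlist(hapSets)))
    dos <- matrix(0L, length(sitePos), length(samples))
    for (s in seq_along(samples)) {
      i1 <- match(hapSets[[2L * s - 1L]], sitePos)
      i2 <- match(hapSets[[2L * s]], sitePos)
      dos[i1, s] <- dos[i1, s] + 1L
      dos[i2, s] <- dos[i2, s] + 1L
    }

    # per-sample locus dropout; genotypes at dropped loci become missing
    keep <- matrix(runif(nloci * length(samples)) < config$retention,
                   nloci, length(samples))
    siteLocus <- findInterval(sitePos, lstart)
    for (s in seq_along(samples))
      dos[!keep[siteLocus, s], s] <- NA_integer_
    polymorphic <- rowSums(dos, na.rm = TRUE) > 0L
    sitePos <- sitePos[polymorphic]
    dos <- dos[polymorphic, , drop = FALSE]

    chrFac <- function(n) factor(rep(chr, n),
                                 levels = names(config$chromLengths))
    sitesL[[chr]] <- GRanges(chrFac(length(sitePos)),
                             IRanges(sitePos, width = 1),
                             REF = "A", ALT = "T")
    genoL[[chr]] <- dos
    covKeepL[[chr]] <- keep
    lociL[[chr]] <- GRanges(chrFac(nloci), IRanges(lstart, width = lw))
  }

  sites <- do.call(c, unname(sitesL))
  geno <- do.call(rbind, genoL)
  colnames(geno) <- samples
  cov <- GRangesList(lapply(setNames(seq_along(samples), samples),
    function(s) {
      do.call(c, unname(lapply(names(lociL), function(chr)
        lociL[[chr]][covKeepL[[chr]][, s]])))
    }))
  gt <- GenotypeTable(geno, sites, cov, samples = samples)

  trL <- lapply(names(config$tracts), function(ind) {
    tr <- config$tracts[[ind]]
    GRanges(tr$chrom, IRanges(tr$start, width = tr$length),
            individual = ind, zygosity = tr$zygosity)
  })
  tracts <- if (length(trL)) do.call(c, trL) else
    GRanges(individual = character(0), zygosity = character(0))
  phen <- setNames(integer(length(focals)), focals)
  if (!is.null(config$causalLocus) && length(tracts))
    phen[unique(tracts$individual[
      IRanges::overlapsAny(tracts, config$causalLocus)])] <- 1L
  popmap <- data.frame(
    sample = samples,
    population = c(rep("DON", config$nDonor), rep("NAT", config$nFocal)),
    species = c(rep("donor_sp", config$nDonor),
                rep("native_sp", config$nFocal)))
  structure(list(gt = gt, truth = list(tracts = tracts, phenotypes = phen),
                 popmap = popmap,
                 grid = WindowGrid(config$chromLengths, 1e5),
                 config = config),
            class = "radmix_sim")
}

#' Write a simulated dataset to standard files
#'
#' Writes a bgzipped VCF of genotypes (via \pkg{vcfR}), a combined
#' 4-column coverage BED (sample in the name field), a truth-tract BED, a
#' phenotype TSV, a popmap TSV, and a key-value config echo recording the
#' seed.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- sim$gt
  sites <- siteRanges(gt)
  g <- genoMatrix(gt)
  gtChar <- matrix("./.", nrow(g), ncol(g), dimnames = dimnames(g))
  gtChar[!is.na(g) & g == 0L] <- "0/0"
  gtChar[!is.na(g) & g == 1L] <- "0/1"
  gtChar[!is.na(g) & g == 2L] <- "1/1"
  fix <- cbind(CHROM = as.character(seqnames(sites)),
               POS = as.character(start(sites)),
               ID = ".", REF = sites$REF, ALT = sites$ALT,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    paste0("##source=radmix_simulateDataset_seed",
                           sim$config$seed)),
           fix = fix,
           gt = cbind(FORMAT = "GT", gtChar))
  paths <- c(vcf = file.path(dir, "genotypes.vcf.gz"),
             coverage = file.path(dir, "coverage.bed"),
             truth = file.path(dir, "truth_tracts.bed"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             popmap = file.path(dir, "popmap.tsv"),
             config = file.path(dir, "config.txt"))
  vcfR::write.vcf(v, file = paths["vcf"])
  covAll <- unlist(sampleCoverage(gt))
  write.table(data.frame(as.character(seqnames(covAll)),
                         start(covAll) - 1L, end(covAll), names(covAll)),
              paths["coverage"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tr <- sim$truth$tracts
  write.table(data.frame(as.character(seqnames(tr)), start(tr) - 1L,
                         end(tr), tr$individual, tr$zygosity),
              paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(sim$truth$phenotypes),
                         sim$truth$phenotypes),
              paths["phenotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$popmap, paths["popmap"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cfg <- sim$config
  scal <- vapply(cfg, function(x) is.atomic(x) && length(x) == 1L, TRUE)
  writeLines(paste0(names(cfg)[scal], "=",
                    vapply(cfg[scal], as.character, "")), paths["config"])
  invisible(paths)
}

#' Window-level recovery of planted tracts
#'
#' Discretizes the truth tracts onto the grid (a window counts as
#' introgressed when at least \code{minOverlap} of it is covered by a
#' tract of the individual) and compares against the decoded paths: a
#' window predicted SRC or HET is an introgression call.  Windows reported
#' MISSING are excluded from the confusion matrix.  Per planted tract, the
#' offset between tract boundaries and the span of overlapping predicted
#' blocks is reported in windows.
#'
#' @param truth truth list from \code{\link{simulateDataset}} (or a
#'   \code{GRanges} of tracts with \code{individual} metadata).
#' @param paths named list of \code{\link{AncestryPath-class}}.
#' @param grid the \code{\link{WindowGrid-class}} used for decoding.
#' @param minOverlap window overlap fraction counting as introgressed
#'   (default 0.5).
#' @return list: sensitivity, specificity, fpr, confusion (TP/FP/FN/TN),
#'   nMissing, boundary (data.frame per tract with start/end errors in
#'   windows).
#' @export
evaluateRecovery <- function(truth, paths, grid, minOverlap = 0.5) {
  tracts <- if (is(truth, "GRanges")) truth else truth$tracts
  win <- gridWindows(grid)
  W <- windowSize(grid)
  if (length(paths) && length(pathWindows(paths[[1L]])) != length(win))
    stop("grid mismatch: paths were decoded on a different window grid")
  TP <- FP <- FN <- TN <- 0L; nMissing <- 0L
  bound <- list()
  for (ind in names(paths)) {
    st <- pathStates(paths[[ind]])
    tr <- tracts[tracts$individual == ind]
    frac <- rep(0, length(win))
    if (length(tr)) {
      ov <- findOverlaps(win, tr)
      if (length(ov)) {
        pw <- width(pintersect(win[queryHits(ov)], tr[subjectHits(ov)]))
        agg <- tapply(pw, queryHits(ov), sum)
        frac[as.integer(names(agg))] <- agg / width(win)[as.integer(names(agg))]
      }
    }
    truthI <- frac >= minOverlap
    pred <- st %in% c("SRC", "HET")
    inf <- st != "MISSING"
    nMissing <- nMissing + sum(!inf)
    TP <- TP + sum(pred & truthI & inf)
    FP <- FP + sum(pred & !truthI & inf)
    FN <- FN + sum(!pred & truthI & inf)
    TN <- TN + sum(!pred & !truthI & inf)
    blocks <- extractBlocks(paths[[ind]])
    for (ti in seq_along(tr)) {
      hit <- blocks[IRanges::overlapsAny(blocks, tr[ti])]
      bound[[length(bound) + 1L]] <- data.frame(
        individual = ind, chrom = as.character(seqnames(tr))[ti],
        start = start(tr)[ti], end = end(tr)[ti],
        startErrWin = if (length(hit))
          abs(min(start(hit)) - start(tr)[ti]) / W else NA_real_,
        endErrWin = if (length(hit))
          abs(max(end(hit)) - end(tr)[ti]) / W else NA_real_)
    }
  }
  list(sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       fpr = if (TN + FP > 0) FP / (TN + FP) else NA_real_,
       confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
       nMissing = nMissing,
       boundary = if (length(bound)) do.call(rbind, bound) else NULL)
}

#' Draw a stochastic tract plan
#'
#' For each individual, draws \code{count} donor tracts with lengths
#' exponentially distributed around \code{meanLength} — the expected tract
#' length after \code{t} generations of recombination at per-bp rate
#' \code{r} is 1/(r t), so \code{meanLength} encodes the age being
#' emulated — on chromosomes chosen proportionally to length, with uniform
#' start positions such that the tract fits.  Lengths are floored at one
#' window-scale unit (1e5 bp would be typical) only by the caller's choice
#' of \code{meanLength}; raw draws are capped at the chromosome length.
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param individuals character vector of focal individuals to receive
#'   tracts.
#' @param count tracts per individual.
#' @param meanLength mean tract length in bp.
#' @param zygosity "het" or "hom" for all tracts.
#' @param seed RNG seed.
#' @return named list of tract data.frames suitable for
#'   \code{\link{simConfig}}.
#' @export
randomTractPlan <- function(chromLengths, individuals, count, meanLength,
                            zygosity = "het", seed) {
  set.seed(seed)
  setNames(lapply(individuals, function(ind) {
    chrom <- sample(names(chromLengths), count, replace = TRUE,
                    prob = chromLengths)
    len <- pmin(pmax(ceiling(stats::rexp(count, 1 / meanLength)), 1),
                chromLengths[chrom])
    start <- floor(runif(count) * (chromLengths[chrom] - len)) + 1
    data.frame(chrom = chrom, start = start, length = len,
               zygosity = zygosity, row.names = NULL)
  }), individuals)
}

#' Preset: polymorphic invaded population with a shared donor haplotype
#'
#' A 15-individual focal population and a 10-individual donor panel over
#' 12 x 5 Mb chromosomes; six focal individuals carry one breakpoint-
#' identical homozygous donor tract of 2.2 Mb (3.67% of the genome, within
#' the few-percent admixture range typical of a recently invaded
#' population) spanning a causal fruit-color locus on chromosome 3, so
#' that carriers — and only carriers — show the dominant phenotype.
#'
#' @param seed RNG seed.
#' @return a \code{\link{simConfig}}.
#' @export
mg114Scenario <- function(seed) {
  carriers <- sprintf("NAT_%02d", 1:6)
  tracts <- setNames(lapply(carriers, function(i)
    data.frame(chrom = "chr03", start = 1200001, length = 2200000,
               zygosity = "hom")), carriers)
  simConfig(nDonor = 10L, nFocal = 15L, tracts = tracts,
            causalLocus = GRanges("chr03", IRanges(2300001, 2310000)),
            seed = seed)
}
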