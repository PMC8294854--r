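#' Extract ancestry blocks from a decoded path
#'
#' Maximal runs of identical non-MISSING state become blocks; interior runs
#' of MISSING windows flanked on both sides by the same state are bridged
#' into the enclosing block (mirroring the "ghost shading" of data-free
#' windows between same-state neighbours), while MISSING runs flanked by
#' different states, or at chromosome ends, belong to no block.  Only donor
#' (SRC) and heterozygous (HET) blocks are reported; native runs are the
#' background.  Coordinates snap to window boundaries.
#'
#' @param path an \code{\link{AncestryPath-class}}.
#' @return \code{GRanges} of blocks with metadata columns
#'   \code{individual}, \code{state}, \code{n_windows} (informative windows
#'   in the block) and \code{n_missing_bridged}.
#' @export
extractBlocks <- function(path) {
  win <- pathWindows(path)
  st <- as.character(pathStates(path))
  out <- list()
  for (chr in unique(as.character(seqnames(win)))) {
    idx <- which(as.character(seqnames(win)) == chr)
    s <- st[idx]
    obs <- which(s != "MISSING")
    if (!length(obs)) next
    r <- rle(s[obs])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] %in% c("SRC", "HET")) next
      wFirst <- idx[obs[starts[j]]]; wLast <- idx[obs[ends[j]]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = start(win)[wFirst], end = end(win)[wLast],
        state = r$values[j], n_windows = r$lengths[j],
        n_missing_bridged = (obs[ends[j]] - obs[starts[j]] + 1L) - r$lengths[j])
    }
  }
  lev <- GenomeInfoDb::seqlevels(win)
  if (!length(out)) {
    gr <- GRanges(individual = character(0), state = character(0),
                  n_windows = integer(0), n_missing_bridged = integer(0))
    GenomeInfoDb::seqlevels(gr) <- lev
    return(gr)
  }
  df <- do.call(rbind, out)
  GRanges(factor(df$chrom, levels = lev), IRanges(df$start, df$end),
          individual = path@individual, state = df$state,
          n_windows = df$n_windows, n_missing_bridged = df$n_missing_bridged)
}

#' Genome-wide admixture proportion of an individual
#'
#' Fraction of the assayable genome carrying donor ancestry, with
#' heterozygous windows weighted 1/2 (diploid dosage):
#' (SRC bp + 0.5 * HET bp) / non-MISSING bp.
#'
#' @param path an \code{\link{AncestryPath-class}} (all chromosomes).
#' @return numeric in [0, 1].
#' @export
admixtureProportion <- function(path) {
  st <- pathStates(path)
  w <- width(pathWindows(path))
  informative <- st != "MISSING"
  if (!any(informative))
    stop("all windows missing: admixture proportion undefined")
  (sum(w[st == "SRC"]) + 0.5 * sum(w[st == "HET"])) / sum(w[informative])
}

#' Group individuals by shared block breakpoints
#'
#' Two blocks match when both their starts and their ends lie within
#' \code{tolerance} windows of each other; matching is closed transitively
#' and the block carriers are partitioned into identity groups.  All blocks
#' supplied must be from one chromosome and one state.
#'
#' @param blocks \code{GRanges} of blocks (as from
#'   \code{\link{extractBlocks}}), one chromosome, one state.
#' @param windowSize window width in bp.
#' @param tolerance allowed breakpoint offset, in windows (default 1, the
#'   HMM's resolution).
#' @return list with \code{groups}, a list of character vectors of
#'   individuals (largest first), and \code{sizes}.
#' @export
sharedBreakpoints <- function(blocks, windowSize, tolerance = 1L) {
  if (length(blocks) == 0L) return(list(groups = list(), sizes = integer(0)))
  if (length(unique(as.character(seqnames(blocks)))) > 1L)
    stop("blocks must come from a single chromosome")
  if (length(unique(blocks$state)) > 1L)
    stop("blocks must share one ancestry state")
  tolBp <- tolerance * windowSize
  nb <- length(blocks)
  parent <- seq_len(nb)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    if (abs(start(blocks)[i] - start(blocks)[j]) <= tolBp &&
        abs(end(blocks)[i] - end(blocks)[j]) <= tolBp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(nb), find, 0L)
  groups <- split(blocks$individual, roots)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- NULL
  list(groups = lapply(groups, unique),
       sizes = vapply(groups, function(g) length(unique(g)), 0L))
}

#' Block age from proportional tract erosion
#'
#' Under survival decay of a tract's extent, x(t) = (1 - c)^t, the age of a
#' block observed at fraction \code{x} of its chromosome is
#' t = ln(x) / ln(1 - c) generations, where \code{c} is the per-generation
#' proportional erosion rate.  A full-chromosome block (x = 1) gives age 0;
#' the estimate is strictly decreasing in \code{x}.  This logarithmic decay
#' form is a deliberate modeling choice (see the methods vignette) suited
#' to order-of-magnitude dating only.
#'
#' @param x observed block length as a fraction of chromosome length,
#'   0 < x <= 1.
#' @param c per-generation proportional erosion rate, 0 < c < 1; see
#'   \code{\link{erosionRate}}.
#' @return estimated age in generations.
#' @export
estimateBlockAge <- function(x, c) {
  if (any(x <= 0 | x > 1)) stop("x must lie in (0, 1]")
  if (any(c <= 0 | c >= 1)) stop("c must lie in (0, 1)")
  log(x) / log(1 - c)
}

#' Per-generation tract erosion rate from a recombination rate
#'
#' c = r_bp * L * kappa: the probability per generation that recombination
#' cuts the tract, taken proportional to the per-bp per-generation
#' recombination rate times chromosome length, with a tunable
#' proportionality constant.
#'
#' @param rBp recombination rate per bp per generation.
#' @param chromLength chromosome length in bp.
#' @param kappa proportionality constant (default 1).
#' @return erosion rate in (0, 1); capped below 1.
#' @export
erosionRate <- function(rBp, chromLength, kappa = 1) {
  min(rBp * chromLength * kappa, 1 - 1e-9)
}

#' Summarize blocks and admixture per individual
#'
#' @param paths named list of \code{\link{AncestryPath-class}} objects.
#' @return data.frame: individual, n_blocks, mean_block_bp, total_src_bp,
#'   admixture_proportion.
#' @export
blockSummary <- function(paths) {
  do.call(rbind, lapply(paths, function(p) {
    b <- extractBlocks(p)
    data.frame(individual = p@individual, n_blocks = length(b),
               mean_block_bp = if (length(b)) mean(width(b)) else NA_real_,
               total_src_bp = sum(width(b)[b$state == "SRC"]),
               admixture_proportion = admixtureProportion(p),
               row.names = NULL)
  }))
}

#' Write ancestry blocks as BED
#'
#' Six-column BED: chrom, start (0-based), end, name =
#' \code{individual|state}, score = number of bridged missing windows,
#' strand = ".".
#'
#' @param blocks \code{GRanges} from \code{\link{extractBlocks}}.
#' @param path output file.
#' @export
writeBlocksBed <- function(blocks, path) {
  df <- data.frame(chrom = as.character(seqnames(blocks)),
                   start = start(blocks) - 1L, end = end(blocks),
                   name = paste(blocks$individual, blocks$state, sep = "|"),
                   score = blocks$n_missing_bridged, strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
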