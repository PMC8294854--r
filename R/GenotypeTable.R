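#' Construct a GenotypeTable
#'
#' @param geno integer matrix of alt-allele dosages (sites x samples), with
#'   column names taken as sample identifiers when \code{samples} is not
#'   given.
#' @param sites \code{GRanges} of SNP positions with \code{REF}/\code{ALT}
#'   metadata columns, one per row of \code{geno}.
#' @param coverage named \code{GRangesList} of callable intervals per sample;
#'   a plain \code{GRanges} is recycled to every sample.
#' @param samples optional character vector of sample identifiers.
#'
#' @details Multi-allelic sites must be removed before construction (the VCF
#'   reader \code{\link{readGenotypes}} drops them with a message).  Sites
#'   are reordered by chromosome and position.
#'
#' @return A \code{\link{GenotypeTable-class}} object.
#' @export
GenotypeTable <- function(geno, sites, coverage, samples = colnames(geno)) {
  if (is.null(samples)) stop("sample identifiers required")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(sites))
    stop("nrow(geno) must equal length(sites)")
  colnames(geno) <- samples
  if (is(coverage, "GRanges"))
    coverage <- GRangesList(setNames(rep(list(coverage), length(samples)), samples))
  coverage <- GRangesList(lapply(coverage, reduce))
  ord <- order(as.character(seqnames(sites)), start(sites))
  new("GenotypeTable", samples = samples, sites = sites[ord],
      geno = geno[ord, , drop = FALSE], coverage = coverage[samples])
}

#' @describeIn GenotypeTable Sample identifiers.
#' @param x,object a \code{GenotypeTable}.
#' @export
sampleIds <- function(x) x@samples

#' @describeIn GenotypeTable SNP positions as \code{GRanges}.
#' @export
siteRanges <- function(x) x@sites

#' @describeIn GenotypeTable Dosage matrix (sites x samples).
#' @export
genoMatrix <- function(x) x@geno

#' @describeIn GenotypeTable Callable intervals, all samples or one.
#' @param sample optional single sample identifier.
#' @export
sampleCoverage <- function(x, sample = NULL) {
  if (is.null(sample)) x@coverage else x@coverage[[.checkSample(x, sample)]]
}

.checkSample <- function(x, sample) {
  missing <- setdiff(sample, x@samples)
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  sample
}

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", length(object@sites), "biallelic sites x",
      length(object@samples), "samples\n")
  cat("  chromosomes:", paste(unique(as.character(seqnames(object@sites))),
                              collapse = ", "), "\n")
  ncalled <- sum(!is.na(object@geno))
  cat(sprintf("  genotype completeness: %.1f%%\n",
              100 * ncalled / length(object@geno)))
  cat(sprintf("  coverage: %.2f Mb mean per sample\n",
              mean(vapply(object@coverage,
                          function(g) sum(width(g)), 0)) / 1e6))
})

#' Read genotypes, coverage and population map from standard files
#'
#' Loads a VCF of diploid biallelic genotypes (via \pkg{vcfR}), per-sample
#' coverage BED intervals (via \pkg{rtracklayer}) and assembles a
#' \code{\link{GenotypeTable}}.  Multi-allelic and non-SNP records are
#' dropped with a message reporting how many.
#'
#' @param vcf path to a VCF file (plain or bgzipped).
#' @param coverage either a named list/vector of per-sample BED paths, a
#'   single 4-column BED path whose name field holds the sample, or a
#'   \code{GRangesList} already in memory.
#' @param samples optional subset of samples to keep.
#'
#' @return A \code{GenotypeTable}.
#' @export
readGenotypes <- function(vcf, coverage, samples = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!keep))
    message("dropped ", sum(!keep), " multi-allelic or non-SNP sites")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
  dos <- .gtToDosage(gt)
  sites <- GRanges(fix[keep, "CHROM"],
                   IRanges(as.integer(fix[keep, "POS"]), width = 1),
                   REF = ref[keep], ALT = alt[keep])
  cov <- .readCoverage(coverage, colnames(dos))
  GenotypeTable(dos, sites, cov, samples = colnames(dos))
}

.gtToDosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

.readCoverage <- function(coverage, samples) {
  if (is(coverage, "GRangesList") || is(coverage, "GRanges")) return(coverage)
  if (length(coverage) == 1L && is.null(names(coverage))) {
    bed <- rtracklayer::import(coverage[[1]], format = "BED")
    if (!"name" %in% colnames(mcols(bed)))
      stop("single coverage BED must carry sample names in column 4")
    return(GRangesList(split(granges(bed), mcols(bed)$name))[samples])
  }
  paths <- unlist(coverage)
  GRangesList(lapply(setNames(paths[samples], samples), function(p)
    granges(rtracklayer::import(p, format = "BED"))))
}

#' Read a population map
#'
#' A population map is a headerless three-column TSV:
#' \code{sample<TAB>population<TAB>species}.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{sample}, \code{population},
#'   \code{species}.
#' @export
readPopmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population", "species"),
                   colClasses = "character")
  pm
}
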