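#' Donor-ancestry carrier status at a locus
#'
#' An individual is a carrier at a locus when any donor (SRC) or
#' heterozygous (HET) block overlaps the locus interval (half-open overlap
#' semantics: a block ending exactly at the locus start does not overlap).
#' SRC overlap gives hom-carrier, otherwise HET overlap gives het-carrier.
#' Under the default dominance coding both collapse to "carrier" in
#' downstream tests, since heterozygous donor ancestry suffices for the
#' dominant phenotype.
#'
#' @param blocks \code{GRanges} of ancestry blocks (pooled across
#'   individuals), with \code{individual} and \code{state} metadata.
#' @param locus \code{GRanges} of length 1 (the candidate interval).
#' @param individuals character vector of all individuals to report
#'   (non-carriers included).
#' @return named factor with levels \code{non-carrier}, \code{het-carrier},
#'   \code{hom-carrier}.
#' @export
carrierStatus <- function(blocks, locus, individuals) {
  stopifnot(length(locus) == 1L)
  if (length(blocks) &&
      !as.character(seqnames(locus)) %in%
        unique(as.character(seqnames(blocks))) &&
      !as.character(seqnames(locus)) %in% GenomeInfoDb::seqlevels(blocks))
    stop("locus chromosome not present among block chromosomes")
  status <- setNames(rep("non-carrier", length(individuals)), individuals)
  if (length(blocks)) {
    ov <- blocks[IRanges::overlapsAny(blocks, locus)]
    hets <- unique(ov$individual[ov$state == "HET"])
    homs <- unique(ov$individual[ov$state == "SRC"])
    status[intersect(hets, individuals)] <- "het-carrier"
    status[intersect(homs, individuals)] <- "hom-carrier"
  }
  factor(status, levels = c("non-carrier", "het-carrier", "hom-carrier"))
}

.chi2yates <- function(a, b, c, d, correct = TRUE) {
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(num - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  N * num^2 / denom
}

#' Chi-square test of ancestry against a binary phenotype
#'
#' Pearson's chi-square test of independence on a 2x2 carrier-by-phenotype
#' table, with the Yates continuity correction applied by default:
#' chi2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d)), the corrected
#' numerator floored at 0.  The p-value is the upper tail of chi-square
#' with 1 degree of freedom.
#'
#' @param table 2x2 matrix (rows carrier/non-carrier, columns phenotype
#'   +/-) or numeric length-4 vector \code{c(a, b, c, d)} with
#'   a = carrier & phenotype+, b = non-carrier & phenotype+,
#'   c = carrier & phenotype-, d = non-carrier & phenotype-.
#' @param correct apply the continuity correction (default TRUE).
#' @return list of class \code{radmix_assoc}: \code{chi2}, \code{df},
#'   \code{p}, \code{table}, \code{corrected}.
#' @examples
#' ancestryPhenotypeTest(c(6, 0, 0, 9))  # chi2 = 11.12
#' ancestryPhenotypeTest(c(6, 0, 0, 6))  # chi2 = 8.33
#' @export
ancestryPhenotypeTest <- function(table, correct = TRUE) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    stopifnot(length(table) == 4L)
    a <- table[1]; b <- table[2]; c <- table[3]; d <- table[4]
  }
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  if (min((a + b), (c + d), (a + c), (b + d)) == 0)
    stop("degenerate table: every row and column margin must be positive")
  chi2 <- .chi2yates(a, b, c, d, correct)
  out <- list(chi2 = unname(chi2), df = 1L,
              p = unname(pchisq(chi2, df = 1, lower.tail = FALSE)),
              table = matrix(c(a, c, b, d), 2, 2,
                             dimnames = list(c("carrier", "non-carrier"),
                                             c("phenotype+", "phenotype-"))),
              corrected = correct)
  class(out) <- "radmix_assoc"
  out
}

#' @export
print.radmix_assoc <- function(x, ...) {
  cat(sprintf("chi2 = %.2f; df = %d; p = %.4g%s\n", x$chi2, x$df, x$p,
              if (x$corrected) " (Yates-corrected)" else ""))
  print(x$table)
  invisible(x)
}

#' Genome-wide admixture-mapping scan
#'
#' Tests, window by window, the association between local donor-ancestry
#' carrier status (SRC or HET at the window; dominance coding) and a binary
#' phenotype.  Only windows with at least one carrier and one non-carrier
#' among informative individuals are tested; windows where the phenotype is
#' constant among informative individuals are skipped (NA).  Raw p-values
#' and Benjamini-Hochberg q-values over the tested windows are reported,
#' and windows overlapping supplied candidate loci are flagged.
#'
#' @param paths named list of \code{\link{AncestryPath-class}} objects, one
#'   per individual.
#' @param phenotypes named 0/1 vector (1 = phenotype present), names are
#'   individuals.
#' @param candidates optional \code{GRanges} of candidate gene loci.
#' @param correct apply the Yates correction (default TRUE).
#' @return data.frame: chrom, start (0-based), end, a, b, c, d, chi2, p, q,
#'   candidate.
#' @export
genomeScan <- function(paths, phenotypes, candidates = NULL, correct = TRUE) {
  ind <- names(paths)
  ph <- phenotypes[ind]
  if (any(is.na(ph))) stop("phenotype missing for some individuals")
  if (length(unique(ph)) < 2L)
    stop("phenotype is constant: association is undefined")
  win <- pathWindows(paths[[1L]])
  st <- matrix(vapply(paths, function(p) as.character(pathStates(p)),
                      character(length(win))), nrow = length(win))
  carrier <- st == "SRC" | st == "HET"
  informative <- st != "MISSING"
  P <- matrix(rep(ph == 1, each = nrow(st)), nrow(st))
  a <- rowSums(carrier & P & informative)
  b <- rowSums(!carrier & P & informative)
  cc <- rowSums(carrier & !P & informative)
  d <- rowSums(!carrier & !P & informative)
  testable <- (a + cc) > 0 & (b + d) > 0 & (a + b) > 0 & (cc + d) > 0
  chi2 <- p <- rep(NA_real_, length(a))
  chi2[testable] <- .chi2yates(a[testable], b[testable], cc[testable],
                               d[testable], correct)
  p[testable] <- pchisq(chi2[testable], 1, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[testable] <- p.adjust(p[testable], method = "BH")
  cand <- if (is.null(candidates)) rep(FALSE, length(win)) else
    IRanges::overlapsAny(win, candidates)
  data.frame(chrom = as.character(seqnames(win)), start = start(win) - 1L,
             end = end(win), a = a, b = b, c = cc, d = d,
             chi2 = chi2, p = p, q = q, candidate = cand)
}

#' Read a binary phenotype table
#'
#' Headerless two-column TSV \code{individual<TAB>phenotype} with phenotype
#' coded 0/1.
#'
#' @param path TSV path.
#' @return named integer vector.
#' @export
readPhenotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("individual", "phenotype"))
  setNames(as.integer(df$phenotype), df$individual)
}
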