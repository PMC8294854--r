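#' Run the full local-ancestry pipeline on a simulated scenario
#'
#' Composes the pipeline end to end: simulate the panel, count windowed
#' pairwise differences, decode every focal individual against the donor
#' panel, extract ancestry blocks, score window-level recovery against the
#' planted truth, call carrier status at the causal locus, and run the
#' genome-wide ancestry-phenotype scan.
#'
#' The observation track defaults to \code{maxPanel = 1}: each window's
#' binomial observation comes from the focal individual and a single panel
#' sample.  Summing counts over many panel pairs multiplies \code{n}
#' without adding independent information — the shared divergence to the
#' donor ancestor is counted once per pair — which makes the binomial
#' overconfident and inflates false ancestry switches; one pair keeps the
#' emission model's independence assumption honest (see the methods
#' vignette).  Set \code{maxPanel = Inf} for full aggregation.
#'
#' @param config a \code{\link{simConfig}} (e.g.
#'   \code{\link{mg114Scenario}}).
#' @param maxPanel panel samples aggregated per observation (default 1).
#' @param tau HMM per-window switch rate.
#' @param minSites minimum compared sites for an informative window.
#' @return list: \code{paths}, \code{blocks} (pooled \code{GRanges}),
#'   \code{recovery} (from \code{\link{evaluateRecovery}}),
#'   \code{carriers} (factor per focal individual at the causal locus, or
#'   \code{NULL}), \code{scan} (genome-wide association table, or
#'   \code{NULL} when the phenotype is constant), \code{truth},
#'   \code{popmap}.
#' @export
runScenario <- function(config, maxPanel = 1L, tau = 1e-3,
                        minSites = 100L) {
  sim <- simulateDataset(config)
  donors <- sim$popmap$sample[sim$popmap$population == "DON"]
  focals <- sim$popmap$sample[sim$popmap$population == "NAT"]
  cmb <- combn(donors, 2L)
  pairs <- rbind(
    data.frame(sampleA = cmb[1L, ], sampleB = cmb[2L, ],
               stringsAsFactors = FALSE),
    expand.grid(sampleA = focals, sampleB = donors,
                stringsAsFactors = FALSE))
  counts <- countAllPairs(sim$gt, sim$grid, pairs = pairs,
                          popmap = sim$popmap)
  paths <- decodePopulation(counts, focals, donors, sim$grid,
                            trans = symmetricTransitions(tau),
                            minSites = minSites, maxPanel = maxPanel)
  blocks <- do.call(c, unname(lapply(paths, extractBlocks)))
  recovery <- evaluateRecovery(sim$truth, paths, sim$grid)
  carriers <- if (!is.null(config$causalLocus))
    carrierStatus(blocks, config$causalLocus, focals) else NULL
  scan <- if (length(unique(sim$truth$phenotypes)) > 1L)
    genomeScan(paths, sim$truth$phenotypes,
               candidates = config$causalLocus) else NULL
  list(paths = paths, blocks = blocks, recovery = recovery,
       carriers = carriers, scan = scan, truth = sim$truth,
       popmap = sim$popmap)
}
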