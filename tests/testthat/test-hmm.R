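test_that("emission parameter construction and invariants", {
  p <- EmissionParams(0.0005, 0.0023)
  expect_equal(p@pHet, 0.0014)
  expect_error(EmissionParams(0.01, 0.001))    # ordering violated
  expect_error(EmissionParams(0, 0.5))         # rate at boundary
  tr <- symmetricTransitions(1e-3)
  expect_equal(rowSums(tr@trans), c(SRC = 1, HET = 1, NAT = 1))
  expect_equal(tr@trans["SRC", "HET"], 5e-4)
})

test_that("emission parameters are recovered as medians of window rates", {
  # panel P1,P2; native N1.  Construct counts with known per-window rates.
  win <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 101, 201), width = 100))
  k <- cbind(c(1L, 2L, 6L),    # P1:P2 rates 0.001, 0.002, 0.006
             c(20L, 30L, 40L), # N1:P1 rates 0.02, 0.03, 0.04
             c(22L, 30L, 41L)) # N1:P2
  n <- matrix(1000L, 3, 3)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(k = k, n = n), rowRanges = win,
    colData = S4Vectors::DataFrame(sampleA = c("P1", "N1", "N1"),
                                   sampleB = c("P2", "P1", "P2")))
  counts <- new("PairWindowCounts", se)
  p <- estimateEmissionParams(counts, panel = c("P1", "P2"), nativeRef = "N1")
  expect_equal(p@pSrc, 0.002)   # median(0.001, 0.002, 0.006)
  expect_equal(p@pNat, 0.03)    # median of the six cross rates
  expect_equal(p@pHet, (0.002 + 0.03) / 2)
  expect_error(estimateEmissionParams(counts, panel = "P1", nativeRef = "N1"),
               "insufficient data")
  # undiverged populations: swap roles so pNat <= pSrc
  p2 <- new("PairWindowCounts", se[, c(2, 3, 1)])
  expect_error(
    estimateEmissionParams(counts, panel = c("N1", "P1"), nativeRef = "P2"),
    "not diverged")
})

test_that("binomial emission log-likelihoods match direct pmf evaluation", {
  prm <- EmissionParams(0.0005, 0.0023)
  expect_equal(emissionLogLik(0L, 0L, prm), matrix(0, 1, 3,
    dimnames = list(NULL, c("SRC", "HET", "NAT"))))
  ll <- emissionLogLik(2L, 2000L, prm)
  direct <- function(k, n, p) lchoose(n, k) + k * log(p) + (n - k) * log(1 - p)
  expect_equal(ll[1, "SRC"], direct(2, 2000, 0.0005), ignore_attr = TRUE)
  expect_equal(ll[1, "HET"], direct(2, 2000, 0.0014), ignore_attr = TRUE)
  expect_equal(ll[1, "NAT"], direct(2, 2000, 0.0023), ignore_attr = TRUE)
  # direct pmf evaluation puts k = 2 of 2000 in the HET basin, k = 1 in SRC
  expect_equal(unname(which.max(ll[1, ])), 2L)
  ll1 <- emissionLogLik(1L, 2000L, prm)
  expect_equal(unname(which.max(ll1[1, ])), 1L)
  expect_error(emissionLogLik(3L, 2L, prm), "exceed")
})

test_that("argmax state moves SRC -> HET -> NAT as k grows, never reversing", {
  prm <- EmissionParams(0.0005, 0.0023)
  n <- 5000L
  am <- apply(emissionLogLik(0:n, rep(n, n + 1L), prm), 1, which.max)
  expect_true(all(diff(am) >= 0))
  expect_equal(sort(unique(am)), 1:3)
})

test_that("binomial emissions are normalized", {
  prm <- EmissionParams(0.05, 0.4)
  for (n in c(1L, 7L, 50L, 200L)) {
    ll <- emissionLogLik(0:n, rep(n, n + 1L), prm)
    expect_equal(colSums(exp(ll)), c(SRC = 1, HET = 1, NAT = 1),
                 tolerance = 1e-9)
  }
})

test_that("single informative window decodes to its emission argmax", {
  prm <- EmissionParams(0.0005, 0.0023)
  dec <- viterbiDecode(data.frame(k = 0L, n = 1000L), prm)
  expect_equal(as.character(dec$state), "SRC")
})

test_that("Viterbi equals exhaustive path enumeration on short tracks", {
  set.seed(101)
  prm <- EmissionParams(0.01, 0.1)
  for (rep in 1:40) {
    L <- sample(1:8, 1)
    tr <- symmetricTransitions(runif(1, 0.01, 0.4))
    n <- sample(c(0L, 50L, 200L), L, replace = TRUE)
    k <- vapply(n, function(ni) if (ni == 0L) 0L else
      rbinom(1L, ni, sample(c(0.01, 0.05, 0.1), 1)), 0L)
    track <- data.frame(k = k, n = n)
    dec <- viterbiDecode(track, prm, tr)
    emiss <- emissionLogLik(k, n, prm)
    expect_equal(unname(dec$logLik), oracleViterbi(emiss, tr),
                 tolerance = 1e-10)
  }
})

test_that("a missing window between donor-like windows is bridged to SRC", {
  prm <- EmissionParams(0.0005, 0.0023)
  tr <- symmetricTransitions(1e-3)  # stay probability 0.999
  track <- data.frame(k = c(1L, 0L, 0L), n = c(2000L, 0L, 2000L),
                      missing = c(FALSE, TRUE, FALSE))
  dec <- viterbiDecode(track, prm, tr)
  expect_equal(as.character(dec$state), c("SRC", "SRC", "SRC"))
  emiss <- emissionLogLik(track$k, track$n, prm)
  expect_equal(unname(dec$logLik), oracleViterbi(emiss, tr), tolerance = 1e-10)
})

test_that("adding a constant to a window's log-emissions leaves the path unchanged", {
  set.seed(55)
  prm <- EmissionParams(0.02, 0.2)
  tr <- symmetricTransitions(0.05)
  n <- rep(100L, 10L)
  k <- rbinom(10L, n, 0.1)
  emiss <- emissionLogLik(k, n, prm)
  base <- radmix:::.viterbi(emiss, tr)
  shifted <- emiss
  shifted[4L, ] <- shifted[4L, ] + 7.3
  again <- radmix:::.viterbi(shifted, tr)
  expect_equal(again$states, base$states)
  expect_equal(again$logLik, base$logLik + 7.3)
})

test_that("exact ties break conservatively toward native ancestry", {
  tr <- new("TransitionModel", trans = matrix(1 / 3, 3, 3),
            init = rep(1 / 3, 3))
  dec <- radmix:::.viterbi(matrix(0, 2, 3), tr)
  expect_equal(dec$states, c(3L, 3L))  # NAT on all-tied emissions
})

test_that("chromosomes decode independently", {
  cfg <- simConfig(chromLengths = c(chr01 = 8e5, chr02 = 8e5),
                   nDonor = 4, nFocal = 3,
                   tracts = list(NAT_01 = data.frame(
                     chrom = "chr02", start = 200001, length = 300000,
                     zygosity = "hom")),
                   seed = 31)
  sim <- simulateDataset(cfg)
  counts <- countAllPairs(sim$gt, sim$grid, popmap = sim$popmap)
  donors <- paste0("DON_0", 1:4)
  both <- decodeIndividual(counts, "NAT_01", donors,
                           c("NAT_02", "NAT_03"), sim$grid, maxPanel = 1)
  prm <- estimateEmissionParams(counts, donors, c("NAT_02", "NAT_03"))
  # decode each chromosome alone and compare
  track <- observationTrack(counts, "NAT_01", donors, maxPanel = 1)
  for (chr in c("chr01", "chr02")) {
    sel <- track$chrom == chr
    alone <- viterbiDecode(track[sel, ], prm)
    expect_equal(as.character(alone$state),
                 as.character(both@decoded[sel]))
    expect_equal(unname(alone$logLik), unname(both@logLik[chr]))
  }
})

test_that("a planted homozygous tract is labeled SRC and clean genomes stay NAT", {
  cfg <- simConfig(chromLengths = c(chr01 = 3e6), nDonor = 5, nFocal = 3,
                   tracts = list(NAT_01 = data.frame(
                     chrom = "chr01", start = 1000001, length = 1500000,
                     zygosity = "hom")),
                   seed = 77)
  sim <- simulateDataset(cfg)
  counts <- countAllPairs(sim$gt, sim$grid, popmap = sim$popmap)
  donors <- paste0("DON_0", 1:5)
  paths <- decodePopulation(counts, paste0("NAT_0", 1:3), donors, sim$grid,
                            maxPanel = 1)
  st1 <- pathStates(paths[["NAT_01"]])
  tractWin <- 11:25  # windows [1.0, 2.5) Mb
  expect_gte(mean(st1[tractWin] == "SRC"), 0.9)
  stClean <- unlist(lapply(paths[c("NAT_02", "NAT_03")], function(p)
    as.character(pathStates(p))))
  expect_gte(mean(stClean[stClean != "MISSING"] == "NAT"), 0.98)
})

test_that("heterozygous tracts are assigned the HET state", {
  cfg <- simConfig(chromLengths = c(chr01 = 3e6), nDonor = 5, nFocal = 3,
                   tracts = list(NAT_01 = data.frame(
                     chrom = "chr01", start = 1000001, length = 1500000,
                     zygosity = "het")),
                   seed = 78)
  sim <- simulateDataset(cfg)
  counts <- countAllPairs(sim$gt, sim$grid, popmap = sim$popmap)
  path <- decodeIndividual(counts, "NAT_01", paste0("DON_0", 1:5),
                           c("NAT_02", "NAT_03"), sim$grid, maxPanel = 1)
  st <- pathStates(path)
  expect_gte(mean(st[11:25] == "HET"), 0.8)
})
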