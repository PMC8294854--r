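test_that("Watterson's theta follows the closed form", {
  # 2 diploids = 4 haplotypes, 3 segregating sites
  g <- cbind(s1 = c(1L, 0L, 1L), s2 = c(0L, 1L, 2L))
  gt <- makeGT(g, pos = c(10, 20, 30), chromLen = 100)
  st <- siteStats(gt)
  expect_equal(st$S, 3L)
  expect_equal(st$thetaW, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  expect_equal(round(st$thetaW, 4), 1.6364)
})

test_that("pi and Tajima's D match the all-pairs haplotype oracle", {
  set.seed(31)
  for (rep in 1:25) {
    ns <- sample(2:5, 1)
    g <- matrix(sample(0:2, 15 * ns, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)), 15, ns,
                dimnames = list(NULL, paste0("s", seq_len(ns))))
    gt <- makeGT(g, pos = seq(10, by = 10, length.out = 15), chromLen = 200)
    st <- siteStats(gt)
    orc <- oracleStats(g)
    expect_equal(st$S, orc$S)
    expect_equal(st$thetaW, orc$thetaW, tolerance = 1e-12)
    expect_equal(st$pi, orc$pi, tolerance = 1e-12)
    if (is.na(orc$D)) expect_true(is.na(st$tajimaD)) else
      expect_equal(st$tajimaD, orc$D, tolerance = 1e-10)
  }
})

test_that("monomorphic input flags Tajima's D as undefined", {
  g <- matrix(0L, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  g[1, ] <- 2L  # fixed alternate: still not segregating
  gt <- makeGT(g, pos = seq(5, 25, by = 5), chromLen = 50)
  st <- siteStats(gt)
  expect_equal(st$S, 0L)
  expect_equal(st$thetaW, 0)
  expect_true(is.na(st$tajimaD))
})

test_that("the folded SFS bins minor alleles and respects masks", {
  # one singleton among 4 chromosomes
  g <- cbind(a = c(1L, 0L), b = c(0L, 2L))
  gt <- makeGT(g, pos = c(100, 200), chromLen = 1000)
  sfs <- foldedSFS(gt)
  expect_equal(unname(sfs$counts), c(0, 1, 1))  # classes 0,1,2 of n=4
  # masking the second site removes its contribution; empty mask is identity
  m <- GenomicRanges::GRanges("c1", IRanges::IRanges(150, 250))
  sfsM <- foldedSFS(gt, mask = m)
  expect_equal(unname(sfsM$counts), c(0, 1, 0))
  expect_equal(sfsM$masked, 1L)
  expect_equal(foldedSFS(gt, mask = GenomicRanges::GRanges())$counts,
               sfs$counts)
})

test_that("projection spreads sites by the hypergeometric expectation", {
  # site with 2 alt of 4 called chromosomes, projected to 2
  g <- cbind(a = 1L, b = 1L)
  gt <- makeGT(g, pos = 50, chromLen = 100)
  sfs <- foldedSFS(gt, nProj = 2)
  h <- dhyper(0:2, 2, 2, 2)  # P(0,1,2 alt among 2 drawn)
  expect_equal(unname(sfs$counts), c(h[1] + h[3], h[2]))
  expect_equal(sum(sfs$counts), 1)  # per-site mass conserved
  # a site with too few called chromosomes is dropped
  g2 <- cbind(a = 1L, b = NA_integer_)
  gt2 <- makeGT(g2, pos = 50, chromLen = 100)
  expect_warning(sfs2 <- foldedSFS(gt2, nProj = 4), "projection")
  expect_equal(sfs2$dropped, 1L)
  expect_equal(sum(sfs2$counts), 0)
})

test_that("projection conserves total mass over a random panel", {
  set.seed(17)
  g <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                     prob = c(0.5, 0.2, 0.1, 0.2)), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  gt <- makeGT(g, pos = seq(10, by = 15, length.out = 50), chromLen = 1000)
  sfs <- foldedSFS(gt, nProj = 4)
  nKept <- sum(2 * rowSums(!is.na(g)) >= 4)
  expect_equal(sum(sfs$counts), nKept, tolerance = 1e-9)
})

test_that("SFS bootstrap is seeded, total-preserving, and unbiased", {
  sfs <- structure(list(counts = c(`0` = 0, `1` = 60, `2` = 25, `3` = 15),
                        n = 6, masked = 0L, dropped = 0L),
                   class = "radmix_sfs")
  b1 <- bootstrapSFS(sfs, reps = 5, seed = 42)
  b2 <- bootstrapSFS(sfs, reps = 5, seed = 42)
  expect_identical(b1, b2)
  expect_true(all(vapply(b1, function(s) sum(s$counts), 0) == 100))
  many <- bootstrapSFS(sfs, reps = 1000, seed = 7)
  avg <- Reduce(`+`, lapply(many, `[[`, "counts")) / 1000
  expect_equal(unname(avg), unname(sfs$counts), tolerance = 0.05)
  one <- structure(list(counts = c(`1` = 30), n = 2, masked = 0L,
                        dropped = 0L), class = "radmix_sfs")
  expect_true(all(vapply(bootstrapSFS(one, 10, 1),
                         function(s) s$counts, 0) == 30))
})

test_that("Patterson's D matches its definition and is antisymmetric in P1/P2", {
  set.seed(23)
  mkgt <- function(g) makeGT(g, pos = seq(100, by = 100,
                                          length.out = nrow(g)),
                             chromLen = 1e5)
  for (rep in 1:10) {
    g <- matrix(sample(0:2, 4 * 30, replace = TRUE), 30, 4,
                dimnames = list(NULL, c("p1", "p2", "p3", "o")))
    g[, "o"] <- sample(c(0L, 2L), 30, replace = TRUE)  # fixed outgroup
    gt <- mkgt(g)
    d12 <- pattersonD(gt, "p1", "p2", "p3", "o", reps = 50, seed = 5)
    d21 <- pattersonD(gt, "p2", "p1", "p3", "o", reps = 50, seed = 5)
    # direct-site oracle
    der <- g / 2
    flip <- g[, "o"] == 2L
    der[flip, ] <- 1 - g[flip, ] / 2
    abba <- sum((1 - der[, "p1"]) * der[, "p2"] * der[, "p3"])
    baba <- sum(der[, "p1"] * (1 - der[, "p2"]) * der[, "p3"])
    if (abba + baba > 0) {
      expect_equal(d12$D, (abba - baba) / (abba + baba), tolerance = 1e-12)
      expect_equal(d21$D, -d12$D, tolerance = 1e-12)
      expect_true(abs(d12$D) <= 1)
    } else {
      expect_true(is.na(d12$D))
    }
  }
})

test_that("polymorphic outgroup sites are excluded from D", {
  g <- cbind(p1 = c(0L, 0L), p2 = c(2L, 2L), p3 = c(2L, 2L),
             o = c(1L, 0L))  # first site: polymorphic outgroup
  gt <- makeGT(g, pos = c(100, 200), chromLen = 1000)
  d <- pattersonD(gt, "p1", "p2", "p3", "o", reps = 10, seed = 1)
  expect_equal(d$nSites, 1L)
  expect_equal(d$D, 1)  # pure ABBA at the remaining site
})

test_that("demographic rescaling recovers absolute units", {
  r <- rescaleDemography(theta = 68.40, mu = 1e-8, L = 5806952,
                         nu = c(NB = 408.32 / 294.5, NF = 4041.63 / 294.5))
  expect_equal(r$Nref, 68.40 / (4 * 1e-8 * 5806952))
  expect_equal(round(r$Nref, 1), 294.5, tolerance = 1e-3)
  # nu = 1 maps to Nref itself
  expect_equal(rescaleDemography(1, 1e-8, 1e6, nu = 1)$N,
               rescaleDemography(1, 1e-8, 1e6)$Nref)
  # time rescaling: T_gen = 2 Nref T
  r2 <- rescaleDemography(68.40, 1e-8, 5806952, Tcoal = c(0.1, 0.2))
  expect_equal(r2$T_gen, 2 * r2$Nref * c(0.1, 0.2))
  expect_error(rescaleDemography(-1, 1e-8, 1e6), "positive")
  expect_equal(bottleneckTotalTime(96.52, 105.14), 201.66)
  expect_equal(bottleneckTotalTime(77.15, 123.02), 200.17)
})

test_that("windowed Tajima's D reports a mean and dispersion across windows", {
  set.seed(40)
  g <- matrix(sample(0:2, 60 * 4, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
              60, 4, dimnames = list(NULL, paste0("s", 1:4)))
  gt <- makeGT(g, pos = seq(10, by = 30, length.out = 60), chromLen = 2000)
  res <- tajimaDWindowed(gt, paste0("s", 1:4), WindowGrid(c(c1 = 2000), 500))
  expect_equal(nrow(res$perWindow), 4L)
  expect_true(is.finite(res$mean) && is.finite(res$sd))
  # masking everything leaves no usable windows
  resM <- tajimaDWindowed(gt, paste0("s", 1:4), WindowGrid(c(c1 = 2000), 500),
                          mask = GenomicRanges::GRanges(
                            "c1", IRanges::IRanges(1, 2000)))
  expect_true(all(resM$perWindow$S == 0))
})
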