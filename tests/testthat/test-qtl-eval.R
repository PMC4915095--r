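test_that("r2 matches hand-computed haplotype frequencies", {
  # a locus against itself
  h <- rep(c(1, 2), 5)
  expect_equal(computeR2(h, h), 1)
  # haplotype counts AB = 4, Ab = 1, aB = 1, ab = 4: D = 0.15, r2 = 0.36
  a <- c(rep("A", 5), rep("a", 5))
  b <- c(rep("B", 4), "b", "B", rep("b", 4))
  expect_equal(computeR2(a, b), 0.36, tolerance = 1e-12)
  # monomorphic locus is undefined
  expect_true(is.na(computeR2(rep(1, 10), h)))
  # unphased fallback
  expect_equal(computeR2(c(0, 1, 2, 2), c(0, 1, 2, 2), method = "genotype"), 1)
  # loci in linkage equilibrium: r2 ~ 0 at large samples
  set.seed(50)
  x <- rbinom(1e5, 1, 0.4) + 1
  z <- rbinom(1e5, 1, 0.6) + 1
  expect_lt(computeR2(x, z), 1e-3)
})

test_that("LD decay declines with distance and bins pairs correctly", {
  # single chromosome, two loci: one pair in one bin
  g <- fixedGenome(markerChrom = c(1, 1), markerPos = c(0.2, 0.5),
                   qtlChrom = 1, qtlPos = 0.9)
  mh <- rbind(rep(c(1L, 2L), 6), rep(c(1L, 1L, 2L, 2L), 3))
  pop <- fixedPop(g, mh, matrix(1:2, 1, 12))
  prof <- ldDecayProfile(pop, breaks = seq(0, 1, 0.25))
  expect_equal(sum(prof$nPairs), 1L)
  expect_equal(prof$nPairs[2], 1L) # distance 0.3 falls in (0.25, 0.5]
  expect_true(is.na(prof$meanR2[1]))

  # smoothed decay over replicates of a short history: r2 falls with distance
  g2 <- makeGenome(1, 25, nMarkers = 120, nQtl = 2, seed = 51)
  profs <- lapply(1:10, function(r) {
    pop <- simulateHistorical(g2, historicalSchedule(60, 60, 40, 30,
                                                     hld = FALSE),
                              seed = 500 + r)
    ldDecayProfile(pop, breaks = c(0, 1, 2, 4, 8, 16))$meanR2
  })
  avg <- colMeans(do.call(rbind, profs))
  expect_gt(avg[1], avg[5])
  expect_lt(cor(seq_along(avg), avg, method = "spearman"), 0)
})

test_that("QTL variance shares respect symmetry and LD accounting", {
  g <- fixedGenome(markerChrom = 1, markerPos = 1,
                   qtlChrom = c(1, 1), qtlPos = c(2, 3))
  # balanced orthogonal design over 4 animals:
  # QTL1 genotypes (by haplotype pairs) and QTL2 arranged uncorrelated
  qh <- rbind(c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L),
              c(1L, 1L, 1L, 1L, 2L, 1L, 2L, 1L))
  pop <- fixedPop(g, matrix(1L, 1, 8), qh)
  eff <- new("QTLEffects", effects = rbind(c(0, 1, NA, NA), c(0, 1, NA, NA)),
             scaleFactor = 1)
  pop <- computeTbv(pop, eff)
  pop@phenotype <- pop@tbv # define the cohort
  sh <- qtlVarianceShares(pop, eff, cohort = 1:4)
  expect_equal(sh$share, c(50, 50)) # two independent QTLs of equal variance
  expect_equal(sum(sh$share), 100)

  # a single contributing QTL explains 100 %
  effOne <- new("QTLEffects", effects = rbind(c(0, 1, NA, NA), c(0, 0, NA, NA)),
                scaleFactor = 1)
  popOne <- computeTbv(pop, effOne)
  shOne <- qtlVarianceShares(popOne, effOne, cohort = 1:4)
  expect_equal(shOne$share, c(100, 0))

  # perfectly linked duplicate QTLs: shares no longer sum to 100
  qhLD <- rbind(qh[1, ], qh[1, ])
  popLD <- computeTbv(fixedPop(g, matrix(1L, 1, 8), qhLD), eff)
  shLD <- qtlVarianceShares(popLD, eff, cohort = 1:4)
  expect_equal(sum(shLD$share), 50) # 2 var(g) / var(2 g) * 100
})

test_that("window variances partition the genome and scale invariantly", {
  set.seed(52)
  n <- 30
  M <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  map <- data.frame(chrom = c(1, 1, 1, 2, 2, 2), pos = c(0.2, 1.4, 2.5,
                                                         0.3, 0.6, 2.2))
  u <- c(0, 0.5, 0, 0, 0, 0)
  w <- windowVariances(u, M, map, chromLengths = c(3, 3))
  expect_equal(nrow(w), 6L) # 3 windows per chromosome, SNPs or not
  expect_equal(sum(w$nSnps), 6L)
  expect_equal(w$pvar[w$chrom == 1 & w$window == 1], 100)
  expect_equal(sum(w$pvar), 100)
  # doubling effects leaves shares unchanged
  w2 <- windowVariances(2 * u, M, map, chromLengths = c(3, 3))
  expect_equal(w2$pvar, w$pvar)
  # orthogonal windows: shares add to 100
  Mo <- cbind(rep(0:1, each = 8), rep(0:1, times = 8))
  mapo <- data.frame(chrom = c(1, 1), pos = c(0.5, 1.5))
  wo <- windowVariances(c(1, 1), Mo, mapo, chromLengths = 2)
  expect_equal(sum(wo$pvar), 100, tolerance = 1e-9)
})

test_that("top windows are selected deterministically with genomic ties", {
  w <- data.frame(chrom = c(1, 1, 2), window = c(0, 1, 0),
                  start = c(0, 1, 0), end = c(1, 2, 1),
                  nSnps = 1, pvar = c(5, 10, 5))
  top <- topWindows(w, 2)
  expect_equal(top$pvar, c(10, 5))
  expect_equal(top$chrom, c(1, 1)) # tie broken by genomic order
  expect_equal(top$mid, c(1.5, 0.5))
})

test_that("greedy QTL matching counts one-to-one hits within tolerance", {
  # a window midpoint exactly on a QTL counts
  expect_equal(matchTrueQtl(data.frame(chrom = 1, pos = 3.5),
                            data.frame(chrom = 1, mid = 3.5)), 1L)
  # everything farther than 1 Mb: no hits
  expect_equal(matchTrueQtl(data.frame(chrom = 1, pos = c(1, 5)),
                            data.frame(chrom = 1, mid = c(2.5, 7))), 0L)
  # different chromosomes never match
  expect_equal(matchTrueQtl(data.frame(chrom = 1, pos = 2),
                            data.frame(chrom = 2, mid = 2)), 0L)
  # two windows near one QTL contribute one, not two
  expect_equal(matchTrueQtl(data.frame(chrom = 1, pos = c(2, 9)),
                            data.frame(chrom = 1, mid = c(1.8, 2.2, 8.9))),
               2L)
  expect_equal(matchTrueQtl(data.frame(chrom = 1, pos = 2),
                            data.frame(chrom = 1, mid = c(1.8, 2.2))), 1L)
})

test_that("greedy matching equals the exhaustive optimum on small instances", {
  set.seed(53)
  agree <- 0L; total <- 200L
  for (i in seq_len(total)) {
    nw <- sample(1:6, 1); nq <- sample(1:6, 1)
    qtl <- data.frame(chrom = sample(1:2, nq, TRUE), pos = runif(nq, 0, 8))
    win <- data.frame(chrom = sample(1:2, nw, TRUE), mid = runif(nw, 0, 8))
    D <- abs(outer(win$mid, qtl$pos, "-"))
    D[outer(win$chrom, qtl$chrom, "!=")] <- Inf
    greedy <- matchTrueQtl(qtl, win)
    opt <- optimalMatchCount(D, tolerance = 1)
    expect_lte(greedy, opt)
    if (greedy == opt) agree <- agree + 1L
  }
  expect_equal(agree, total)
})

test_that("replicate aggregation reproduces hand-computed summaries", {
  rep1 <- data.frame(cell = c("SIw1", "true"), pvarTop = c(10, 30),
                     pvar1st = c(2, 5), nTrue = c(1, 16))
  rep2 <- data.frame(cell = c("SIw1", "true"), pvarTop = c(12, 34),
                     pvar1st = c(4, 7), nTrue = c(3, 18))
  agg <- aggregateReplicates(list(rep1, rep2))
  i <- agg$cell == "SIw1"
  expect_equal(agg$nTrue_mean[i], 2)
  expect_equal(agg$nTrue_sd[i], sqrt(2), tolerance = 1e-12)
  # identical replicates: zero SD
  agg0 <- aggregateReplicates(list(rep1, rep1))
  expect_true(all(agg0$pvarTop_sd == 0))
  # one replicate: SD is missing
  agg1 <- aggregateReplicates(list(rep1))
  expect_true(all(is.na(agg1$pvarTop_sd)))
  # canonical row order
  cells <- c("true", "SIIw2", "BayesC_pi0.99", "SIw1")
  mk <- function() data.frame(cell = cells, pvarTop = rnorm(4),
                              pvar1st = rnorm(4), nTrue = rpois(4, 2))
  agg2 <- aggregateReplicates(list(mk(), mk()))
  expect_equal(agg2$cell, c("BayesC_pi0.99", "SIw1", "SIIw2", "true"))
  # inconsistent cell sets are rejected
  bad <- data.frame(cell = "SIw2", pvarTop = 1, pvar1st = 1, nTrue = 1)
  expect_error(aggregateReplicates(list(rep1, bad)), "inconsistent")
})
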