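test_that("genome layout obeys the map invariants", {
  g <- makeGenome(12, 300, nMarkers = 600, nQtl = 80, seed = 42)
  expect_equal(length(g@chromLengths), 12)
  expect_equal(sum(g@chromLengths), 300)
  expect_equal(nMarkers(g), 600)
  expect_equal(nQtl(g), 80)
  # strictly increasing within chromosomes, inside bounds
  same <- diff(g@markerChrom) == 0
  expect_true(all(diff(g@markerPos)[same] > 0))
  expect_true(all(g@markerPos >= 0 &
                    g@markerPos <= g@chromLengths[g@markerChrom]))
  expect_true(all(g@qtlAlleleCounts %in% 2:4))
  # mutation mean u = 2 * loci * rate
  expect_equal(mutationMeanU(g), 2 * 680 * 1e-4)
  # counts roughly proportional to length
  perChrom <- tabulate(g@markerChrom, 12)
  expect_true(cor(perChrom, g@chromLengths) > 0.95)
})

test_that("trait variance components are derived consistently", {
  tr <- traitSpec(h2 = 0.3, varP = 2)
  expect_equal(varA(tr) + varE(tr), tr@varP)
  expect_error(traitSpec(h2 = 1.2), "h2")
})

test_that("historical schedules encode the bottleneck design", {
  hld <- historicalSchedule(1000, 1000, 2020, 200)
  # founder generation + 1,000 constant + 2,020 declining = 3,020 bred
  expect_equal(length(hld@sizes) - 1L, 3020L)
  expect_true(hld@hld)
  expect_equal(hld@sizes[1], 1000L)
  expect_equal(tail(hld@sizes, 1), 200L)
  expect_true(all(diff(hld@sizes) <= 0))
  lld <- historicalSchedule(1000, 1000, 1020, 200)
  expect_false(lld@hld)
  expect_equal(length(lld@sizes) - 1L, 2020L)
  expect_error(historicalSchedule(10, 100, 5, 200), "finalSize")
})

test_that("offspring without mutation carry only parental alleles", {
  g <- fixedGenome(markerChrom = rep(1, 5), markerPos = 1:5,
                   qtlChrom = 1, qtlPos = 5.5,
                   qtlAlleleCounts = 4L, mutationRate = 0)
  sched <- historicalSchedule(0, 2, 1, 2, hld = FALSE)
  for (s in 1:5) {
    pop <- simulateHistorical(g, sched, seed = s)
    expect_true(all(pop@markerHap %in% 1:2))
    expect_true(all(pop@qtlHap %in% 1:4))
  }
})

test_that("gene drop without recombination returns whole parental haplotypes", {
  # one chromosome of (near) zero map length: no crossovers can occur, so a
  # gamete must equal one of the parent's two haplotypes (exhaustive check)
  g <- fixedGenome(markerChrom = rep(1, 4), markerPos = (1:4) * 1e-9,
                   qtlChrom = 1, qtlPos = 5e-9, qtlAlleleCounts = 4L,
                   chromLengths = 1e-8)
  mh <- cbind(rep(1L, 4), rep(2L, 4), c(1L, 2L, 1L, 2L), c(2L, 1L, 2L, 1L))
  qh <- matrix(c(1L, 2L, 3L, 4L), 1)
  pop <- fixedPop(g, mh, qh, sex = c("F", "M"))
  cmap <- ssqtl:::.combinedMap(g)
  H <- ssqtl:::.combinedHap(pop, cmap)
  set.seed(1)
  gam <- ssqtl:::.gametes(H, rep(1:2, each = 25), cmap)
  for (j in 1:50) {
    p <- if (j <= 25) 1L else 2L
    expect_true(any(apply(H[, c(2 * p - 1, 2 * p)], 2,
                          function(h) all(h == gam[, j]))))
  }
})

test_that("historical phase ends at the scheduled size with half females", {
  g <- fixedGenome(markerChrom = rep(1, 10), markerPos = 1:10,
                   qtlChrom = 1, qtlPos = 10.5, mutationRate = 1e-3)
  pop <- simulateHistorical(g, historicalSchedule(5, 30, 10, 20, hld = FALSE),
                            seed = 2)
  expect_equal(nrow(pop@pedigree), 20L)
  expect_equal(sum(pop@pedigree$sex == "F"), 10L)
  expect_true(all(pop@pedigree$sire == 0))
})

test_that("segregating-locus selection respects MAF and errors on shortfall", {
  g <- fixedGenome(markerChrom = rep(1, 3), markerPos = 1:3,
                   qtlChrom = 1, qtlPos = 3.5)
  # marker 1 fixed, marker 2 MAF 0.125, marker 3 MAF 0.5; QTL segregating
  mh <- rbind(rep(1L, 8), c(2L, rep(1L, 7)), rep(c(1L, 2L), 4))
  qh <- matrix(rep(c(1L, 2L), 4), 1)
  pop <- fixedPop(g, mh, qh)
  sub <- selectSegregatingLoci(pop, mafMin = 0.2, nMarkers = 1, nQtl = 1)
  expect_equal(nMarkers(sub@genome), 1L)
  expect_equal(sub@genome@markerPos, 3)
  # mafMin = 0: every polymorphic marker eligible
  sub0 <- selectSegregatingLoci(pop, mafMin = 0, nMarkers = 2, nQtl = 1)
  expect_setequal(sub0@genome@markerPos, c(2, 3))
  expect_error(selectSegregatingLoci(pop, 0, nMarkers = 3, nQtl = 1),
               "shortfall")
  # all loci fixed -> no segregating QTLs
  popFix <- fixedPop(g, matrix(1L, 3, 8), matrix(1L, 1, 8))
  expect_error(selectSegregatingLoci(popFix, 0, nMarkers = 1, nQtl = 1),
               "segregating")
})

test_that("QTL effects are rescaled to the exact target additive variance", {
  pop <- randomPop(150, nMarkers = 5, nQtl = 30, seed = 9)
  tr <- traitSpec()
  eff <- assignQtlEffects(pop, tr, seed = 10)
  pop <- computeTbv(pop, eff)
  expect_equal(var(pop@tbv), 0.14, tolerance = 1e-9)
  # zero target -> all-zero effects
  eff0 <- assignQtlEffects(pop, tr, targetVarA = 0, seed = 10)
  expect_true(all(eff0@effects == 0, na.rm = TRUE))
  # monomorphic QTLs -> zero variance -> error
  popFix <- randomPop(10, nQtl = 3, seed = 1)
  popFix@qtlHap[] <- 1L
  expect_error(assignQtlEffects(popFix, tr), "zero genetic variance")
})

test_that("Hardy-Weinberg QTL variance matches genotype enumeration", {
  # single biallelic QTL with effects (0, e): enumerate the three genotypes
  # with binomial weights
  for (p in c(0.1, 0.5, 0.8)) {
    e <- 0.7
    w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    vals <- c(0, e, 2 * e)
    oracle <- sum(w * vals^2) - sum(w * vals)^2
    got <- hweQtlVariance(matrix(c(1 - p, p, 0, 0), 1),
                          matrix(c(0, e, NA, NA), 1))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_equal(oracle, e^2 * 2 * p * (1 - p), tolerance = 1e-12)
  }
})

test_that("phenotypes are sex-limited and add the residual variance", {
  pop <- randomPop(200, nQtl = 10, seed = 4)
  tr <- traitSpec()
  pop <- computeTbv(pop, assignQtlEffects(pop, tr, seed = 5))
  # varE = 0: phenotype equals TBV for females, missing for males
  p0 <- simulatePhenotypes(pop, traitSpec(h2 = 1 - 1e-12), seed = 6)
  f <- p0@pedigree$sex == "F"
  expect_equal(p0@phenotype[f], p0@tbv[f], tolerance = 1e-5)
  expect_true(all(is.na(p0@phenotype[!f])))
  # residual variance 0.86 = (1 - 0.14) * 1.0
  expect_equal(varE(tr), 0.86)
})

test_that("offspring phenotype regresses on mid-parent TBV with slope one", {
  set.seed(11)
  pop <- randomPop(300, nMarkers = 2, nQtl = 40)
  tr <- traitSpec()
  eff <- assignQtlEffects(pop, tr, seed = 12)
  pop <- computeTbv(pop, eff)
  cmap <- ssqtl:::.combinedMap(pop@genome)
  H <- ssqtl:::.combinedHap(pop, cmap)
  nTrio <- 10000
  sires <- sample(which(pop@pedigree$sex == "M"), nTrio, replace = TRUE)
  dams <- sample(which(pop@pedigree$sex == "F"), nTrio, replace = TRUE)
  Ho <- matrix(0L, cmap$nLoci, 2 * nTrio)
  Ho[, seq(1, 2 * nTrio, 2)] <- ssqtl:::.gametes(H, sires, cmap)
  Ho[, seq(2, 2 * nTrio, 2)] <- ssqtl:::.gametes(H, dams, cmap)
  tbvOff <- ssqtl:::.tbvFromHaplotypes(Ho[cmap$qtlRows, , drop = FALSE],
                                       eff@effects)
  phenOff <- tbvOff + rnorm(nTrio, 0, sqrt(varE(tr)))
  midParent <- (pop@tbv[sires] + pop@tbv[dams]) / 2
  slope <- coef(lm(phenOff ~ midParent))[2]
  expect_equal(unname(slope), 1, tolerance = 0.2)
})

test_that("expansion bookkeeping and mechanics follow the design", {
  sched <- expansionSchedule(100, 6, 5)
  expect_equal(expansionCohortSizes(sched)[1], 500L)
  expect_equal(tail(expansionCohortSizes(sched), 1), 16000L)
  expect_equal(sched@damCounts, as.integer(100 * 2^(0:5)))
  expect_equal(selectionTotalAnimals(selectionSchedule(15, 240, 6000)),
               90000L)

  pop <- randomPop(40, nMarkers = 10, nQtl = 5, seed = 21)
  # zero generations: unchanged
  expect_identical(simulateExpansion(pop, expansionSchedule(10, 0)), pop)
  ex <- simulateExpansion(pop, expansionSchedule(8, 3, 5), seed = 22)
  expect_equal(nrow(ex@pedigree), 40L + 8L * 5L + 16L * 5L + 32L * 5L)
  g3 <- ex@pedigree[ex@pedigree$generation == 3, ]
  expect_equal(nrow(g3), 160L)
  # parents always from the immediately preceding generation
  for (gg in 1:3) {
    cohort <- ex@pedigree[ex@pedigree$generation == gg, ]
    expect_true(all(ex@pedigree$generation[cohort$sire] == gg - 1))
    expect_true(all(ex@pedigree$generation[cohort$dam] == gg - 1))
  }
})

test_that("selection keeps parents fixed when replacement is zero", {
  pop <- randomPop(60, nMarkers = 10, nQtl = 8, seed = 31)
  tr <- traitSpec()
  eff <- assignQtlEffects(pop, tr, seed = 32)
  pop <- computeTbv(pop, eff)
  sched <- selectionSchedule(3, 5, 20, replacementRate = 0)
  sel <- simulateSelection(pop, tr, eff, sched, seed = 33)
  ped <- sel@pedigree
  s1 <- unique(ped$sire[ped$generation == 1])
  d1 <- sort(unique(ped$dam[ped$generation == 1]))
  for (gg in 2:3) {
    expect_true(all(ped$sire[ped$generation == gg] %in% s1))
    expect_equal(sort(unique(ped$dam[ped$generation == gg])), d1)
  }
  expect_equal(sum(ped$generation > 0), 60L)
})

test_that("truncation selection on EBV yields a positive response", {
  gains <- replicate(10, {
    pop <- randomPop(80, nMarkers = 6, nQtl = 25)
    tr <- traitSpec(h2 = 0.3)
    eff <- assignQtlEffects(pop, tr)
    pop <- computeTbv(pop, eff)
    sel <- simulateSelection(pop, tr, eff,
                             selectionSchedule(4, 8, 30, 0.5))
    ped <- sel@pedigree
    mean(sel@tbv[ped$generation == 4]) - mean(sel@tbv[ped$generation == 1])
  })
  expect_gt(mean(gains), 0)
})

test_that("pedigrees are generation-sorted and acyclic", {
  st <- smallStudy()
  ped <- st$pop@pedigree
  nf <- ped$sire > 0
  expect_true(all(ped$sire[nf] < ped$id[nf]))
  expect_true(all(ped$dam[ped$dam > 0] < ped$id[ped$dam > 0]))
  expect_true(validObject(st$pop))
  # genotyped animals are phenotyped females of the last generations
  gid <- which(st$pop@genotyped)
  expect_true(all(ped$sex[gid] == "F"))
  expect_true(all(!is.na(st$pop@phenotype[gid])))
})

test_that("allele frequencies drift without systematic change", {
  # no mutation, no selection: expected frequency change per generation is 0
  cnt <- simulateAlleleDrift(3000, sizes = rep(50, 31), alleleCounts = 2L,
                             mutationRate = 0, seed = 44)
  p <- cnt[, 1] / rowSums(cnt)
  expect_equal(mean(p), 0.5, tolerance = 0.02)
  # and a fixed locus stays fixed
  expect_true(all(rowSums(cnt) == 100))
})

test_that("the longer bottleneck erodes more heterozygosity", {
  long <- simulateAlleleDrift(2000, historicalSchedule(50, 80, 120, 30)@sizes,
                              mutationRate = 1e-4, seed = 45)
  short <- simulateAlleleDrift(2000, historicalSchedule(50, 80, 60, 30)@sizes,
                               mutationRate = 1e-4, seed = 46)
  het <- function(cnt) {
    p <- cnt / rowSums(cnt)
    mean(1 - rowSums(p^2))
  }
  expect_lt(het(long), het(short))
})

test_that("realized heritability of unselected cohorts matches the design", {
  set.seed(77)
  h2 <- replicate(10, realizedH2Once())
  se <- sd(h2) / sqrt(length(h2))
  expect_lt(abs(mean(h2) - 0.14), 2 * se + 1e-12)
})
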