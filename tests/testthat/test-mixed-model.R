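test_that("MME solutions obey the closed forms of simple animal models", {
  # unrelated animals, one record each, mean + animal:
  # beta = mean(y), a_i = (y_i - mean(y)) / (1 + lambda)
  y <- c(1.2, -0.4, 0.7, 2.1)
  lambda <- 0.86 / 0.14
  fit <- solveMME(y, animal = 1:4, Kinv = Matrix::Diagonal(4), lambda = lambda)
  expect_equal(fit@betaHat, mean(y), tolerance = 1e-10)
  expect_equal(unname(fit@aHat), (y - mean(y)) / (1 + lambda),
               tolerance = 1e-10)
  expect_true(fit@converged)
  expect_lt(fit@residualNorm, 1e-10)

  # infinite shrinkage: breeding values vanish, beta -> least squares
  X <- cbind(1, c(0, 0, 1, 1))
  fitInf <- solveMME(y, X, animal = 1:4, Kinv = Matrix::Diagonal(4), lambda = 1e12)
  expect_equal(max(abs(fitInf@aHat)), 0, tolerance = 1e-6)
  expect_equal(fitInf@betaHat, unname(coef(lm(y ~ 0 + X))), tolerance = 1e-4)
})

test_that("ssGBLUP collapses to pedigree BLUP when Gb equals A22", {
  ped <- randomPedigree(60, seed = 15)
  geno <- 41:60
  Ainv <- buildAinv(ped)
  A22 <- buildA22(ped, geno)
  Hinv <- buildHinv(Ainv, A22, A22, geno)
  set.seed(16)
  rec <- sample(10:60, 35)
  y <- rnorm(35)
  fitA <- solveMME(y, animal = rec, Kinv = Ainv, lambda = 3)
  fitH <- solveMME(y, animal = rec, Kinv = Hinv, lambda = 3)
  expect_equal(fitA@aHat, fitH@aHat, tolerance = 1e-8)
  expect_equal(fitA@betaHat, fitH@betaHat, tolerance = 1e-8)
})

test_that("conjugate-gradient and direct solvers agree", {
  ped <- randomPedigree(150, seed = 17)
  Ainv <- buildAinv(ped)
  set.seed(18)
  rec <- sample(50:150, 80)
  y <- rnorm(80)
  d <- solveMME(y, animal = rec, Kinv = Ainv, lambda = 2)
  cg <- solveMME(y, animal = rec, Kinv = Ainv, lambda = 2, cgThreshold = 0)
  expect_true(cg@converged)
  expect_equal(d@aHat, cg@aHat, tolerance = 1e-6)
})

test_that("rank-deficient fixed effects are constrained with a warning", {
  y <- rnorm(6)
  X <- cbind(1, c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1)) # singular
  expect_warning(
    fit <- solveMME(y, X, animal = 1:6, Kinv = Matrix::Diagonal(6), lambda = 5),
    "rank-deficient")
  expect_lt(fit@residualNorm, 1e-8)
})

test_that("phenotype pre-adjustment removes known fixed effects", {
  # mean only: centring
  y <- c(3, 5, 10)
  expect_equal(preadjustPhenotypes(y, matrix(1, 3, 1), mean(y)),
               y - mean(y))
  # two-level factor with known effects (10, 20): residuals recovered exactly
  set.seed(19)
  lev <- rep(1:2, each = 8)
  X <- cbind(as.numeric(lev == 1), as.numeric(lev == 2))
  e <- rnorm(16)
  yk <- X %*% c(10, 20) + e
  expect_equal(preadjustPhenotypes(yk, X, c(10, 20)), e, tolerance = 1e-12)
  expect_error(preadjustPhenotypes(yk, X, c(10, NA)), "level")
  expect_error(preadjustPhenotypes(yk, X, 10), "one solution per")
})

test_that("back-solved SNP effects satisfy the projection identity", {
  set.seed(20)
  n <- 15; m <- 40
  M <- matrix(rbinom(n * m, 2, 0.4), n, m)
  # centring at the generating (not observed) frequencies keeps P D P'
  # full-rank; observed frequencies make it exactly singular (1'P = 0)
  fr <- rep(0.4, m)
  aG <- rnorm(n)
  u <- backsolveSnpEffects(aG, M, freqs = fr, blend = 0)
  P <- sweep(M, 2, 2 * fr)
  expect_lt(max(abs(P %*% u - aG)), 1e-6)
  # zero breeding values give zero effects
  expect_equal(backsolveSnpEffects(rep(0, n), M, freqs = fr, blend = 0),
               rep(0, m))
  # a zero weight forces a zero effect
  d <- rep(1, m); d[c(3, 17)] <- 0
  u0 <- backsolveSnpEffects(aG, M, d = d, freqs = fr, blend = 0)
  expect_equal(u0[c(3, 17)], c(0, 0))
  expect_error(backsolveSnpEffects(aG[-1], M), "one entry per")
  # observed frequencies: singular system is reported
  expect_error(backsolveSnpEffects(aG, M, blend = 0), "blend")
})

test_that("weight updates follow d ~ u^2 2pq with conserved total", {
  # equal effects and frequencies: identity weights
  expect_equal(updateSnpWeights(rep(0.3, 5), rep(0.2, 5)), rep(1, 5))
  # u = (1, 0), p = (0.5, 0.5): d = (2, 0)
  expect_equal(updateSnpWeights(c(1, 0), c(0.5, 0.5)), c(2, 0))
  # normalisation conserves sum(d) = m exactly
  set.seed(21)
  u <- rnorm(30); p <- runif(30, 0.05, 0.95)
  expect_equal(sum(updateSnpWeights(u, p)), 30)
  expect_error(updateSnpWeights(rep(0, 4), rep(0.5, 4)), "degenerate")
})

test_that("genotyped-only GBLUP equals ridge regression on markers", {
  set.seed(22)
  n <- 30; m <- 50
  pgen <- runif(m, 0.2, 0.8)
  M <- matrix(rbinom(n * m, 2, pgen), n, m, byrow = TRUE)
  freqs <- pgen # generating frequencies keep G invertible
  P <- sweep(M, 2, 2 * freqs)
  cc <- sum(2 * freqs * (1 - freqs))
  G <- P %*% t(P) / cc
  y <- rnorm(n, sd = 1)
  lambda <- 4
  fit <- solveMME(y, animal = 1:n, Kinv = solve(G), lambda = lambda)
  # matched ridge: y = 1 mu + P alpha + e, alpha penalised by lambda * c
  or <- ridgeOracle(y, P, lambda * cc)
  expect_equal(unname(fit@aHat), as.vector(P %*% or$b), tolerance = 1e-6)
  expect_equal(fit@betaHat, or$mu, tolerance = 1e-6)
  # and the back-solved effects are the ridge coefficients
  u <- backsolveSnpEffects(fit@aHat, M, freqs = freqs, blend = 0)
  expect_equal(u, unname(or$b), tolerance = 1e-6)
})

test_that("scenarios coincide when every phenotyped animal is genotyped", {
  pop <- randomPop(40, nMarkers = 60, nQtl = 10, seed = 23)
  tr <- traitSpec()
  eff <- assignQtlEffects(pop, tr, seed = 24)
  pop <- computeTbv(pop, eff)
  pop <- simulatePhenotypes(pop, tr, seed = 25)
  pop@genotyped <- !is.na(pop@phenotype) # genotyped = phenotyped females
  fitSI <- runWssGBLUP(pop, tr, "SI", nIterations = 2)
  fitSII <- runWssGBLUP(pop, tr, "SII", nIterations = 2)
  expect_equal(fitSI$uHat, fitSII$uHat, tolerance = 1e-8)
})

test_that("weight iterations run with identity start and shared genotypes", {
  st <- smallStudy()
  fit <- runWssGBLUP(st$pop, st$trait, "SI", nIterations = 3)
  # w1 uses identity weights
  expect_equal(fit$d[, 1], rep(1, nrow(fit$d)))
  # normalisation is conserved across iterations
  expect_equal(colSums(fit$d), rep(nrow(fit$d), 3))
  # increasing concentration of weights from w1 to w3
  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    2 * sum(x * seq_len(n)) / (n * sum(x)) - (n + 1) / n
  }
  g <- apply(fit$d, 2, gini)
  expect_true(all(diff(g) >= -1e-12))
  # solver met its tolerance in every iteration
  for (f in fit$fits) expect_lt(f@residualNorm, 1e-8)
})
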