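#' Solve Henderson's mixed-model equations
#'
#' Fits y = X beta + Z a + e with var(a) = K sigma2_a and var(e) = I sigma2_e
#' by solving
#' \deqn{[X'X, X'Z; Z'X, Z'Z + K^{-1}\lambda] [\beta; a] = [X'y; Z'y]}
#' where lambda = sigma2_e / sigma2_a. `Kinv` may be a pedigree inverse
#' (A^-1, regular BLUP) or a single-step inverse (H^-1, ssGBLUP). The system
#' is solved by a direct sparse factorisation up to `cgThreshold` unknowns and
#' by Jacobi-preconditioned conjugate gradients above it.
#'
#' Rank-deficient fixed effects are handled by zeroing the dependent columns
#' (the corresponding solutions are constrained to 0) with a warning.
#'
#' @param y phenotype vector.
#' @param X fixed-effect incidence matrix (rows = records); defaults to an
#'   overall mean.
#' @param animal animal id (row of `Kinv`) for each record.
#' @param Kinv inverse relationship matrix over all animals.
#' @param lambda variance ratio sigma2_e / sigma2_a; must be positive.
#' @param tol relative-residual tolerance of the iterative solver.
#' @param cgThreshold number of unknowns above which conjugate gradients are
#'   used instead of a direct solve.
#' @return an [MMEResult-class].
#' @export
solveMME <- function(y, X = NULL, animal, Kinv, lambda,
                     tol = 1e-10, cgThreshold = 5e4) {
  nrec <- length(y)
  if (is.null(X)) X <- matrix(1, nrec, 1)
  if (nrow(X) != nrec || length(animal) != nrec)
    stop("X and animal must have one row/entry per record")
  if (lambda <= 0) stop("lambda must be positive")
  nAnim <- nrow(Kinv)
  if (any(animal < 1 | animal > nAnim))
    stop("animal indices must address rows of Kinv")

  X <- Matrix::Matrix(X, sparse = TRUE)
  Z <- sparseMatrix(i = seq_len(nrec), j = animal, x = 1,
                    dims = c(nrec, nAnim))
  XtX <- Matrix::crossprod(X)
  p <- ncol(X)
  qrX <- qr(as.matrix(XtX))
  drop <- integer()
  if (qrX$rank < p) {
    drop <- sort(qrX$pivot[(qrX$rank + 1L):p])
    warning(sprintf("fixed effects rank-deficient; constraining %d solution(s) to zero (column %s)",
                    length(drop), paste(drop, collapse = ", ")))
    X[, drop] <- 0
    XtX <- Matrix::crossprod(X)
  }
  LHS <- rbind(
    cbind(XtX, Matrix::crossprod(X, Z)),
    cbind(Matrix::crossprod(Z, X), Matrix::crossprod(Z) + lambda * Kinv))
  if (length(drop)) LHS[cbind(drop, drop)] <- 1
  rhs <- c(as.vector(Matrix::crossprod(X, y)), as.vector(Matrix::crossprod(Z, y)))

  nUnk <- p + nAnim
  if (nUnk <= cgThreshold) {
    # the MME are symmetric positive definite: sparse Cholesky
    LHSs <- Matrix::forceSymmetric(LHS)
    sol <- tryCatch(as.vector(Matrix::solve(Matrix::Cholesky(LHSs, LDL = FALSE),
                                            rhs, system = "A")),
                    error = function(e) as.vector(Matrix::solve(LHS, rhs)))
    converged <- TRUE
  } else {
    cg <- .pcgSolve(LHS, rhs, tol = tol)
    sol <- cg$x
    converged <- cg$converged
  }
  res <- sqrt(sum((as.vector(LHS %*% sol) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  new("MMEResult",
      betaHat = sol[seq_len(p)],
      aHat = setNames(sol[p + seq_len(nAnim)], rownames(Kinv) %||% seq_len(nAnim)),
      converged = converged && res <= max(tol, 1e-8),
      residualNorm = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jacobi-preconditioned conjugate gradients for the (symmetric PD) MME.
.pcgSolve <- function(A, b, tol = 1e-10, maxit = 5000L) {
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / nb <= tol)
      return(list(x = x, converged = TRUE, iterations = it))
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  list(x = x, converged = FALSE, iterations = maxit)
}

#' Pre-adjust phenotypes for fixed effects estimated elsewhere
#'
#' Subtracts X beta using fixed-effect solutions from a previous analysis
#' (typically a regular BLUP on all available phenotypes), so that a
#' genotyped-only analysis can fit an overall mean alone.
#'
#' @param y phenotypes of the records to adjust.
#' @param X their fixed-effect incidence matrix.
#' @param betaFull fixed-effect solutions from the full-data analysis.
#' @return adjusted phenotype vector y - X betaFull.
#' @export
preadjustPhenotypes <- function(y, X, betaFull) {
  X <- as.matrix(X)
  if (ncol(X) != length(betaFull))
    stop("betaFull must have one solution per fixed-effect column")
  if (anyNA(betaFull[colSums(abs(X)) > 0]))
    stop("a fixed-effect level present in the records has no solution in betaFull")
  as.vector(y - X %*% ifelse(is.na(betaFull), 0, betaFull))
}

#' Back-solve SNP effects from genomic breeding values
#'
#' Converts predicted breeding values of genotyped animals into allele
#' substitution effects: u = D P' (P D P')^-1 a_g, with P the centred dosage
#' matrix and D the SNP weights. With `blend > 0` the inverted matrix is the
#' blended genomic matrix used in the single-step solve,
#' Gb = (1-blend) P D P'/c + blend A22 (c = sum 2pq), and
#' u = ((1-blend)/c) D P' Gb^-1 a_g, which reduces to the plain identity at
#' blend = 0.
#'
#' @param aG predicted breeding values of the genotyped animals.
#' @param M dosage matrix of the genotyped animals (0/1/2), same order.
#' @param d per-SNP weights (diagonal of D).
#' @param freqs allele frequencies used to centre `M` and scale G.
#' @param blend A22 blending fraction matching the G used in the solve.
#' @param A22 pedigree relationship block (required when blend > 0).
#' @return vector of SNP effects, one per column of `M`.
#' @export
backsolveSnpEffects <- function(aG, M, d = rep(1, ncol(M)), freqs = NULL,
                                blend = 0, A22 = NULL) {
  if (length(aG) != nrow(M))
    stop("aG must have one entry per genotyped animal")
  if (length(d) != ncol(M)) stop("one weight per SNP is required")
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  P <- sweep(M, 2L, 2 * freqs)
  cc <- sum(2 * freqs * (1 - freqs))
  GD <- tcrossprod(sweep(P, 2L, d, "*"), P) / cc
  if (blend > 0) {
    if (is.null(A22)) stop("A22 is required when blend > 0")
    Gb <- (1 - blend) * GD + blend * A22
  } else Gb <- GD
  sol <- tryCatch(base::solve(Gb, aG), error = function(e)
    stop("P D P' is singular; use a positive blend", call. = FALSE))
  as.vector(((1 - blend) / cc) * d * base::crossprod(P, sol))
}

#' Update SNP weights from estimated effects
#'
#' Weighted single-step iteration rule: d_i proportional to
#' u_i^2 2 p_i (1 - p_i), rescaled so the weights sum to the number of SNPs
#' (keeping the total genetic variance constant across iterations).
#'
#' @param uHat SNP effects from the previous iteration.
#' @param freqs allele frequencies.
#' @return normalised weight vector.
#' @export
updateSnpWeights <- function(uHat, freqs) {
  d <- uHat^2 * 2 * freqs * (1 - freqs)
  s <- sum(d)
  if (!is.finite(s) || s <= 0)
    stop("degenerate SNP weights: all estimated effects are zero")
  d * length(d) / s
}

#' Weighted single-step GBLUP GWAS
#'
#' Runs the iterative weighting scheme: solve the single-step mixed model with
#' H^-1 built from the current SNP weights, back-solve SNP effects from the
#' genotyped animals' predicted breeding values, recompute the weights, and
#' repeat. Iteration w1 uses identity weights. Scenario "SI" uses all
#' available phenotypes (including those of non-genotyped animals); "SII"
#' restricts the records to the genotyped animals. Both scenarios consume the
#' identical pedigree and genotypes.
#'
#' @param pop a [Population-class] with phenotypes and genotyped flags.
#' @param trait a [TraitSpec-class] supplying the variance ratio.
#' @param scenario "SI" or "SII".
#' @param nIterations number of weight iterations (3: w1, w2, w3).
#' @param blend A22 fraction blended into G.
#' @param yAdjusted optional pre-adjusted phenotypes for the genotyped
#'   animals (scenario SII with external fixed effects); by default the raw
#'   phenotypes are used and the model fits an overall mean.
#' @return list of class `wssgblupFit`: `uHat` (SNPs x iterations matrix),
#'   `d` (weights used per iteration), `aG` per iteration, `genoIds`, `freqs`,
#'   `fits` (the [MMEResult-class] objects).
#' @export
runWssGBLUP <- function(pop, trait, scenario = c("SI", "SII"),
                        nIterations = 3L, blend = 0.05, yAdjusted = NULL) {
  scenario <- match.arg(scenario)
  ped <- pop@pedigree
  genoIds <- which(pop@genotyped)
  if (!length(genoIds)) stop("no genotyped animals in the population")
  M <- markerDosage(pop, genoIds)
  freqs <- colMeans(M) / 2
  poly <- freqs > 0 & freqs < 1
  Mp <- M[, poly, drop = FALSE]
  fp <- freqs[poly]

  rec <- if (scenario == "SI") which(!is.na(pop@phenotype)) else
    genoIds[!is.na(pop@phenotype[genoIds])]
  if (!length(rec)) stop("no phenotype records for scenario ", scenario)
  y <- if (scenario == "SII" && !is.null(yAdjusted)) yAdjusted else
    pop@phenotype[rec]

  Ainv <- buildAinv(ped)
  A22 <- buildA22(ped, genoIds)
  lambda <- varRatio(trait)

  m <- ncol(Mp)
  d <- rep(1, m)
  uHat <- matrix(0, ncol(M), nIterations,
                 dimnames = list(colnames(M), paste0("w", seq_len(nIterations))))
  dHist <- matrix(0, m, nIterations)
  aGs <- matrix(0, length(genoIds), nIterations)
  fits <- vector("list", nIterations)

  for (it in seq_len(nIterations)) {
    dHist[, it] <- d
    G <- buildG(Mp, fp, weights = d)
    Hinv <- buildHinv(Ainv, G, A22, genoIds, blend = blend)
    fit <- solveMME(y, X = matrix(1, length(rec), 1), animal = rec,
                    Kinv = Hinv, lambda = lambda)
    aG <- fit@aHat[genoIds]
    u <- backsolveSnpEffects(aG, Mp, d = d, freqs = fp, blend = blend,
                             A22 = A22)
    uHat[poly, it] <- u
    aGs[, it] <- aG
    fits[[it]] <- fit
    if (it < nIterations) d <- updateSnpWeights(u, fp)
  }

  structure(list(uHat = uHat, d = dHist, aG = aGs, genoIds = genoIds,
                 freqs = freqs, poly = poly, scenario = scenario,
                 fits = fits),
            class = "wssgblupFit")
}
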