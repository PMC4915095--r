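#' Configuration of a Bayes C analysis
#'
#' The inclusion fraction is parameterised by `piExcluded`, the prior fraction
#' of SNPs NOT in the model, held essentially fixed through beta pseudo-counts
#' oriented so the prior mean equals `piExcluded` (with `pseudoCount` total
#' weight the data cannot move it). Defaults are the full-scale chain
#' settings: 550,000 iterations, 50,000 burn-in, thinning 50, giving 10,000
#' kept samples.
#'
#' @param piExcluded prior fraction of SNPs excluded (0.99 or 0.999).
#' @param chainLength,burnIn,thin MCMC chain settings.
#' @param nu prior degrees of freedom of the scaled inverse chi-squared
#'   priors on the SNP-effect and residual variances.
#' @param pseudoCount total beta pseudo-count pinning the inclusion fraction.
#' @return list of class `bayesCConfig`.
#' @export
bayesCConfig <- function(piExcluded = 0.99, chainLength = 550000L,
                         burnIn = 50000L, thin = 50L, nu = 4.2,
                         pseudoCount = 1e10) {
  if (piExcluded < 0 || piExcluded > 1)
    stop("piExcluded must be in [0, 1]")
  if (burnIn >= chainLength) stop("burn-in must be shorter than the chain")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(piExcluded = piExcluded, chainLength = as.integer(chainLength),
                 burnIn = as.integer(burnIn), thin = as.integer(thin),
                 nu = nu, pseudoCount = pseudoCount),
            class = "bayesCConfig")
}

#' Number of kept posterior samples of a chain
#' @param config a [bayesCConfig()].
#' @export
keptSamples <- function(config) {
  (config$chainLength - config$burnIn) %/% config$thin
}

#' Bayes C marker-effect model by Gibbs sampling
#'
#' Fits y = 1 mu + sum_i g_i b_i delta_i + e on genotyped animals: each SNP's
#' inclusion indicator is sampled from its full conditional with the effect
#' integrated out, the effect of an included SNP from its normal full
#' conditional, and the variances from scaled inverse chi-squared full
#' conditionals. SNPs are visited in fixed index order, so a chain is
#' reproducible from the seed. Prior scales default to
#' varA / ((1 - pi) sum 2 p q) for the SNP-effect variance and varE for the
#' residual variance.
#'
#' @param y phenotypes of the genotyped animals (pre-adjusted, or raw with
#'   the overall mean absorbing fixed effects).
#' @param M dosage matrix (0/1/2), animals x SNPs, rows matching `y`.
#' @param config a [bayesCConfig()].
#' @param trait a [TraitSpec-class] from which prior scales are derived.
#' @param seed optional RNG seed.
#' @param fixVariances hold the variances at their starting values (used for
#'   closed-form cross-checks).
#' @param varG0,varE0 starting (and, with `fixVariances`, fixed) variances;
#'   default to the prior scales.
#' @return a [BayesCPosterior-class]. Monomorphic SNPs get effect 0 and
#'   inclusion frequency 0.
#' @export
runBayesC <- function(y, M, config = bayesCConfig(), trait = traitSpec(),
                      seed = NULL, fixVariances = FALSE,
                      varG0 = NULL, varE0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(y) != nrow(M)) stop("y must have one entry per row of M")
  if (anyNA(y)) stop("missing phenotypes are not allowed")

  freqs <- colMeans(M) / 2
  poly <- freqs > 0 & freqs < 1
  Mp <- M[, poly, drop = FALSE]
  fp <- freqs[poly]
  m <- ncol(Mp)
  if (!m) stop("no polymorphic SNPs")

  sum2pq <- sum(2 * fp * (1 - fp))
  scaleG <- varA(trait) / (max(1 - config$piExcluded, 1e-12) * sum2pq)
  scaleE <- varE(trait)
  if (is.null(varG0)) varG0 <- scaleG
  if (is.null(varE0)) varE0 <- scaleE

  res <- cpp_bayesc(Mp * 1.0, as.numeric(y),
                    config$piExcluded, config$pseudoCount,
                    config$chainLength, config$burnIn, config$thin,
                    config$nu, scaleG, config$nu, scaleE,
                    varG0, varE0, fixVariances)

  eff <- numeric(ncol(M)); eff[poly] <- res$snpEffect
  incl <- numeric(ncol(M)); incl[poly] <- res$inclusionProb
  new("BayesCPosterior", snpEffect = eff, inclusionProb = incl,
      mu = res$mu, varG = res$varG, varE = res$varE,
      nKept = as.integer(res$nKept))
}
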