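#' @useDynLib ssqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm rbinom rpois rgamma runif var cor sd setNames
#' @importFrom utils head tail
NULL

#' Genome layout for the simulated populations
#'
#' A `GenomeSpec` describes the autosomes, the map positions of marker and QTL
#' loci (cM within chromosome) and the recurrent mutation rate used during the
#' historical phase. Markers are biallelic; each QTL segregates 2--4 alleles.
#'
#' @slot nChromosomes number of autosomes.
#' @slot chromLengths chromosome lengths in cM; their sum is the genome length.
#' @slot markerChrom,markerPos chromosome index and cM position per marker.
#' @slot qtlChrom,qtlPos chromosome index and cM position per QTL.
#' @slot qtlAlleleCounts number of alleles (2--4) per QTL locus.
#' @slot mutationRate per-locus, per-gamete mutation probability.
#'
#' @export
setClass("GenomeSpec",
  representation(
    nChromosomes = "integer",
    chromLengths = "numeric",
    markerChrom = "integer",
    markerPos = "numeric",
    qtlChrom = "integer",
    qtlPos = "numeric",
    qtlAlleleCounts = "integer",
    mutationRate = "numeric"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@chromLengths) != object@nChromosomes)
    msg <- c(msg, "chromLengths must have one entry per chromosome")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  for (loci in list(cbind(object@markerChrom, object@markerPos),
                    cbind(object@qtlChrom, object@qtlPos))) {
    if (nrow(loci) == 0) next
    if (any(loci[, 1] < 1 | loci[, 1] > object@nChromosomes))
      msg <- c(msg, "locus chromosome index out of range")
    ord <- order(loci[, 1], loci[, 2])
    if (!identical(ord, seq_len(nrow(loci))))
      msg <- c(msg, "loci must be sorted by chromosome and position")
    d <- diff(loci[, 2])
    same <- diff(loci[, 1]) == 0
    if (any(d[same] <= 0))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
    if (any(loci[, 2] < 0 | loci[, 2] > object@chromLengths[loci[, 1]]))
      msg <- c(msg, "positions must lie within their chromosome")
  }
  if (length(object@qtlAlleleCounts) != length(object@qtlPos))
    msg <- c(msg, "one allele count per QTL is required")
  if (any(object@qtlAlleleCounts < 2L | object@qtlAlleleCounts > 4L))
    msg <- c(msg, "QTL allele counts must be in [2, 4]")
  if (object@mutationRate < 0 || object@mutationRate >= 1)
    msg <- c(msg, "mutationRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Trait architecture
#'
#' Heritability, phenotypic variance and the gamma shape of QTL allele
#' effects. Additive and residual variances are derived:
#' \eqn{\sigma^2_a = h^2 \sigma^2_p}, \eqn{\sigma^2_e = \sigma^2_p - \sigma^2_a}.
#'
#' @slot h2 narrow-sense heritability, in (0, 1).
#' @slot varP phenotypic variance, trait units squared.
#' @slot gammaShape shape of the gamma distribution of QTL allele effects.
#' @export
setClass("TraitSpec",
  representation(h2 = "numeric", varP = "numeric", gammaShape = "numeric")
)

setValidity("TraitSpec", function(object) {
  msg <- character()
  if (object@h2 <= 0 || object@h2 >= 1) msg <- c(msg, "h2 must be in (0, 1)")
  if (object@varP <= 0) msg <- c(msg, "varP must be positive")
  if (object@gammaShape <= 0) msg <- c(msg, "gammaShape must be positive")
  if (length(msg)) msg else TRUE
})

#' Demographic schedule for one simulation phase
#'
#' One of three phases: `historical` (random mating with a bottleneck that
#' builds up drift and LD), `expansion` (exponential growth of the dam
#' population under random mating) and `selection` (truncation selection on
#' EBV with overlapping parent generations).
#'
#' @slot phase one of "historical", "expansion", "selection".
#' @slot sizes historical phase: cohort size per generation.
#' @slot hld historical phase: TRUE when the long (high-LD) bottleneck is used.
#' @slot damCounts expansion phase: dams mated in each generation.
#' @slot offspringPerDam expansion phase: products per dam (5).
#' @slot nGenerations selection phase: number of generations.
#' @slot nSires,nDams selection phase: parents in service each generation.
#' @slot replacementRate selection phase: fraction of parents replaced per
#'   generation by top-EBV candidates.
#' @export
setClass("PopSchedule",
  representation(
    phase = "character",
    sizes = "integer",
    hld = "logical",
    damCounts = "integer",
    offspringPerDam = "integer",
    nGenerations = "integer",
    nSires = "integer",
    nDams = "integer",
    replacementRate = "numeric"
  ),
  prototype(
    sizes = integer(), hld = NA, damCounts = integer(),
    offspringPerDam = 5L, nGenerations = 0L, nSires = 0L, nDams = 0L,
    replacementRate = 0.2
  )
)

setValidity("PopSchedule", function(object) {
  msg <- character()
  if (!object@phase %in% c("historical", "expansion", "selection"))
    msg <- c(msg, "unknown phase")
  if (object@phase == "historical") {
    if (length(object@sizes) < 1 || any(object@sizes < 2))
      msg <- c(msg, "historical sizes must all be >= 2")
    n <- length(object@sizes)
    if (n > 1 && any(diff(object@sizes) > 0))
      msg <- c(msg, "historical size path must be non-increasing")
  }
  if (object@phase == "expansion") {
    if (length(object@damCounts) > 1 &&
        !all(object@damCounts[-1] == 2L * head(object@damCounts, -1)))
      msg <- c(msg, "expansion dam counts must double each generation")
    if (any(object@damCounts < 1)) msg <- c(msg, "dam counts must be positive")
    if (object@offspringPerDam < 1)
      msg <- c(msg, "offspringPerDam must be positive")
  }
  if (object@phase == "selection") {
    if (object@nGenerations < 0) msg <- c(msg, "nGenerations must be >= 0")
    if (object@nSires < 1 || object@nDams < 1)
      msg <- c(msg, "selection phase needs sires and dams")
    if (object@replacementRate < 0 || object@replacementRate > 1)
      msg <- c(msg, "replacementRate must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' A simulated population
#'
#' Holds the pedigree, phased marker and QTL haplotypes, true breeding values,
#' phenotypes and genotyping flags of every animal, together with the genome
#' the haplotypes refer to. Haplotype matrices have one row per locus and two
#' columns per animal (columns `2k - 1` and `2k` belong to animal `k`).
#'
#' @slot pedigree data.frame with columns id, sire, dam, sex ("M"/"F"),
#'   generation; founders have sire = dam = 0.
#' @slot markerHap,qtlHap integer matrices, loci by (2 x animals). Marker
#'   alleles are coded 1/2; QTL alleles 1..4.
#' @slot tbv true breeding value per animal (NA until QTL effects exist).
#' @slot phenotype trait value per animal; NA for males (sex-limited trait)
#'   and for unphenotyped cohorts.
#' @slot genotyped flag per animal.
#' @slot genome the [GenomeSpec-class] the haplotypes refer to.
#' @export
setClass("Population",
  representation(
    pedigree = "data.frame",
    markerHap = "matrix",
    qtlHap = "matrix",
    tbv = "numeric",
    phenotype = "numeric",
    genotyped = "logical",
    genome = "GenomeSpec"
  )
)

setValidity("Population", function(object) {
  msg <- character()
  ped <- object@pedigree
  need <- c("id", "sire", "dam", "sex", "generation")
  if (!all(need %in% names(ped)))
    return(paste("pedigree must have columns", paste(need, collapse = ", ")))
  n <- nrow(ped)
  if (!identical(ped$id, seq_len(n)))
    msg <- c(msg, "pedigree ids must be 1..n in order")
  known <- ped$sire > 0 | ped$dam > 0
  if (any(ped$sire[known] >= ped$id[known] & ped$sire[known] > 0) ||
      any(ped$dam[known] >= ped$id[known] & ped$dam[known] > 0))
    msg <- c(msg, "parents must precede offspring in the pedigree")
  if (ncol(object@markerHap) != 2 * n || ncol(object@qtlHap) != 2 * n)
    msg <- c(msg, "haplotype matrices must have two columns per animal")
  if (nrow(object@markerHap) != length(object@genome@markerPos))
    msg <- c(msg, "markerHap rows must match the genome's marker count")
  if (nrow(object@qtlHap) != length(object@genome@qtlPos))
    msg <- c(msg, "qtlHap rows must match the genome's QTL count")
  for (v in c("tbv", "phenotype", "genotyped"))
    if (length(slot(object, v)) != n)
      msg <- c(msg, paste(v, "must have one entry per animal"))
  if (length(msg)) msg else TRUE
})

#' QTL allele effects
#'
#' Additive effect of each QTL allele, after the single rescaling that makes
#' the true-breeding-value variance of the reference cohort equal the target
#' additive variance.
#'
#' @slot effects matrix, one row per QTL, one column per possible allele
#'   (NA beyond the locus's allele count).
#' @slot scaleFactor the multiplicative constant applied to the raw gamma
#'   draws.
#' @export
setClass("QTLEffects",
  representation(effects = "matrix", scaleFactor = "numeric")
)

#' Solutions of one mixed-model solve
#'
#' @slot betaHat fixed-effect solutions.
#' @slot aHat additive-genetic solutions for every animal in the pedigree.
#' @slot converged whether the solver met its tolerance.
#' @slot residualNorm relative residual of the solved system.
#' @export
setClass("MMEResult",
  representation(betaHat = "numeric", aHat = "numeric",
                 converged = "logical", residualNorm = "numeric")
)

#' Posterior summaries of a Bayes C chain
#'
#' @slot snpEffect posterior mean of \eqn{b_i \delta_i} per SNP.
#' @slot inclusionProb posterior inclusion frequency per SNP.
#' @slot mu,varG,varE posterior means of the overall mean, the SNP-effect
#'   variance and the residual variance.
#' @slot nKept number of retained (post burn-in, thinned) samples.
#' @export
setClass("BayesCPosterior",
  representation(snpEffect = "numeric", inclusionProb = "numeric",
                 mu = "numeric", varG = "numeric", varE = "numeric",
                 nKept = "integer")
)

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@nChromosomes, "chromosomes,",
      sprintf("%.1f cM,", sum(object@chromLengths)),
      length(object@markerPos), "markers,",
      length(object@qtlPos), "QTLs\n")
  cat("  mutation rate", object@mutationRate,
      sprintf("(expected mutations per individual u = %.3f)\n",
              mutationMeanU(object)))
})

setMethod("show", "TraitSpec", function(object) {
  cat(sprintf("TraitSpec: h2 = %.3f, varP = %.3f (varA = %.3f, varE = %.3f), gamma shape = %.2f\n",
              object@h2, object@varP, varA(object), varE(object),
              object@gammaShape))
})

setMethod("show", "Population", function(object) {
  ped <- object@pedigree
  cat("Population:", nrow(ped), "animals in generations",
      min(ped$generation), "to", max(ped$generation), "\n")
  cat(" ", sum(ped$sex == "F"), "females;", sum(object@genotyped),
      "genotyped;", sum(!is.na(object@phenotype)), "phenotyped\n")
  cat(" ", nrow(object@markerHap), "markers and", nrow(object@qtlHap),
      "QTLs on", object@genome@nChromosomes, "chromosomes\n")
})

setMethod("show", "MMEResult", function(object) {
  cat("MMEResult:", length(object@betaHat), "fixed effects,",
      length(object@aHat), "breeding values; relative residual",
      format(object@residualNorm, digits = 3), "\n")
})

setMethod("show", "BayesCPosterior", function(object) {
  cat("BayesCPosterior:", length(object@snpEffect), "SNPs,",
      object@nKept, "kept samples\n")
  cat(sprintf("  posterior means: mu = %.4f, varG = %.5f, varE = %.4f; mean inclusion = %.4f\n",
              object@mu, object@varG, object@varE, mean(object@inclusionProb)))
})
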