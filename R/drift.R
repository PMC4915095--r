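# Single-locus allele-frequency drift through a demographic size path.
# Loci evolve independently (no linkage): each generation the 2N transmitted
# allele copies are a multinomial draw from the mutation-adjusted frequencies
# of the previous generation. This is the marginal model of the full
# gene-dropping simulator and is what the true-QTL summary statistics depend
# on; it makes the full-size demographic schedules tractable.

#' Simulate multinomial allele-frequency drift
#'
#' Starts every locus at equal allele frequencies and pushes it through the
#' size path `sizes` (animals per generation). Mutation moves an allele copy
#' to one of the locus's other alleles uniformly, with probability
#' `mutationRate` per copy per generation.
#'
#' @param nLoci number of independent loci.
#' @param sizes population size per generation (the first entry is the
#'   founder generation); typically `schedule@sizes` of a historical
#'   [PopSchedule-class].
#' @param alleleCounts integer vector (2--4) of alleles per locus; a single
#'   value is recycled.
#' @param mutationRate per-copy per-generation mutation probability.
#' @param seed optional RNG seed.
#' @return matrix `nLoci x 4` of final allele counts (columns beyond a
#'   locus's allele count stay 0); `rowSums` equal `2 * tail(sizes, 1)`.
#' @export
simulateAlleleDrift <- function(nLoci, sizes, alleleCounts = 2L,
                                mutationRate = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nLoci >= 1, all(sizes >= 1),
            all(alleleCounts >= 2L), all(alleleCounts <= 4L))
  k <- rep_len(as.integer(alleleCounts), nLoci)

  # equal founder frequencies, remainders spread over the first alleles
  n2 <- 2L * sizes[1]
  cnt <- matrix(0, nLoci, 4L)
  base <- n2 %/% k
  for (a in 1:4) cnt[, a] <- ifelse(k >= a, base + (a <= n2 %% k), 0)

  for (t in seq_along(sizes)[-1]) {
    p <- cnt / rowSums(cnt)
    if (mutationRate > 0) {
      p <- p * (1 - mutationRate) + mutationRate * (1 - p) / (k - 1L)
      # alleles a locus does not have keep probability 0; the remaining
      # entries already sum to 1 because mutation mass is redistributed
      # within the locus's own alleles
      for (a in 2:4) p[k < a, a] <- 0
    }
    n2 <- 2L * sizes[t]
    cnt <- .vecMultinomial(n2, p)
  }
  cnt
}

# Vectorised multinomial draws via sequential conditional binomials.
.vecMultinomial <- function(size, p) {
  n <- nrow(p)
  out <- matrix(0, n, ncol(p))
  rem <- rep(size, length.out = n)
  pleft <- rep(1, n)
  for (a in seq_len(ncol(p) - 1L)) {
    pr <- ifelse(pleft > 0, pmin(1, pmax(0, p[, a] / pleft)), 0)
    draw <- rbinom(n, rem, pr)
    out[, a] <- draw
    rem <- rem - draw
    pleft <- pleft - p[, a]
  }
  out[, ncol(p)] <- rem
  out
}

#' Additive variance of QTLs from allele frequencies under Hardy-Weinberg
#'
#' For a locus with allele frequencies p and additive allele effects a, the
#' genotypic value is the sum of two independent allele draws, so the locus
#' variance is 2 (sum p a^2 - (sum p a)^2).
#'
#' @param freqs matrix loci x alleles of frequencies (rows sum to 1; unused
#'   allele columns 0).
#' @param effects matrix loci x alleles of allele effects (NA where unused).
#' @return numeric vector of per-locus additive variances.
#' @export
hweQtlVariance <- function(freqs, effects) {
  e <- effects
  e[is.na(e)] <- 0
  m1 <- rowSums(freqs * e)
  m2 <- rowSums(freqs * e^2)
  2 * (m2 - m1^2)
}

#' True-QTL statistics from drifted allele frequencies
#'
#' Reproduces the "true values" summaries of the simulation design: per
#' replicate, 7,000 QTL loci (2--4 alleles) drift through a historical
#' schedule, 1,000 segregating loci are sampled, signed gamma allele effects
#' are drawn and scaled so the summed additive variance equals `varA(trait)`,
#' and each QTL's percentage share of the genetic variance is computed.
#' `topQTL` counts shares of at least `threshold` percent; `pvarTopQtl` sums
#' them; `pvar1stQtl` is the largest share.
#'
#' @param schedule historical [PopSchedule-class] (HLD or LLD size path).
#' @param trait a [TraitSpec-class].
#' @param nLoci QTL loci simulated per replicate.
#' @param nSelected segregating QTLs sampled per replicate.
#' @param nReplicates number of replicates.
#' @param threshold share (%) above which a QTL counts as a topQTL.
#' @param mutationRate per-copy mutation probability.
#' @param seed optional RNG seed.
#' @return data.frame with one row per replicate: topQtl, pvarTopQtl,
#'   pvar1stQtl, nSegregating.
#' @export
qtlDriftStats <- function(schedule, trait, nLoci = 7000L, nSelected = 1000L,
                          nReplicates = 10L, threshold = 1,
                          mutationRate = 1e-4, seed = NULL) {
  stopifnot(schedule@phase == "historical")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    k <- sample(2:4, nLoci, replace = TRUE)
    cnt <- simulateAlleleDrift(nLoci, schedule@sizes, k, mutationRate)
    seg <- which(rowSums(cnt > 0) >= 2L)
    if (length(seg) < nSelected)
      stop(sprintf("replicate %d: only %d segregating QTLs, %d requested",
                   r, length(seg), nSelected))
    pick <- sample(seg, nSelected)
    freqs <- cnt[pick, , drop = FALSE] / rowSums(cnt[pick, , drop = FALSE])
    kk <- k[pick]
    eff <- matrix(NA_real_, nSelected, 4L)
    for (a in 1:4) {
      has <- kk >= a
      eff[has, a] <- rgamma(sum(has), shape = trait@gammaShape) *
        sample(c(-1, 1), sum(has), replace = TRUE)
    }
    v <- hweQtlVariance(freqs, eff)
    tot <- sum(v)
    if (tot <= 0) stop("zero total genetic variance")
    share <- v / tot * 100
    top <- share >= threshold
    out[[r]] <- data.frame(replicate = r, topQtl = sum(top),
                           pvarTopQtl = sum(share[top]),
                           pvar1stQtl = max(share),
                           nSegregating = length(seg))
  }
  do.call(rbind, out)
}
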