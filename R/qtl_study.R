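# True-QTL statistics at the full demographic design.
#
# The headline "true values" (topQTL counts and their variance shares) are
# properties of the QTL genotypes of the phenotyped selection population, not
# of the marker panel. They can therefore be recomputed without markers by
# gene-dropping only the QTL loci, treating loci as unlinked: per-locus
# multinomial drift through the historical bottleneck (the marginal model of
# the full simulator), Hardy-Weinberg founder genotypes from the drifted
# frequencies, and an explicit gene drop through the expansion and the
# EBV-selection phases at their full population sizes. Linkage between QTLs
# only perturbs the total-variance denominator with zero expectation, so the
# unlinked approximation is unbiased for the share statistics while making
# the full-size design tractable.

# haplotype matrix (loci x n) sampled from per-locus allele frequencies
.hweHaplotypes <- function(freqs, n) {
  cum1 <- freqs[, 1]
  cum2 <- cum1 + freqs[, 2]
  cum3 <- cum2 + freqs[, 3]
  u <- matrix(runif(nrow(freqs) * n), nrow(freqs), n)
  1L + (u > cum1) + (u > cum2) + (u > cum3)
}

# one gamete per offspring from unlinked loci: each locus independently takes
# the parent's first or second haplotype allele
.freeGametes <- function(HA, HB, parentCols) {
  g <- HA[, parentCols, drop = FALSE]
  swap <- matrix(runif(length(g)) < 0.5, nrow(g))
  b <- HB[, parentCols, drop = FALSE]
  g[swap] <- b[swap]
  g
}

.alleleValues <- function(H, effByLocus) {
  nl <- nrow(H)
  matrix(effByLocus[cbind(rep.int(seq_len(nl), ncol(H)), as.vector(H))],
         nl, ncol(H))
}

#' True-QTL statistics of the full study design
#'
#' Recomputes, per replicate, the "true values" of the simulation study:
#' QTL loci drift through the historical bottleneck, a panel of segregating
#' QTLs receives signed gamma allele effects scaled to the additive variance,
#' and the QTL genotypes are gene-dropped (unlinked loci) through the
#' expansion and EBV-selection phases at their scheduled population sizes.
#' Shares of the genetic variance are computed across the phenotyped females
#' of the selection population (founder dams included), exactly the reference
#' cohort of the window analyses.
#'
#' @param historical,expansion,selection the three [PopSchedule-class]
#'   objects of the design.
#' @param trait a [TraitSpec-class].
#' @param nLoci QTL loci simulated through the historical phase.
#' @param nSelected segregating QTLs kept for the study.
#' @param nReplicates replicates to run.
#' @param threshold topQTL share threshold (%).
#' @param mutationRate historical per-copy mutation probability.
#' @param seed optional RNG seed.
#' @return data.frame, one row per replicate: topQtl, pvarTopQtl,
#'   pvar1stQtl, nSegregating.
#' @seealso [qtlDriftStats()] for the frequency-only approximation that stops
#'   at the last historical generation.
#' @export
qtlStudyStats <- function(historical, expansion, selection, trait,
                          nLoci = 7000L, nSelected = 1000L,
                          nReplicates = 10L, threshold = 1,
                          mutationRate = 1e-4, seed = NULL) {
  stopifnot(historical@phase == "historical",
            expansion@phase == "expansion",
            selection@phase == "selection")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates))
    out[[r]] <- cbind(replicate = r,
                      .oneQtlStudy(historical, expansion, selection, trait,
                                   nLoci, nSelected, threshold, mutationRate))
  do.call(rbind, out)
}

.oneQtlStudy <- function(historical, expansion, selection, trait,
                         nLoci, nSelected, threshold, mutationRate) {
  ## historical phase: per-locus drift
  k <- sample(2:4, nLoci, replace = TRUE)
  cnt <- simulateAlleleDrift(nLoci, historical@sizes, k, mutationRate)
  seg <- which(rowSums(cnt > 0) >= 2L)
  if (length(seg) < nSelected)
    stop(sprintf("only %d segregating QTLs, %d requested", length(seg),
                 nSelected))
  pick <- sample(seg, nSelected)
  freqs <- cnt[pick, , drop = FALSE] / rowSums(cnt[pick, , drop = FALSE])
  kk <- k[pick]
  eff <- matrix(0, nSelected, 4L)
  for (a in 1:4) {
    has <- kk >= a
    eff[has, a] <- rgamma(sum(has), shape = trait@gammaShape) *
      sample(c(-1, 1), sum(has), replace = TRUE)
  }

  ## founders of the expansion: HWE genotypes at the drifted frequencies
  n0 <- tail(historical@sizes, 1)
  HA <- .hweHaplotypes(freqs, n0)
  HB <- .hweHaplotypes(freqs, n0)
  tbvOf <- function(HA, HB) colSums(.alleleValues(HA, eff)) +
    colSums(.alleleValues(HB, eff))
  v0 <- var(tbvOf(HA, HB))
  if (!is.finite(v0) || v0 <= 0) stop("zero genetic variance among founders")
  eff <- eff * sqrt(varA(trait) / v0)

  sex <- .balancedSexes(n0)
  ids <- seq_len(n0)
  ped <- list(data.frame(id = ids, sire = 0L, dam = 0L))
  lastId <- n0
  tbvAll <- tbvOf(HA, HB)
  phenAll <- rep(NA_real_, n0)

  ## expansion: random mating, dams double, 100 % replacement
  for (g in seq_along(expansion@damCounts)) {
    nd <- expansion@damCounts[g]
    females <- ids[sex == "F"]; males <- ids[sex == "M"]
    if (length(females) < nd) stop("not enough expansion dams")
    dams <- if (length(females) == nd) females else sample(females, nd)
    nOff <- nd * expansion@offspringPerDam
    damOf <- rep(dams, each = expansion@offspringPerDam)
    sireOf <- males[sample.int(length(males), nOff, replace = TRUE)]
    colOf <- function(who) match(who, ids)
    gS <- .freeGametes(HA, HB, colOf(sireOf))
    gD <- .freeGametes(HA, HB, colOf(damOf))
    newIds <- lastId + seq_len(nOff)
    ped[[length(ped) + 1L]] <- data.frame(id = newIds, sire = sireOf,
                                          dam = damOf)
    lastId <- lastId + nOff
    HA <- gS; HB <- gD
    ids <- newIds
    sex <- .balancedSexes(nOff)
    tbvNew <- tbvOf(HA, HB)
    tbvAll <- c(tbvAll, tbvNew)
    phenAll <- c(phenAll, rep(NA_real_, nOff))
  }

  ## selection phase: EBV truncation selection, one product per dam
  males <- ids[sex == "M"]; females <- ids[sex == "F"]
  if (length(males) < selection@nSires || length(females) < selection@nDams)
    stop("not enough selection founders")
  sires <- sample(males, selection@nSires)
  dams <- sample(females, selection@nDams)
  phenAll[dams] <- tbvAll[dams] + rnorm(length(dams), 0, sqrt(varE(trait)))
  lambda <- varRatio(trait)
  nRepS <- round(selection@replacementRate * selection@nSires)
  nRepD <- round(selection@replacementRate * selection@nDams)

  # sufficient statistics of the per-QTL genotypic values over the reference
  # cohort: the phenotyped females of the generations that supply the
  # genotyped animals (the last three). Pooling across all selection cohorts
  # would fold the genetic trend into the variances and is not used.
  refGens <- max(1L, selection@nGenerations - 2L):selection@nGenerations
  s1 <- numeric(nSelected); s2 <- numeric(nSelected); nPhen <- 0L
  t1 <- 0; t2 <- 0
  accumulate <- function(HA, HB, cols) {
    gval <- .alleleValues(HA[, cols, drop = FALSE], eff) +
      .alleleValues(HB[, cols, drop = FALSE], eff)
    s1 <<- s1 + rowSums(gval)
    s2 <<- s2 + rowSums(gval^2)
    tb <- colSums(gval)
    t1 <<- t1 + sum(tb); t2 <<- t2 + sum(tb^2)
    nPhen <<- nPhen + length(cols)
  }

  # haplotype store restricted to current parents (and the newest cohort)
  keep <- unique(c(sires, dams))
  store <- match(keep, ids)
  HA <- HA[, store, drop = FALSE]; HB <- HB[, store, drop = FALSE]
  ids <- keep

  for (g in seq_len(selection@nGenerations)) {
    nOff <- selection@nDams
    sireOf <- sires[sample.int(length(sires), nOff, replace = TRUE)]
    damOf <- dams
    gS <- .freeGametes(HA, HB, match(sireOf, ids))
    gD <- .freeGametes(HA, HB, match(damOf, ids))
    newIds <- lastId + seq_len(nOff)
    ped[[length(ped) + 1L]] <- data.frame(id = newIds, sire = sireOf,
                                          dam = damOf)
    lastId <- lastId + nOff
    sexNew <- .balancedSexes(nOff)
    tbvNew <- colSums(.alleleValues(gS, eff)) +
      colSums(.alleleValues(gD, eff))
    phenNew <- rep(NA_real_, nOff)
    fem <- which(sexNew == "F")
    phenNew[fem] <- tbvNew[fem] + rnorm(length(fem), 0, sqrt(varE(trait)))
    tbvAll <- c(tbvAll, tbvNew)
    phenAll <- c(phenAll, phenNew)

    # merge newest cohort into the haplotype store
    HA <- cbind(HA, gS); HB <- cbind(HB, gD)
    ids <- c(ids, newIds)
    if (g %in% refGens) accumulate(HA, HB, match(newIds[fem], ids))

    if (nRepS > 0L || nRepD > 0L) {
      pedDf <- do.call(rbind, ped)
      ebv <- .pedigreeBlup(pedDf, phenAll, lambda, inbreeding = FALSE,
                           cgThreshold = 0)
      newM <- newIds[sexNew == "M"]; newF <- newIds[fem]
      keepS <- sires[order(-ebv[sires],
                           sires)][seq_len(length(sires) - nRepS)]
      keepD <- dams[order(-ebv[dams], dams)][seq_len(length(dams) - nRepD)]
      sires <- c(keepS, newM[order(-ebv[newM], newM)][seq_len(nRepS)])
      dams <- c(keepD, newF[order(-ebv[newF], newF)][seq_len(nRepD)])
    }
    keep <- unique(c(sires, dams))
    sel <- match(keep, ids)
    HA <- HA[, sel, drop = FALSE]; HB <- HB[, sel, drop = FALSE]
    ids <- keep
  }

  vq <- (s2 - s1^2 / nPhen) / (nPhen - 1)
  denom <- (t2 - t1^2 / nPhen) / (nPhen - 1)
  share <- vq / denom * 100
  top <- share >= threshold
  data.frame(topQtl = sum(top), pvarTopQtl = sum(share[top]),
             pvar1stQtl = max(share), nSegregating = length(seg))
}
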