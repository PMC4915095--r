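# Internal machinery shared by the simulation phases. Marker and QTL loci are
# interleaved into a single position-sorted matrix during meiosis so that both
# locus classes segregate on the same recombination events; the Population
# slots keep them separate.

.combinedMap <- function(genome) {
  chrom <- c(genome@markerChrom, genome@qtlChrom)
  pos <- c(genome@markerPos, genome@qtlPos)
  k <- c(rep(2L, length(genome@markerPos)), genome@qtlAlleleCounts)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; k <- k[ord]
  nLoci <- length(pos)
  isMarker <- ord <= length(genome@markerPos)
  start <- integer(genome@nChromosomes)
  end <- integer(genome@nChromosomes)
  for (c in seq_len(genome@nChromosomes)) {
    idx <- which(chrom == c)
    start[c] <- if (length(idx)) idx[1] - 1L else 0L
    end[c] <- if (length(idx)) idx[length(idx)] else 0L
  }
  list(pos = pos, chromStart = start, chromEnd = end,
       chromLen = genome@chromLengths, k = k,
       markerRows = which(isMarker), qtlRows = which(!isMarker),
       nLoci = nLoci)
}

.combinedHap <- function(pop, cmap) {
  H <- matrix(0L, cmap$nLoci, ncol(pop@markerHap))
  H[cmap$markerRows, ] <- pop@markerHap
  H[cmap$qtlRows, ] <- pop@qtlHap
  H
}

.founderHap <- function(genome, cmap, n) {
  H <- matrix(0L, cmap$nLoci, 2L * n)
  H[cmap$markerRows, ] <- sample(1:2, length(cmap$markerRows) * 2L * n,
                                 replace = TRUE)
  kq <- cmap$k[cmap$qtlRows]
  H[cmap$qtlRows, ] <- 1L + floor(runif(length(kq) * 2L * n) * rep(kq, 2L * n))
  H
}

# Gamete formation; recurrent mutation (expected u = 2 * nLoci * rate per
# individual) happens inside the C++ kernel when mutRate > 0.
.gametes <- function(H, parents, cmap, mutRate = 0) {
  cpp_drop_gametes(H, as.integer(parents - 1L), cmap$pos,
                   as.integer(cmap$chromStart), as.integer(cmap$chromEnd),
                   cmap$chromLen, mutRate, cmap$k)
}

# Sexes in a cohort: a random permutation of a balanced vector, so each animal
# is male or female with probability 1/2 but cohort counts are (near) exactly
# half and half. This keeps the deterministic cohort bookkeeping of the
# demographic design (e.g. 100 females among the 200 last historical animals).
.balancedSexes <- function(n) {
  s <- rep(c("M", "F"), n %/% 2L)
  if (n %% 2L) s <- c(s, sample(c("M", "F"), 1L))
  sample(s)
}

.emptyPedigree <- function(n, generation = 0L) {
  data.frame(id = seq_len(n), sire = 0L, dam = 0L,
             sex = .balancedSexes(n), generation = generation)
}

.makePopulation <- function(ped, H, cmap, genome, tbv = NULL,
                            phenotype = NULL, genotyped = NULL) {
  n <- nrow(ped)
  new("Population", pedigree = ped,
      markerHap = H[cmap$markerRows, , drop = FALSE],
      qtlHap = H[cmap$qtlRows, , drop = FALSE],
      tbv = if (is.null(tbv)) rep(NA_real_, n) else tbv,
      phenotype = if (is.null(phenotype)) rep(NA_real_, n) else phenotype,
      genotyped = if (is.null(genotyped)) rep(FALSE, n) else genotyped,
      genome = genome)
}

#' Simulate the historical population
#'
#' Random union of gametes through the size path of a historical
#' [PopSchedule-class]: a constant-size phase followed by a gradual decline
#' that produces the bottleneck (and hence drift and LD). Recurrent mutation
#' at the genome's rate is active throughout this phase and only here.
#' Only the final generation is returned, as the founder cohort of the
#' expansion phase.
#'
#' @param genome a [GenomeSpec-class].
#' @param schedule a historical [PopSchedule-class].
#' @param seed optional RNG seed.
#' @return a [Population-class] holding the last historical generation
#'   (pedigree founders, half of them female).
#' @export
simulateHistorical <- function(genome, schedule, seed = NULL) {
  stopifnot(is(genome, "GenomeSpec"), is(schedule, "PopSchedule"))
  if (schedule@phase != "historical")
    stop("simulateHistorical() needs a schedule with phase 'historical'")
  if (!is.null(seed)) set.seed(seed)
  sizes <- schedule@sizes
  if (any(sizes <= 0)) stop("population sizes must be positive")

  cmap <- .combinedMap(genome)
  H <- .founderHap(genome, cmap, sizes[1])
  sex <- .balancedSexes(sizes[1])

  for (t in seq_along(sizes)[-1]) {
    n <- sizes[t]
    males <- which(sex == "M"); females <- which(sex == "F")
    if (!length(males) || !length(females))
      stop("a historical generation ran out of one sex")
    sires <- males[sample.int(length(males), n, replace = TRUE)]
    dams <- females[sample.int(length(females), n, replace = TRUE)]
    H <- cpp_next_generation(H, as.integer(sires - 1L),
                             as.integer(dams - 1L), cmap$pos,
                             as.integer(cmap$chromStart),
                             as.integer(cmap$chromEnd), cmap$chromLen,
                             genome@mutationRate, cmap$k)
    sex <- .balancedSexes(n)
  }

  ped <- .emptyPedigree(length(sex))
  ped$sex <- sex
  .makePopulation(ped, H, cmap, genome)
}

#' Restrict a population to segregating marker and QTL loci
#'
#' Markers are sampled uniformly without replacement among loci with minor
#' allele frequency at least `mafMin`; QTLs among loci still segregating
#' (at least two alleles present). The genome map is restricted to the
#' selected loci.
#'
#' @param pop a [Population-class], normally the last historical generation.
#' @param mafMin minimum marker MAF (0.02 at full scale).
#' @param nMarkers,nQtl numbers of loci to retain.
#' @param seed optional RNG seed.
#' @return a [Population-class] on the restricted genome.
#' @export
selectSegregatingLoci <- function(pop, mafMin = 0.02, nMarkers, nQtl,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- pop@genome
  f2 <- rowMeans(pop@markerHap == 2L)
  maf <- pmin(f2, 1 - f2)
  elig <- which(maf > 0 & maf >= mafMin)
  if (length(elig) < nMarkers)
    stop(sprintf(
      "only %d markers with MAF >= %g are segregating; %d requested (shortfall %d)",
      length(elig), mafMin, nMarkers, nMarkers - length(elig)))
  segQtl <- which(matrixStatsRowAnyDiff(pop@qtlHap))
  if (length(segQtl) < nQtl)
    stop(sprintf("only %d QTLs are segregating; %d requested (shortfall %d)",
                 length(segQtl), nQtl, nQtl - length(segQtl)))
  mk <- sort(elig[sample.int(length(elig), nMarkers)])
  qt <- sort(segQtl[sample.int(length(segQtl), nQtl)])

  genome <- new("GenomeSpec",
                nChromosomes = g@nChromosomes, chromLengths = g@chromLengths,
                markerChrom = g@markerChrom[mk], markerPos = g@markerPos[mk],
                qtlChrom = g@qtlChrom[qt], qtlPos = g@qtlPos[qt],
                qtlAlleleCounts = g@qtlAlleleCounts[qt],
                mutationRate = g@mutationRate)
  new("Population", pedigree = pop@pedigree,
      markerHap = pop@markerHap[mk, , drop = FALSE],
      qtlHap = pop@qtlHap[qt, , drop = FALSE],
      tbv = pop@tbv, phenotype = pop@phenotype, genotyped = pop@genotyped,
      genome = genome)
}

# TRUE per row when the row is not constant
matrixStatsRowAnyDiff <- function(m) {
  if (ncol(m) < 2L) return(rep(FALSE, nrow(m)))
  rowSums(m != m[, 1L]) > 0L
}

#' Draw and scale QTL allele effects
#'
#' Allele effects are sampled from a gamma distribution (shape
#' `trait@gammaShape`, scale 1) with an independent random sign per allele,
#' then rescaled by one multiplicative constant so that the variance of true
#' breeding values over the reference cohort equals the target additive
#' variance.
#'
#' @param pop a [Population-class] whose QTLs the effects refer to.
#' @param trait a [TraitSpec-class].
#' @param refIds animal ids defining the reference cohort for the rescaling;
#'   defaults to all animals in `pop`.
#' @param targetVarA target additive variance; defaults to `varA(trait)`.
#'   A target of 0 yields all-zero effects.
#' @param seed optional RNG seed.
#' @return a [QTLEffects-class].
#' @export
assignQtlEffects <- function(pop, trait, refIds = NULL,
                             targetVarA = varA(trait), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- pop@genome
  nq <- nQtl(g)
  eff <- matrix(NA_real_, nq, 4L)
  for (a in 1:4) {
    has <- g@qtlAlleleCounts >= a
    eff[has, a] <- rgamma(sum(has), shape = trait@gammaShape) *
      sample(c(-1, 1), sum(has), replace = TRUE)
  }
  if (targetVarA == 0) {
    eff[!is.na(eff)] <- 0
    return(new("QTLEffects", effects = eff, scaleFactor = 0))
  }
  if (is.null(refIds)) refIds <- pop@pedigree$id
  raw <- .tbvFromHaplotypes(pop@qtlHap, eff, refIds)
  v <- var(raw)
  if (!is.finite(v) || v <= 0)
    stop("zero genetic variance in the reference cohort before scaling")
  s <- sqrt(targetVarA / v)
  new("QTLEffects", effects = eff * s, scaleFactor = s)
}

.tbvFromHaplotypes <- function(qtlHap, effects, ids = NULL) {
  cols <- if (is.null(ids)) seq_len(ncol(qtlHap)) else
    as.vector(rbind(2L * ids - 1L, 2L * ids))
  h <- qtlHap[, cols, drop = FALSE]
  nq <- nrow(h)
  vals <- matrix(effects[cbind(rep.int(seq_len(nq), ncol(h)), as.vector(h))],
                 nq, ncol(h))
  percol <- colSums(vals)
  percol[seq(1L, length(percol), 2L)] + percol[seq(2L, length(percol), 2L)]
}

#' Compute true breeding values
#'
#' The TBV of an animal is the sum of its QTL allele effects over both
#' haplotypes.
#'
#' @param pop a [Population-class].
#' @param effects a [QTLEffects-class] for `pop`'s QTLs.
#' @return `pop` with the `tbv` slot filled.
#' @export
computeTbv <- function(pop, effects) {
  pop@tbv <- .tbvFromHaplotypes(pop@qtlHap, effects@effects)
  validObject(pop)
  pop
}

#' Attach phenotypes to a population
#'
#' The trait is sex-limited: phenotype = TBV + e with
#' e ~ Normal(0, varE(trait)) for females, missing for males.
#'
#' @param pop a [Population-class] with TBVs computed.
#' @param trait a [TraitSpec-class].
#' @param seed optional RNG seed.
#' @param ids animals to (re)phenotype; defaults to every female.
#' @return `pop` with phenotypes filled for females among `ids`.
#' @export
simulatePhenotypes <- function(pop, trait, seed = NULL, ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(pop@tbv))) stop("TBVs must be computed before phenotypes")
  if (is.null(ids)) ids <- pop@pedigree$id
  f <- ids[pop@pedigree$sex[ids] == "F"]
  pop@phenotype[f] <- pop@tbv[f] + rnorm(length(f), 0, sqrt(varE(trait)))
  pop
}

#' Simulate the expansion phase
#'
#' Random mating with 100 % replacement: in each generation the scheduled
#' number of dams (doubling every generation) is drawn from the previous
#' generation's females, each dam leaves `offspringPerDam` products sired by
#' males drawn at random from the previous generation. No selection and no
#' mutation operate here.
#'
#' @param pop a [Population-class]; its last generation founds the expansion.
#' @param schedule an expansion [PopSchedule-class].
#' @param effects optional [QTLEffects-class]; when supplied, TBVs of the new
#'   animals are filled in.
#' @param seed optional RNG seed.
#' @return a [Population-class] containing `pop` plus all expansion cohorts.
#' @export
simulateExpansion <- function(pop, schedule, effects = NULL, seed = NULL) {
  stopifnot(is(schedule, "PopSchedule"))
  if (schedule@phase != "expansion")
    stop("simulateExpansion() needs a schedule with phase 'expansion'")
  if (!is.null(seed)) set.seed(seed)
  nGen <- length(schedule@damCounts)
  if (nGen == 0L) return(pop)

  cmap <- .combinedMap(pop@genome)
  cohorts <- expansionCohortSizes(schedule)
  n0 <- nrow(pop@pedigree)
  total <- n0 + sum(cohorts)
  H <- matrix(0L, cmap$nLoci, 2L * total)
  H[, seq_len(2L * n0)] <- .combinedHap(pop, cmap)
  ped <- pop@pedigree
  tbv <- c(pop@tbv, rep(NA_real_, total - n0))
  gen0 <- max(ped$generation)
  prev <- ped$id[ped$generation == gen0]

  for (g in seq_len(nGen)) {
    femalesPrev <- prev[ped$sex[prev] == "F"]
    malesPrev <- prev[ped$sex[prev] == "M"]
    nd <- schedule@damCounts[g]
    if (length(femalesPrev) < nd)
      stop(sprintf("expansion generation %d needs %d dams, only %d females available",
                   g, nd, length(femalesPrev)))
    if (!length(malesPrev)) stop("no males available in the expansion phase")
    dams <- if (length(femalesPrev) == nd) femalesPrev else
      sample(femalesPrev, nd)
    nOff <- cohorts[g]
    damOf <- rep(dams, each = schedule@offspringPerDam)
    sireOf <- malesPrev[sample.int(length(malesPrev), nOff, replace = TRUE)]
    ids <- nrow(ped) + seq_len(nOff)
    cols <- 2L * rep(ids, each = 2L) - c(1L, 0L)
    H[, cols[c(TRUE, FALSE)]] <- .gametes(H, sireOf, cmap)
    H[, cols[c(FALSE, TRUE)]] <- .gametes(H, damOf, cmap)
    ped <- rbind(ped, data.frame(id = ids, sire = sireOf, dam = damOf,
                                 sex = .balancedSexes(nOff),
                                 generation = gen0 + g))
    prev <- ids
  }

  out <- .makePopulation(ped, H, cmap, pop@genome,
                         tbv = tbv,
                         phenotype = c(pop@phenotype,
                                       rep(NA_real_, total - n0)),
                         genotyped = c(pop@genotyped,
                                       rep(FALSE, total - n0)))
  if (!is.null(effects)) out <- computeTbv(out, effects)
  out
}

#' Simulate the selection phase
#'
#' Founders (`nSires` males and `nDams` females) are sampled from the last
#' generation of `pop`; founder dams are phenotyped. Each generation, every
#' dam is mated to a randomly assigned selected sire and leaves one product;
#' female offspring are phenotyped at birth. After each cohort, breeding
#' values are estimated by pedigree BLUP (overall mean plus animal, true
#' variance ratio) on all female phenotypes recorded so far, and the
#' scheduled fraction of sires and dams is replaced by the top-EBV candidates
#' of the newest cohort.
#'
#' @param pop a [Population-class] with TBVs computed (e.g. the expansion
#'   output).
#' @param trait a [TraitSpec-class].
#' @param effects the [QTLEffects-class] used to compute TBVs of new cohorts.
#' @param schedule a selection [PopSchedule-class].
#' @param nGenotyped number of females of the last `genotypeLastGens`
#'   generations to flag as genotyped.
#' @param genotypeLastGens how many final generations supply the genotyped
#'   females.
#' @param seed optional RNG seed.
#' @return a [Population-class] containing `pop` plus all selection cohorts,
#'   with phenotype and genotyped flags set.
#' @export
simulateSelection <- function(pop, trait, effects, schedule, nGenotyped = 0L,
                              genotypeLastGens = 3L, seed = NULL) {
  stopifnot(is(schedule, "PopSchedule"))
  if (schedule@phase != "selection")
    stop("simulateSelection() needs a schedule with phase 'selection'")
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(pop@tbv)))
    stop("TBVs must be computed before the selection phase")

  cmap <- .combinedMap(pop@genome)
  ped <- pop@pedigree
  gen0 <- max(ped$generation)
  last <- ped$id[ped$generation == gen0]
  males <- last[ped$sex[last] == "M"]
  females <- last[ped$sex[last] == "F"]
  if (length(males) < schedule@nSires || length(females) < schedule@nDams)
    stop(sprintf("last generation has %d males / %d females; %d sires and %d dams requested",
                 length(males), length(females), schedule@nSires,
                 schedule@nDams))
  sires <- sample(males, schedule@nSires)
  dams <- sample(females, schedule@nDams)

  nGen <- schedule@nGenerations
  n0 <- nrow(ped)
  total <- n0 + nGen * schedule@nDams
  H <- matrix(0L, cmap$nLoci, 2L * total)
  H[, seq_len(2L * n0)] <- .combinedHap(pop, cmap)
  tbv <- c(pop@tbv, rep(NA_real_, total - n0))
  phen <- c(pop@phenotype, rep(NA_real_, total - n0))
  lambda <- varRatio(trait)

  # founder dams carry records (the trait is female-only)
  phen[dams] <- tbv[dams] + rnorm(length(dams), 0, sqrt(varE(trait)))

  nRepS <- round(schedule@replacementRate * schedule@nSires)
  nRepD <- round(schedule@replacementRate * schedule@nDams)

  for (g in seq_len(nGen)) {
    nOff <- schedule@nDams
    sireOf <- sires[sample.int(length(sires), nOff, replace = TRUE)]
    damOf <- dams
    ids <- nrow(ped) + seq_len(nOff)
    allCols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    H[, allCols[c(TRUE, FALSE)]] <- .gametes(H, sireOf, cmap)
    H[, allCols[c(FALSE, TRUE)]] <- .gametes(H, damOf, cmap)
    sexes <- .balancedSexes(nOff)
    ped <- rbind(ped, data.frame(id = ids, sire = sireOf, dam = damOf,
                                 sex = sexes, generation = gen0 + g))
    qh <- H[cmap$qtlRows, allCols, drop = FALSE]
    tbv[ids] <- .tbvFromHaplotypes(qh, effects@effects)
    isF <- ids[sexes == "F"]
    phen[isF] <- tbv[isF] + rnorm(length(isF), 0, sqrt(varE(trait)))

    if (nRepS > 0L || nRepD > 0L) {
      ebv <- .pedigreeBlup(ped, phen, lambda)
      newM <- ids[sexes == "M"]; newF <- isF
      if (length(newM) < nRepS || length(newF) < nRepD)
        stop(sprintf("generation %d: %d male / %d female candidates cannot satisfy replacement of %d sires / %d dams",
                     g, length(newM), length(newF), nRepS, nRepD))
      keepS <- sires[order(-ebv[sires], sires)][seq_len(length(sires) - nRepS)]
      keepD <- dams[order(-ebv[dams], dams)][seq_len(length(dams) - nRepD)]
      inS <- newM[order(-ebv[newM], newM)][seq_len(nRepS)]
      inD <- newF[order(-ebv[newF], newF)][seq_len(nRepD)]
      sires <- c(keepS, inS)
      dams <- c(keepD, inD)
    }
  }

  genotyped <- rep(FALSE, total)
  if (nGenotyped > 0L) {
    pool <- ped$id[ped$generation > gen0 + nGen - genotypeLastGens &
                     ped$sex == "F"]
    if (length(pool) < nGenotyped)
      stop(sprintf("only %d females in the last %d generations; %d genotypes requested",
                   length(pool), genotypeLastGens, nGenotyped))
    genotyped[sample(pool, nGenotyped)] <- TRUE
  }

  .makePopulation(ped, H, cmap, pop@genome, tbv = tbv, phenotype = phen,
                  genotyped = genotyped)
}

# Pedigree BLUP (overall mean + animal) used as the selection criterion.
# Selection pedigrees reuse dams across many generations, which fills in the
# Cholesky factor badly; conjugate gradients are the reliable solver there.
.pedigreeBlup <- function(ped, phen, lambda, inbreeding = TRUE,
                          cgThreshold = 5e4) {
  rec <- which(!is.na(phen))
  Ainv <- buildAinv(ped, inbreeding = inbreeding)
  fit <- solveMME(phen[rec], X = matrix(1, length(rec), 1),
                  animal = rec, Kinv = Ainv, lambda = lambda,
                  cgThreshold = cgThreshold)
  fit@aHat
}

#' Genotype dosages of a population
#'
#' Marker genotypes coded as the number of copies of allele 2 (0, 1 or 2).
#'
#' @param pop a [Population-class].
#' @param ids animals to extract; defaults to the genotyped animals.
#' @return integer matrix, animals by markers, rownames = animal ids.
#' @export
markerDosage <- function(pop, ids = NULL) {
  if (is.null(ids)) ids <- which(pop@genotyped)
  if (!length(ids)) stop("no genotyped animals")
  cols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  h <- pop@markerHap[, cols, drop = FALSE] == 2L
  d <- t(h[, c(TRUE, FALSE), drop = FALSE] + h[, c(FALSE, TRUE), drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- ids
  d
}
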