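# Physical lengths (Mb) of the 29 bovine autosomes (UMD3.1 order of
# magnitude); used only as proportions when laying out a simulated genome.
.BOVINE_AUTOSOME_MB <- c(
  158.3, 137.1, 121.4, 120.8, 121.2, 119.5, 112.6, 113.4, 105.7, 104.3,
  107.3, 91.2, 84.2, 84.6, 85.3, 81.7, 75.2, 66.0, 64.1, 72.0,
  71.6, 61.4, 52.5, 62.7, 42.9, 51.7, 45.4, 46.3, 51.5
)

#' Construct a genome specification
#'
#' Lays out `nChromosomes` autosomes with lengths proportional to the bovine
#' physical autosome lengths, normalised to `totalLength` cM. Marker and QTL
#' counts per chromosome are proportional to chromosome length; positions are
#' uniform within chromosomes. Each QTL is given 2--4 alleles uniformly at
#' random.
#'
#' @param nChromosomes number of autosomes (up to 29).
#' @param totalLength total genome length in cM.
#' @param nMarkers,nQtl number of marker / QTL loci to place.
#' @param mutationRate per-locus per-gamete recurrent mutation probability,
#'   active in the historical phase.
#' @param seed optional RNG seed.
#' @return a [GenomeSpec-class].
#' @export
makeGenome <- function(nChromosomes = 29L, totalLength = 2333,
                       nMarkers, nQtl, mutationRate = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nChromosomes <- as.integer(nChromosomes)
  stopifnot(nChromosomes >= 1, nChromosomes <= length(.BOVINE_AUTOSOME_MB),
            totalLength > 0, nMarkers >= 1, nQtl >= 1)
  prop <- .BOVINE_AUTOSOME_MB[seq_len(nChromosomes)]
  lens <- prop / sum(prop) * totalLength

  alloc <- function(n) {
    # largest-remainder allocation proportional to length, >= 1 per chromosome
    raw <- lens / sum(lens) * n
    k <- pmax(1L, floor(raw))
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(raw - floor(raw), decreasing = TRUE)
      k[extra[seq_len(rem)]] <- k[extra[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      drop <- order(k, decreasing = TRUE)
      i <- 1L
      while (rem < 0) {
        if (k[drop[i]] > 1L) { k[drop[i]] <- k[drop[i]] - 1L; rem <- rem + 1L }
        i <- if (i == nChromosomes) 1L else i + 1L
      }
    }
    as.integer(k)
  }
  place <- function(counts) {
    chrom <- rep(seq_len(nChromosomes), counts)
    pos <- unlist(lapply(seq_len(nChromosomes), function(c)
      sort(runif(counts[c], 0, lens[c]))), use.names = FALSE)
    list(chrom = as.integer(chrom), pos = pos)
  }
  mk <- place(alloc(nMarkers))
  qt <- place(alloc(nQtl))

  new("GenomeSpec",
      nChromosomes = nChromosomes, chromLengths = lens,
      markerChrom = mk$chrom, markerPos = mk$pos,
      qtlChrom = qt$chrom, qtlPos = qt$pos,
      qtlAlleleCounts = as.integer(sample(2:4, nQtl, replace = TRUE)),
      mutationRate = mutationRate)
}

#' @rdname makeGenome
#' @param genome a [GenomeSpec-class].
#' @export
nMarkers <- function(genome) length(genome@markerPos)

#' @rdname makeGenome
#' @export
nQtl <- function(genome) length(genome@qtlPos)

#' @rdname makeGenome
#' @export
totalLength <- function(genome) sum(genome@chromLengths)

#' Expected mutations per individual per generation
#'
#' The mutation count drawn each generation is Poisson with mean
#' u = 2 x (number of loci) x (mutation rate) per individual.
#' @param genome a [GenomeSpec-class].
#' @export
mutationMeanU <- function(genome) {
  2 * (nMarkers(genome) + nQtl(genome)) * genome@mutationRate
}

#' Mean spacing between adjacent markers
#'
#' Average cM distance between adjacent markers within chromosomes.
#' @param genome a [GenomeSpec-class].
#' @export
meanAdjacentSpacing <- function(genome) {
  d <- diff(genome@markerPos)
  mean(d[diff(genome@markerChrom) == 0])
}

#' Marker and QTL maps as data frames
#'
#' @param genome a [GenomeSpec-class].
#' @return data.frame with columns `chrom` and `pos` (cM; 1 cM is treated as
#'   1 Mb for window analyses).
#' @export
markerMap <- function(genome) {
  data.frame(chrom = genome@markerChrom, pos = genome@markerPos)
}

#' @rdname markerMap
#' @export
qtlMap <- function(genome) {
  data.frame(chrom = genome@qtlChrom, pos = genome@qtlPos,
             nAlleles = genome@qtlAlleleCounts)
}

#' Construct a trait specification
#'
#' @param h2 narrow-sense heritability.
#' @param varP phenotypic variance.
#' @param gammaShape shape of the gamma distribution of QTL allele effects.
#' @return a [TraitSpec-class].
#' @export
traitSpec <- function(h2 = 0.14, varP = 1, gammaShape = 0.4) {
  new("TraitSpec", h2 = h2, varP = varP, gammaShape = gammaShape)
}

#' Derived variance components of a trait
#'
#' `varA` is the additive genetic variance (h2 x varP), `varE` the residual
#' variance (varP - varA) and `varRatio` the mixed-model shrinkage ratio
#' varE / varA.
#' @param trait a [TraitSpec-class].
#' @export
varA <- function(trait) trait@h2 * trait@varP

#' @rdname varA
#' @export
varE <- function(trait) trait@varP - varA(trait)

#' @rdname varA
#' @export
varRatio <- function(trait) varE(trait) / varA(trait)

#' Historical-phase demographic schedule
#'
#' A constant-size random-mating phase followed by a gradual (linear) decline
#' that creates the bottleneck responsible for drift and LD. The long decline
#' (2,020 generations at full scale) yields the high-LD population, the short
#' one (1,020) the low-LD population.
#'
#' @param constantGenerations generations bred at constant size (the founder
#'   cohort is generation 0, so the size path has `constantGenerations +
#'   declineGenerations + 1` entries).
#' @param constantSize population size during the constant phase.
#' @param declineGenerations generations over which the size declines.
#' @param finalSize size of the last historical generation.
#' @param hld flag recording whether this is the long-bottleneck (high-LD)
#'   configuration.
#' @return a [PopSchedule-class] with phase "historical".
#' @export
historicalSchedule <- function(constantGenerations = 1000L,
                               constantSize = 1000L,
                               declineGenerations = 2020L,
                               finalSize = 200L,
                               hld = declineGenerations > 1020L) {
  stopifnot(constantGenerations >= 0, declineGenerations >= 1,
            constantSize >= 2, finalSize >= 2, finalSize <= constantSize)
  sizes <- c(rep(constantSize, constantGenerations + 1L),
             round(seq(constantSize, finalSize,
                       length.out = declineGenerations + 1L))[-1L])
  new("PopSchedule", phase = "historical", sizes = as.integer(sizes),
      hld = hld)
}

#' Expansion-phase schedule
#'
#' Exponential growth of the dam population: the number of dams doubles every
#' generation, each dam leaves `offspringPerDam` products, replacement is
#' 100 % and mating is random.
#'
#' @param initialDams dams mated in the first expansion generation.
#' @param nGenerations number of expansion generations.
#' @param offspringPerDam products per dam.
#' @return a [PopSchedule-class] with phase "expansion".
#' @export
expansionSchedule <- function(initialDams = 100L, nGenerations = 6L,
                              offspringPerDam = 5L) {
  stopifnot(initialDams >= 1, nGenerations >= 0, offspringPerDam >= 1)
  new("PopSchedule", phase = "expansion",
      damCounts = as.integer(initialDams * 2^(seq_len(nGenerations) - 1L)),
      offspringPerDam = as.integer(offspringPerDam))
}

#' Selection-phase schedule
#'
#' Truncation selection on EBV with overlapping parent generations: each dam
#' is mated to a randomly assigned selected sire and leaves one product per
#' generation; a fixed fraction of sires and dams is replaced each generation
#' by the top-EBV candidates of the newest cohort.
#'
#' @param nGenerations number of selection generations.
#' @param nSires,nDams parents in service each generation.
#' @param replacementRate fraction of parents replaced per generation.
#' @return a [PopSchedule-class] with phase "selection".
#' @export
selectionSchedule <- function(nGenerations = 15L, nSires = 240L,
                              nDams = 6000L, replacementRate = 0.2) {
  new("PopSchedule", phase = "selection",
      nGenerations = as.integer(nGenerations), nSires = as.integer(nSires),
      nDams = as.integer(nDams), replacementRate = replacementRate)
}

#' Cohort bookkeeping for a schedule
#'
#' `expansionCohortSizes` returns the number of animals born in each expansion
#' generation (dams x offspring per dam); `selectionTotalAnimals` the number
#' of animals produced over the whole selection phase (dams x generations,
#' one product per dam).
#' @param schedule a [PopSchedule-class].
#' @export
expansionCohortSizes <- function(schedule) {
  stopifnot(schedule@phase == "expansion")
  as.integer(schedule@damCounts) * schedule@offspringPerDam
}

#' @rdname expansionCohortSizes
#' @export
selectionTotalAnimals <- function(schedule) {
  stopifnot(schedule@phase == "selection")
  schedule@nGenerations * schedule@nDams
}
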