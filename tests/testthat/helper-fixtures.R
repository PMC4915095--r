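# Fixtures are built in code; nothing is read from disk.

# A genome with explicitly chosen maps (no randomness), for controlled tests.
fixedGenome <- function(markerChrom, markerPos, qtlChrom, qtlPos,
                        qtlAlleleCounts = rep(2L, length(qtlPos)),
                        chromLengths = NULL, mutationRate = 0) {
  nc <- max(c(markerChrom, qtlChrom))
  if (is.null(chromLengths))
    chromLengths <- sapply(seq_len(nc), function(c)
      max(c(markerPos[markerChrom == c], qtlPos[qtlChrom == c], 1)) + 1)
  new("GenomeSpec", nChromosomes = as.integer(nc),
      chromLengths = as.numeric(chromLengths),
      markerChrom = as.integer(markerChrom), markerPos = as.numeric(markerPos),
      qtlChrom = as.integer(qtlChrom), qtlPos = as.numeric(qtlPos),
      qtlAlleleCounts = as.integer(qtlAlleleCounts),
      mutationRate = mutationRate)
}

# Founder population with explicit haplotype matrices.
fixedPop <- function(genome, markerHap, qtlHap, sex = NULL) {
  n <- ncol(markerHap) / 2
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    sex = if (is.null(sex)) rep(c("F", "M"), length.out = n)
                      else sex,
                    generation = 0L)
  new("Population", pedigree = ped,
      markerHap = markerHap, qtlHap = qtlHap,
      tbv = rep(NA_real_, n), phenotype = rep(NA_real_, n),
      genotyped = rep(FALSE, n), genome = genome)
}

# Random founder population: biallelic markers at given frequencies, QTLs at
# uniform alleles. Used where pedigree structure is irrelevant.
randomPop <- function(n, nMarkers = 20, nQtl = 4, freq = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- max(nMarkers, nQtl) + 2
  genome <- fixedGenome(markerChrom = rep(1L, nMarkers),
                        markerPos = seq_len(nMarkers),
                        qtlChrom = rep(1L, nQtl),
                        qtlPos = seq_len(nQtl) + 0.5,
                        chromLengths = len)
  mh <- matrix(1L + rbinom(nMarkers * 2 * n, 1, freq), nMarkers, 2 * n)
  qh <- matrix(sample(1:2, nQtl * 2 * n, replace = TRUE), nQtl, 2 * n)
  fixedPop(genome, mh, qh)
}

# Random multi-generation pedigree with overlapping matings (and therefore
# some inbreeding), parents always preceding offspring.
randomPedigree <- function(n, nFounders = max(4L, n %/% 5L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sex <- sample(rep(c("M", "F"), length.out = n))
  sire <- integer(n); dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= nFounders) next
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) && length(females) && runif(1) > 0.1) {
      sire[i] <- sample(males, 1L)
      dam[i] <- sample(females, 1L)
    }
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex,
             generation = 0L)
}

# Exhaustive maximum one-to-one matching under a distance threshold, by
# recursion over windows; oracle for the greedy QTL matcher.
optimalMatchCount <- function(D, tolerance) {
  ok <- is.finite(D) & D <= tolerance
  best <- function(w, used) {
    if (w > nrow(D)) return(0L)
    b <- best(w + 1L, used) # leave window w unmatched
    for (q in which(ok[w, ] & !used)) {
      used[q] <- TRUE
      b <- max(b, 1L + best(w + 1L, used))
      used[q] <- FALSE
    }
    b
  }
  best(1L, rep(FALSE, ncol(D)))
}

# Closed-form ridge / SNP-BLUP solution with an unpenalised mean:
# [n, 1'G; G'1, G'G + lambda I] [mu; b] = [1'y; G'y]
ridgeOracle <- function(y, G, lambda) {
  n <- nrow(G); m <- ncol(G)
  LHS <- rbind(cbind(n, t(colSums(G))),
               cbind(colSums(G), crossprod(G) + lambda * diag(m)))
  sol <- solve(LHS, c(sum(y), crossprod(G, y)))
  list(mu = unname(sol[1]), b = unname(sol[-1]))
}

# One replicate of the realized-heritability check: effects are scaled on a
# founder cohort, then an unselected cohort of mutually unrelated offspring
# (each parent pair used once) is bred and phenotyped. Unrelated offspring
# keep the sample variance of TBV unbiased for the population variance.
realizedH2Once <- function(nFounders = 600, nQtl = 40) {
  pop <- randomPop(nFounders, nMarkers = 2, nQtl = nQtl)
  tr <- traitSpec()
  eff <- assignQtlEffects(pop, tr)
  pop <- computeTbv(pop, eff)
  sires <- sample(which(pop@pedigree$sex == "M"))
  dams <- sample(which(pop@pedigree$sex == "F"))
  n <- min(length(sires), length(dams))
  cmap <- ssqtl:::.combinedMap(pop@genome)
  H <- ssqtl:::.combinedHap(pop, cmap)
  Ho <- matrix(0L, cmap$nLoci, 2 * n)
  Ho[, seq(1, 2 * n, 2)] <- ssqtl:::.gametes(H, sires[seq_len(n)], cmap)
  Ho[, seq(2, 2 * n, 2)] <- ssqtl:::.gametes(H, dams[seq_len(n)], cmap)
  tbv <- ssqtl:::.tbvFromHaplotypes(Ho[cmap$qtlRows, , drop = FALSE],
                                    eff@effects)
  phen <- tbv + rnorm(n, 0, sqrt(varE(tr)))
  var(tbv) / var(phen)
}

# A small simulated study (shared fixture): short history, tiny genome,
# expansion and a few selection generations, some genotyped females.
smallStudyCache <- new.env(parent = emptyenv())
smallStudy <- function(ld = "hld", baseSeed = 3L) {
  key <- paste(ld, baseSeed)
  if (!is.null(smallStudyCache[[key]])) return(smallStudyCache[[key]])
  cfg <- experimentConfig(ld, "mini", nReplicates = 1L, baseSeed = baseSeed,
    genome = list(nChromosomes = 4L, totalLength = 60,
                  nMarkerLoci = 1000L, nQtlLoci = 130L),
    panel = list(nMarkers = 250L, nQtl = 25L),
    historical = list(constantGenerations = 120L, constantSize = 80L,
                      declineGenerations = c(hld = 100L, lld = 50L),
                      finalSize = 40L),
    expansion = list(initialDams = 10L, nGenerations = 4L),
    selection = list(nGenerations = 3L, nSires = 12L, nDams = 120L),
    genotyping = list(nGenotyped = 100L, lastGens = 3L),
    bayesc = list(chainLength = 2000L, burnIn = 500L, thin = 3L))
  smallStudyCache[[key]] <- simulateReplicate(cfg, 1L)
  smallStudyCache[[key]]$config <- cfg
  smallStudyCache[[key]]
}
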