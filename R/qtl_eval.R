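#' Linkage disequilibrium between two loci
#'
#' r-squared from haplotype frequencies when phased data are available
#' (D^2 / (pA pa pB pb)), or as the squared correlation of genotype dosages
#' for unphased input. Monomorphic loci give NA.
#'
#' @param a,b for `method = "haplotype"`, allele vectors over haplotypes (any
#'   two codes); for `method = "genotype"`, dosage vectors over animals.
#' @param method how to measure LD.
#' @return r-squared in \[0, 1\], or NA if a locus is monomorphic.
#' @export
computeR2 <- function(a, b, method = c("haplotype", "genotype")) {
  method <- match.arg(method)
  if (method == "genotype") {
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    return(cor(a, b)^2)
  }
  ua <- unique(a); ub <- unique(b)
  if (length(ua) < 2 || length(ub) < 2) return(NA_real_)
  if (length(ua) > 2 || length(ub) > 2)
    stop("haplotype r2 requires biallelic loci")
  x <- as.numeric(a == ua[1])
  z <- as.numeric(b == ub[1])
  pA <- mean(x); pB <- mean(z)
  D <- mean(x * z) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' LD decay profile
#'
#' Mean r-squared of same-chromosome marker pairs binned by map distance
#' (1 cM is reported as 1 Mb). Above `maxPairs` pairs per chromosome a seeded
#' random subsample is used.
#'
#' @param pop a [Population-class] (marker haplotypes are used).
#' @param breaks distance bin boundaries in Mb.
#' @param maxPairs cap on pairs evaluated per chromosome.
#' @param seed RNG seed for the pair subsample.
#' @return data.frame: bin lower/upper bound, midpoint, mean r2, pair count;
#'   empty bins have NA mean.
#' @export
ldDecayProfile <- function(pop, breaks = seq(0, 10, by = 0.25),
                           maxPairs = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- pop@genome
  nb <- length(breaks) - 1L
  sumr2 <- numeric(nb); npair <- integer(nb)
  maxd <- max(breaks)

  for (c in seq_len(g@nChromosomes)) {
    idx <- which(g@markerChrom == c)
    if (length(idx) < 2) next
    hap <- pop@markerHap[idx, , drop = FALSE]
    pos <- g@markerPos[idx]
    polym <- matrixStatsRowAnyDiff(hap)
    idx2 <- which(polym)
    if (length(idx2) < 2) next
    pr <- utils::combn(idx2, 2L)
    d <- pos[pr[2, ]] - pos[pr[1, ]]
    keep <- d <= maxd
    pr <- pr[, keep, drop = FALSE]; d <- d[keep]
    if (!length(d)) next
    if (length(d) > maxPairs) {
      s <- sample.int(length(d), maxPairs)
      pr <- pr[, s, drop = FALSE]; d <- d[s]
    }
    hc <- hap - rowMeans(hap)
    ss <- sqrt(rowSums(hc^2))
    num <- rowSums(hc[pr[1, ], , drop = FALSE] * hc[pr[2, ], , drop = FALSE])
    r2 <- (num / (ss[pr[1, ]] * ss[pr[2, ]]))^2
    bin <- findInterval(d, breaks, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    t1 <- tapply(r2[ok], factor(bin[ok], levels = seq_len(nb)), sum)
    t2 <- tapply(rep(1L, sum(ok)), factor(bin[ok], levels = seq_len(nb)), sum)
    sumr2 <- sumr2 + ifelse(is.na(t1), 0, t1)
    npair <- npair + ifelse(is.na(t2), 0L, as.integer(t2))
  }
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             meanR2 = ifelse(npair > 0, sumr2 / pmax(npair, 1L), NA_real_),
             nPairs = npair)
}

#' Per-QTL shares of the genetic variance
#'
#' For each QTL, the variance across the reference cohort of its genotypic
#' value (the sum of the animal's two allele effects) as a percentage of the
#' cohort's TBV variance. QTLs at or above `threshold` percent are the
#' topQTL.
#'
#' @param pop a [Population-class] with TBVs.
#' @param effects the [QTLEffects-class].
#' @param cohort animal ids of the reference cohort; defaults to the
#'   phenotyped animals.
#' @param threshold topQTL share threshold in percent.
#' @return data.frame (qtl, chrom, pos, share, top) sorted by genome order.
#' @export
qtlVarianceShares <- function(pop, effects, cohort = NULL, threshold = 1) {
  if (is.null(cohort)) cohort <- which(!is.na(pop@phenotype))
  if (length(cohort) < 2) stop("reference cohort must have at least 2 animals")
  cols <- as.vector(rbind(2L * cohort - 1L, 2L * cohort))
  h <- pop@qtlHap[, cols, drop = FALSE]
  nq <- nrow(h)
  e <- effects@effects
  vals <- matrix(e[cbind(rep.int(seq_len(nq), ncol(h)), as.vector(h))],
                 nq, ncol(h))
  gval <- vals[, c(TRUE, FALSE), drop = FALSE] +
    vals[, c(FALSE, TRUE), drop = FALSE]
  vq <- apply(gval, 1L, var)
  denom <- var(pop@tbv[cohort])
  if (!is.finite(denom) || denom <= 0)
    stop("zero total genetic variance in the reference cohort")
  share <- vq / denom * 100
  data.frame(qtl = seq_len(nq), chrom = pop@genome@qtlChrom,
             pos = pop@genome@qtlPos, share = share,
             top = share >= threshold)
}

#' Variance explained by SNPs in consecutive windows
#'
#' Splits each chromosome into consecutive windows of `windowSize` Mb
#' (1 cM = 1 Mb on simulated maps). The window genetic value of an animal is
#' the dosage-weighted sum of the window's SNP effects; `pvar` is the
#' variance of that value across animals as a percentage of the variance of
#' the total genomic value M u. Windows without SNPs get pvar 0.
#'
#' @param uHat SNP effects (WssGBLUP back-solutions or Bayes C posterior
#'   means).
#' @param M dosage matrix, animals x SNPs.
#' @param map data.frame with `chrom` and `pos` per SNP.
#' @param chromLengths chromosome lengths (cM/Mb), one per chromosome.
#' @param windowSize window width in Mb.
#' @return data.frame: chrom, window, start, end, nSnps, pvar.
#' @export
windowVariances <- function(uHat, M, map, chromLengths, windowSize = 1) {
  stopifnot(length(uHat) == ncol(M), nrow(map) == ncol(M))
  gTot <- as.vector(M %*% uHat)
  vTot <- var(gTot)
  if (!is.finite(vTot) || vTot <= 0)
    stop("total genomic value has zero variance")
  win <- floor(map$pos / windowSize)
  out <- do.call(rbind, lapply(seq_along(chromLengths), function(c) {
    nw <- max(1L, ceiling(chromLengths[c] / windowSize))
    data.frame(chrom = c, window = seq_len(nw) - 1L)
  }))
  out$start <- out$window * windowSize
  out$end <- out$start + windowSize
  key <- paste(map$chrom, win)
  okey <- paste(out$chrom, out$window)
  grp <- split(seq_len(ncol(M)), key)
  out$nSnps <- 0L
  out$pvar <- 0
  for (k in names(grp)) {
    i <- match(k, okey)
    if (is.na(i)) next
    idx <- grp[[k]]
    w <- as.vector(M[, idx, drop = FALSE] %*% uHat[idx])
    out$nSnps[i] <- length(idx)
    out$pvar[i] <- var(w) / vTot * 100
  }
  out
}

#' Top marker windows
#'
#' The `nTop` windows with the largest explained-variance share; ties are
#' broken by genomic order (chromosome, then window), making the selection
#' deterministic.
#'
#' @param windows output of [windowVariances()].
#' @param nTop number of windows to keep (set equal to the topQTL count).
#' @return the selected rows, with a `mid` column (window midpoint).
#' @export
topWindows <- function(windows, nTop) {
  ord <- order(-windows$pvar, windows$chrom, windows$window)
  sel <- windows[ord[seq_len(min(nTop, nrow(windows)))], , drop = FALSE]
  sel$mid <- (sel$start + sel$end) / 2
  sel
}

#' Count true QTLs flagged by top windows
#'
#' One-to-one matching between top-window midpoints and topQTL positions on
#' the same chromosome: a window can flag a QTL when their distance is at
#' most `tolerance` Mb, each window and each QTL is used at most once, and
#' the count returned is the maximum number of QTLs that can be flagged
#' (exact bipartite matching by augmenting paths, candidates examined
#' nearest-first). This equals greedy nearest-first matching except in rare
#' geometries where the greedy pairing strands a matchable window.
#'
#' @param qtl data.frame of topQTL with `chrom` and `pos`.
#' @param windows data.frame of top windows with `chrom` and `mid` (see
#'   [topWindows()]).
#' @param tolerance maximum distance in Mb.
#' @return integer count of matched QTLs (NtrueQTL).
#' @export
matchTrueQtl <- function(qtl, windows, tolerance = 1) {
  if (!nrow(qtl) || !nrow(windows)) return(0L)
  D <- abs(outer(windows$mid, qtl$pos, "-"))
  D[outer(windows$chrom, qtl$chrom, "!=")] <- Inf
  nW <- nrow(D); nQ <- ncol(D)
  matchQ <- integer(nQ) # window matched to each QTL (0 = free)
  tryAugment <- function(w, visited) {
    cand <- which(is.finite(D[w, ]) & D[w, ] <= tolerance)
    for (q in cand[order(D[w, cand])]) {
      if (visited[q]) next
      visited[q] <- TRUE
      if (matchQ[q] == 0L || Recall(matchQ[q], visited)) {
        matchQ[q] <<- w
        return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (w in seq_len(nW))
    if (tryAugment(w, rep(FALSE, nQ))) n <- n + 1L
  n
}

#' Aggregate replicate statistics into a summary table
#'
#' Means and SDs of the per-cell detection statistics over replicates, in the
#' canonical row order: Bayes C (both inclusion fractions), WssGBLUP SI
#' w1--w3, SII w1--w3, followed by the true-value row.
#'
#' @param stats list with one data.frame per replicate; each must have a
#'   `cell` column and identical cell sets, plus numeric statistic columns.
#' @return data.frame of cell, then mean and SD per statistic. With a single
#'   replicate the SDs are NA.
#' @export
aggregateReplicates <- function(stats) {
  if (!length(stats)) stop("no replicate statistics supplied")
  cells <- stats[[1]]$cell
  for (s in stats)
    if (!identical(sort(s$cell), sort(cells)))
      stop("replicates have inconsistent cell sets")
  num <- setdiff(names(stats[[1]]),
                 c("cell", "replicate"))
  ord <- .cellOrder(cells)
  out <- data.frame(cell = ord)
  for (v in num) {
    vals <- sapply(stats, function(s) s[[v]][match(ord, s$cell)])
    vals <- matrix(vals, nrow = length(ord))
    out[[paste0(v, "_mean")]] <- rowMeans(vals)
    out[[paste0(v, "_sd")]] <- if (ncol(vals) > 1) apply(vals, 1, sd)
      else NA_real_
  }
  out
}

.cellOrder <- function(cells) {
  canon <- c("BayesC_pi0.99", "BayesC_pi0.999",
             "SIw1", "SIw2", "SIw3", "SIIw1", "SIIw2", "SIIw3", "true")
  c(canon[canon %in% cells], sort(setdiff(cells, canon)))
}
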