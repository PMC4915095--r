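#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve norm writeMM
NULL

.checkPedigree <- function(ped) {
  if (is(ped, "Population")) ped <- ped@pedigree
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (!identical(as.integer(ped$id), seq_len(n)))
    stop("pedigree ids must be 1..n in order")
  s <- as.integer(ped$sire); d <- as.integer(ped$dam)
  if (any(s < 0) || any(d < 0) || any(s > n) || any(d > n))
    stop("parent ids out of range")
  if (any(s >= ped$id & s > 0) || any(d >= ped$id & d > 0))
    stop("pedigree is cyclic or not sorted: parents must precede offspring")
  list(sire = s, dam = d, n = n)
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense Wright numerator relationship matrix A by the tabular recursion:
#' off-diagonals are parent averages, the diagonal is 1 plus half the
#' parents' relationship (1 + inbreeding coefficient).
#'
#' @param ped pedigree data.frame (id, sire, dam; 0 = unknown, parents before
#'   offspring) or a [Population-class].
#' @return dense numeric matrix n x n.
#' @export
buildA <- function(ped) {
  p <- .checkPedigree(ped)
  A <- cpp_tabular_A(p$sire, p$dam)
  dimnames(A) <- list(seq_len(p$n), seq_len(p$n))
  A
}

#' Inbreeding coefficients
#'
#' Meuwissen & Luo ancestor-tracing algorithm; equals `diag(buildA(ped)) - 1`.
#' @inheritParams buildA
#' @export
inbreeding <- function(ped) {
  p <- .checkPedigree(ped)
  cpp_inbreeding(p$sire, p$dam)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' 1/m_i to its own diagonal, -1/(2 m_i) to animal-parent entries and
#' 1/(4 m_i) among its known parents, where m_i is the Mendelian-sampling
#' variance (0.5 - 0.25 (F_s + F_d) with both parents known, 0.75 - 0.25 F_p
#' with one, 1 with none).
#'
#' @inheritParams buildA
#' @param inbreeding account for inbreeding in the Mendelian-sampling
#'   variances (exact). Setting this to FALSE treats all parents as
#'   non-inbred, a standard approximation for very deep pedigrees where the
#'   ancestor-tracing cost dominates and coefficients stay near zero.
#' @return sparse symmetric matrix (Matrix package).
#' @export
buildAinv <- function(ped, inbreeding = TRUE) {
  p <- .checkPedigree(ped)
  FF <- if (inbreeding) cpp_inbreeding(p$sire, p$dam) else numeric(p$n)
  s <- p$sire; d <- p$dam; n <- p$n
  Fs <- ifelse(s > 0, FF[pmax(s, 1)], 0)
  Fd <- ifelse(d > 0, FF[pmax(d, 1)], 0)
  m <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
              ifelse(s > 0 | d > 0, 0.75 - 0.25 * (Fs + Fd), 1))
  al <- 1 / m
  i <- seq_len(n)

  ii <- i; jj <- i; xx <- al
  hs <- s > 0
  ii <- c(ii, i[hs], s[hs]); jj <- c(jj, s[hs], i[hs])
  xx <- c(xx, rep(-al[hs] / 2, 2))
  hd <- d > 0
  ii <- c(ii, i[hd], d[hd]); jj <- c(jj, d[hd], i[hd])
  xx <- c(xx, rep(-al[hd] / 2, 2))
  ii <- c(ii, s[hs], d[hd]); jj <- c(jj, s[hs], d[hd])
  xx <- c(xx, al[hs] / 4, al[hd] / 4)
  hb <- hs & hd
  ii <- c(ii, s[hb], d[hb]); jj <- c(jj, d[hb], s[hb])
  xx <- c(xx, rep(al[hb] / 4, 2))

  sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Pedigree relationship among a subset of animals
#'
#' A22, the block of the numerator relationship matrix for the (genotyped)
#' subset, computed by the tabular method on the pedigree pruned to the
#' subset's ancestors.
#'
#' @inheritParams buildA
#' @param ids animals defining the subset, in the order wanted for A22.
#' @return dense matrix `length(ids)` square, dimnames = ids.
#' @export
buildA22 <- function(ped, ids) {
  if (is(ped, "Population")) ped <- ped@pedigree
  p <- .checkPedigree(ped)
  keep <- rep(FALSE, p$n)
  keep[ids] <- TRUE
  repeat {
    par <- unique(c(p$sire[keep], p$dam[keep]))
    par <- par[par > 0]
    par <- par[!keep[par]]
    if (!length(par)) break
    keep[par] <- TRUE
  }
  sub <- which(keep)
  newId <- integer(p$n)
  newId[sub] <- seq_along(sub)
  s <- ifelse(p$sire[sub] > 0, newId[pmax(p$sire[sub], 1)], 0L)
  d <- ifelse(p$dam[sub] > 0, newId[pmax(p$dam[sub], 1)], 0L)
  A <- cpp_tabular_A(as.integer(s), as.integer(d))
  out <- A[newId[ids], newId[ids], drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' VanRaden genomic relationship matrix
#'
#' G = P D P' / sum(2 p q) where P is the column-centred dosage matrix
#' (entry = dosage - 2p) and D optional SNP weights (identity by default).
#' Monomorphic SNPs (frequency 0 or 1) are excluded with a warning.
#'
#' @param M dosage matrix, animals x SNPs, entries 0/1/2.
#' @param freqs allele frequencies per SNP; defaults to the observed
#'   frequencies in `M`.
#' @param weights optional per-SNP weights (diagonal of D).
#' @return dense symmetric matrix, animals square.
#' @export
buildG <- function(M, freqs = NULL, weights = NULL) {
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  stopifnot(length(freqs) == ncol(M))
  mono <- freqs <= 0 | freqs >= 1
  if (any(mono)) {
    warning(sprintf("%d monomorphic SNPs excluded from G", sum(mono)))
    M <- M[, !mono, drop = FALSE]
    freqs <- freqs[!mono]
    if (!is.null(weights)) weights <- weights[!mono]
  }
  if (!ncol(M)) stop("no polymorphic SNPs left")
  P <- sweep(M, 2L, 2 * freqs)
  denom <- sum(2 * freqs * (1 - freqs))
  G <- if (is.null(weights)) tcrossprod(P) / denom else
    tcrossprod(sweep(P, 2L, weights, "*"), P) / denom
  G <- (G + base::t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Single-step combined relationship matrix inverse
#'
#' H combines pedigree and genomic information; its inverse is the pedigree
#' inverse plus a correction on the genotyped block:
#' Hinv = Ainv + \[0, 0; 0, Gb^-1 - A22^-1\], with Gb a blend of the genomic
#' matrix and A22 for invertibility (default 0.95 G + 0.05 A22).
#'
#' @param Ainv sparse inverse pedigree relationship matrix (all animals).
#' @param G genomic relationship matrix of the genotyped animals.
#' @param A22 pedigree relationship block of the genotyped animals, in the
#'   same order as `G`.
#' @param genoIndex row positions of the genotyped animals within `Ainv`.
#' @param blend weight of A22 in the blended genomic matrix.
#' @return sparse symmetric matrix of `nrow(Ainv)` square.
#' @export
buildHinv <- function(Ainv, G, A22, genoIndex, blend = 0.05) {
  ng <- length(genoIndex)
  if (ng == 0L) return(Ainv)
  stopifnot(nrow(G) == ng, nrow(A22) == ng)
  Gb <- (1 - blend) * G + blend * A22
  Gbi <- tryCatch(chol2inv(chol(Gb)), error = function(e)
    stop("blended genomic matrix is singular; increase `blend`", call. = FALSE))
  block <- Gbi - chol2inv(chol(A22))
  idx <- rep(genoIndex, each = ng)
  jdx <- rep(genoIndex, times = ng)
  Ainv + sparseMatrix(i = idx, j = jdx, x = as.vector(base::t(block)),
                      dims = dim(Ainv))
}

#' Export a matrix in MatrixMarket coordinate format
#'
#' @param m a matrix (dense or sparse).
#' @param path output file.
#' @export
exportMatrixMarket <- function(m, path) {
  writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
          path)
  invisible(path)
}
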