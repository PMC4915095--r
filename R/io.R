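#' Write a pedigree as CSV
#'
#' Columns id, sire, dam, sex, generation (0 = unknown parent).
#' @param pop a [Population-class] (or a pedigree data.frame).
#' @param path output file.
#' @export
writePedigreeCsv <- function(pop, path) {
  ped <- if (is(pop, "Population")) pop@pedigree else pop
  data.table::fwrite(ped, path)
  invisible(path)
}

#' @rdname writePedigreeCsv
#' @export
readPedigreeCsv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write phenotypes as CSV
#'
#' One row per phenotyped animal: id, phenotype.
#' @param pop a [Population-class].
#' @param path output file.
#' @export
writePhenotypeCsv <- function(pop, path) {
  ids <- which(!is.na(pop@phenotype))
  data.table::fwrite(data.frame(id = ids, phenotype = pop@phenotype[ids]),
                     path)
  invisible(path)
}

#' Write genotypes in PLINK .ped/.map text format
#'
#' Alleles are coded 1/2; the .map carries the position both in cM and in bp
#' through the 1 cM = 1 Mb convention of the simulated maps. By default the
#' genotyped animals are written.
#'
#' @param pop a [Population-class].
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are created.
#' @param ids animals to write.
#' @export
writePlink <- function(pop, prefix, ids = NULL) {
  if (is.null(ids)) ids <- which(pop@genotyped)
  if (!length(ids)) stop("no animals to write")
  ped <- pop@pedigree
  g <- pop@genome
  cols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  hap <- pop@markerHap[, cols, drop = FALSE]

  m <- nMarkers(g)
  geno <- matrix("", length(ids), 2L * m)
  geno[, seq(1L, 2L * m, 2L)] <- base::t(hap[, c(TRUE, FALSE), drop = FALSE])
  geno[, seq(2L, 2L * m, 2L)] <- base::t(hap[, c(FALSE, TRUE), drop = FALSE])
  fam <- cbind(1L, ids, ped$sire[ids], ped$dam[ids],
               ifelse(ped$sex[ids] == "M", 1L, 2L),
               ifelse(is.na(pop@phenotype[ids]), -9,
                      pop@phenotype[ids]))
  data.table::fwrite(data.table::as.data.table(cbind(fam, geno)),
                     paste0(prefix, ".ped"), sep = " ", col.names = FALSE)
  map <- data.frame(chrom = g@markerChrom,
                    snp = sprintf("M%d", seq_len(m)),
                    cm = g@markerPos,
                    bp = round(g@markerPos * 1e6))
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK .ped/.map text genotypes
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return list: `fam` (id, sire, dam, sex, phenotype), `M` (dosage matrix
#'   counting allele 2), `map` (chrom, snp, cm, bp).
#' @export
readPlink <- function(prefix) {
  map <- as.data.frame(data.table::fread(paste0(prefix, ".map"),
                                         col.names = c("chrom", "snp", "cm",
                                                       "bp")))
  ped <- as.data.frame(data.table::fread(paste0(prefix, ".ped"),
                                         header = FALSE))
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped/map mismatch: expected ", 6 + 2 * m, " columns, found ",
         ncol(ped))
  fam <- data.frame(id = ped[[2]], sire = ped[[3]], dam = ped[[4]],
                    sex = ifelse(ped[[5]] == 1, "M", "F"),
                    phenotype = ifelse(ped[[6]] == -9, NA_real_, ped[[6]]))
  al <- as.matrix(ped[, -(1:6)])
  M <- (al[, seq(1L, 2L * m, 2L), drop = FALSE] == 2) +
    (al[, seq(2L, 2L * m, 2L), drop = FALSE] == 2)
  storage.mode(M) <- "integer"
  rownames(M) <- fam$id
  colnames(M) <- map$snp
  list(fam = fam, M = M, map = map)
}

#' Write the true-QTL table
#'
#' TSV of per-QTL chromosome, position, variance share (%) and topQTL flag.
#' @param truth output of [qtlVarianceShares()].
#' @param path output file.
#' @export
writeQtlTruth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' The file may carry `ldLevel`, `scale`, `nReplicates`, `baseSeed` and any
#' of the configuration sub-lists (genome, panel, historical, expansion,
#' selection, genotyping, bayesc, trait, analysis); unspecified values come
#' from the scale preset.
#'
#' @param path YAML file.
#' @return an [experimentConfig()].
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(ldLevel = y$ldLevel %||% "hld",
               scale = y$scale %||% "desk",
               nReplicates = y$nReplicates %||% 10L,
               baseSeed = y$baseSeed %||% 1L)
  extra <- y[setdiff(names(y), c("ldLevel", "scale", "nReplicates",
                                 "baseSeed"))]
  do.call(experimentConfig, c(args, extra))
}
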