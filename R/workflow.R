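#' Experiment configuration
#'
#' Bundles every parameter of one simulation-and-GWAS experiment. Three scale
#' presets are provided: `"full"` is the headline design (2,333 cM genome,
#' 735,293 simulated markers, 7,000 QTLs, 90,000 selection animals, 550,000
#' MCMC iterations); `"desk"` is a reduced configuration preserving the same
#' structure (600 cM, 6,000 markers, 700 QTLs, 12,000 selection animals);
#' `"mini"` is a further-reduced configuration sized so a ten-replicate
#' experiment runs in minutes, used by the package's own qualitative checks.
#' Any element can be overridden through `...` (named sub-lists are merged).
#'
#' @param ldLevel "hld" (long bottleneck, high LD) or "lld" (short
#'   bottleneck, low LD).
#' @param scale one of "mini", "desk", "full".
#' @param nReplicates replicates of the whole pipeline.
#' @param baseSeed base RNG seed; every phase and analysis cell derives its
#'   own stream from (baseSeed, replicate, name).
#' @param ... overrides, e.g. `selection = list(nGenerations = 3)`.
#' @return list of class `ssqtlConfig`.
#' @export
experimentConfig <- function(ldLevel = c("hld", "lld"),
                             scale = c("mini", "desk", "full"),
                             nReplicates = 10L, baseSeed = 1L, ...) {
  ldLevel <- match.arg(ldLevel)
  scale <- match.arg(scale)
  preset <- switch(scale,
    full = list(
      genome = list(nChromosomes = 29L, totalLength = 2333,
                    nMarkerLoci = 735293L, nQtlLoci = 7000L,
                    mutationRate = 1e-4),
      panel = list(mafMin = 0.02, nMarkers = 335000L, nQtl = 1000L),
      historical = list(constantGenerations = 1000L, constantSize = 1000L,
                        declineGenerations = c(hld = 2020L, lld = 1020L),
                        finalSize = 200L),
      expansion = list(initialDams = 100L, nGenerations = 6L,
                       offspringPerDam = 5L),
      selection = list(nGenerations = 15L, nSires = 240L, nDams = 6000L,
                       replacementRate = 0.2),
      genotyping = list(nGenotyped = 2000L, lastGens = 3L),
      bayesc = list(chainLength = 550000L, burnIn = 50000L, thin = 50L)),
    desk = list(
      genome = list(nChromosomes = 29L, totalLength = 600,
                    nMarkerLoci = 9000L, nQtlLoci = 900L,
                    mutationRate = 1e-4),
      panel = list(mafMin = 0.02, nMarkers = 2750L, nQtl = 300L),
      historical = list(constantGenerations = 400L, constantSize = 400L,
                        declineGenerations = c(hld = 804L, lld = 404L),
                        finalSize = 100L),
      expansion = list(initialDams = 40L, nGenerations = 6L,
                       offspringPerDam = 5L),
      selection = list(nGenerations = 5L, nSires = 96L, nDams = 2400L,
                       replacementRate = 0.2),
      genotyping = list(nGenotyped = 800L, lastGens = 3L),
      bayesc = list(chainLength = 55000L, burnIn = 5000L, thin = 5L)),
    mini = list(
      genome = list(nChromosomes = 10L, totalLength = 150,
                    nMarkerLoci = 3200L, nQtlLoci = 320L,
                    mutationRate = 1e-4),
      panel = list(mafMin = 0.02, nMarkers = 700L, nQtl = 60L),
      historical = list(constantGenerations = 300L, constantSize = 150L,
                        declineGenerations = c(hld = 240L, lld = 120L),
                        finalSize = 60L),
      expansion = list(initialDams = 12L, nGenerations = 5L,
                       offspringPerDam = 5L),
      selection = list(nGenerations = 5L, nSires = 24L, nDams = 360L,
                       replacementRate = 0.2),
      genotyping = list(nGenotyped = 240L, lastGens = 3L),
      bayesc = list(chainLength = 5000L, burnIn = 1000L, thin = 4L)))

  cfg <- c(preset, list(
    trait = list(h2 = 0.14, varP = 1, gammaShape = 0.4),
    analysis = list(nIterations = 3L, blend = 0.05, windowSize = 1,
                    threshold = 1, bayesPi = c(0.99, 0.999)),
    ldLevel = ldLevel, scale = scale,
    nReplicates = as.integer(nReplicates), baseSeed = as.integer(baseSeed)))

  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "ssqtlConfig")
}

# Deterministic per-phase / per-cell seed below 2^31, derived from the base
# seed, the replicate and a stream name.
.deriveSeed <- function(baseSeed, replicate, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(baseSeed) * 1000003 + replicate * 7919 + h * 104729) %%
               2147483629 + 1)
}

#' Schedules implied by a configuration
#'
#' @param config an [experimentConfig()].
#' @return list with the historical, expansion and selection
#'   [PopSchedule-class] objects and the [TraitSpec-class].
#' @export
configSchedules <- function(config) {
  h <- config$historical
  decl <- h$declineGenerations[[config$ldLevel]]
  list(
    historical = historicalSchedule(h$constantGenerations, h$constantSize,
                                    decl, h$finalSize,
                                    hld = config$ldLevel == "hld"),
    expansion = expansionSchedule(config$expansion$initialDams,
                                  config$expansion$nGenerations,
                                  config$expansion$offspringPerDam),
    selection = selectionSchedule(config$selection$nGenerations,
                                  config$selection$nSires,
                                  config$selection$nDams,
                                  config$selection$replacementRate),
    trait = traitSpec(config$trait$h2, config$trait$varP,
                      config$trait$gammaShape))
}

#' Simulate one replicate's dataset
#'
#' Historical population, panel selection, QTL effects, expansion and
#' selection phases, with one derived seed per phase so that all analysis
#' cells of a replicate consume the identical dataset.
#'
#' @param config an [experimentConfig()].
#' @param replicate replicate number.
#' @return list: `pop` (the final [Population-class]), `effects`
#'   ([QTLEffects-class]), `trait`, `histPop` (last historical generation on
#'   the selected panel, before expansion).
#' @export
simulateReplicate <- function(config, replicate = 1L) {
  sc <- configSchedules(config)
  g <- config$genome
  genome <- makeGenome(g$nChromosomes, g$totalLength, g$nMarkerLoci,
                       g$nQtlLoci, g$mutationRate,
                       seed = .deriveSeed(config$baseSeed, replicate, "genome"))
  hist <- simulateHistorical(genome, sc$historical,
                             seed = .deriveSeed(config$baseSeed, replicate,
                                                paste0("hist-", config$ldLevel)))
  panel <- selectSegregatingLoci(hist, config$panel$mafMin,
                                 config$panel$nMarkers, config$panel$nQtl,
                                 seed = .deriveSeed(config$baseSeed, replicate,
                                                    "panel"))
  effects <- assignQtlEffects(panel, sc$trait,
                              seed = .deriveSeed(config$baseSeed, replicate,
                                                 "effects"))
  panel <- computeTbv(panel, effects)
  exp <- simulateExpansion(panel, sc$expansion, effects,
                           seed = .deriveSeed(config$baseSeed, replicate,
                                              "expansion"))
  pop <- simulateSelection(exp, sc$trait, effects, sc$selection,
                           nGenotyped = config$genotyping$nGenotyped,
                           genotypeLastGens = config$genotyping$lastGens,
                           seed = .deriveSeed(config$baseSeed, replicate,
                                              "selection"))
  list(pop = pop, effects = effects, trait = sc$trait, histPop = panel)
}

# Detection statistics of one analysis cell given its SNP effects.
.evaluateCell <- function(uHat, M, map, chromLengths, truthTop, nTop,
                          windowSize = 1, tolerance = 1) {
  wins <- windowVariances(uHat, M, map, chromLengths, windowSize)
  tw <- topWindows(wins, nTop)
  data.frame(pvarTop = sum(tw$pvar), pvar1st = max(tw$pvar),
             nTrue = matchTrueQtl(truthTop, tw, tolerance))
}

#' Run every analysis cell on one replicate
#'
#' Runs WssGBLUP (scenarios SI and SII, weight iterations w1..w3) and Bayes C
#' (both inclusion fractions) on one simulated dataset and scores each cell
#' against the true QTLs: `pvarTop` (% genetic variance captured by the top
#' marker windows, as many windows as there are topQTL), `pvar1st` (largest
#' window share) and `nTrue` (topQTL flagged by a top window within the
#' matching tolerance). The returned `stats` also carries a `true` row with
#' Pvar_topQTL, Pvar_1stQTL and the topQTL count in the same columns.
#'
#' @param config an [experimentConfig()].
#' @param replicate replicate number.
#' @param data optional result of [simulateReplicate()] to reuse.
#' @return list: `stats` (data.frame: replicate, cell, pvarTop, pvar1st,
#'   nTrue), `truth` (per-QTL shares), `uHat` (SNP effects per cell),
#'   `data`.
#' @export
runReplicate <- function(config, replicate = 1L, data = NULL) {
  if (is.null(data)) data <- simulateReplicate(config, replicate)
  pop <- data$pop; trait <- data$trait; effects <- data$effects
  an <- config$analysis

  # reference cohort: phenotyped females of the genotyped-era generations
  # (pooling across all cohorts would fold the selection trend into the
  # variances)
  ped <- pop@pedigree
  refCohort <- ped$id[ped$generation > max(ped$generation) -
                        config$genotyping$lastGens &
                        !is.na(pop@phenotype)]
  truth <- qtlVarianceShares(pop, effects, cohort = refCohort,
                             threshold = an$threshold)
  truthTop <- truth[truth$top, , drop = FALSE]
  nTop <- nrow(truthTop)
  if (nTop == 0L)
    stop("no QTL reaches the topQTL threshold in this replicate")

  genoIds <- which(pop@genotyped)
  M <- markerDosage(pop, genoIds)
  map <- markerMap(pop@genome)
  chromLengths <- pop@genome@chromLengths

  uHat <- list()
  rows <- list()

  for (scen in c("SI", "SII")) {
    set.seed(.deriveSeed(config$baseSeed, replicate, paste0("wss-", scen)))
    fit <- runWssGBLUP(pop, trait, scen, nIterations = an$nIterations,
                       blend = an$blend)
    for (it in seq_len(an$nIterations)) {
      cell <- paste0(scen, "w", it)
      uHat[[cell]] <- fit$uHat[, it]
      rows[[cell]] <- cbind(cell = cell,
                            .evaluateCell(fit$uHat[, it], M, map,
                                          chromLengths, truthTop, nTop,
                                          an$windowSize))
    }
  }

  yGeno <- pop@phenotype[genoIds]
  for (pi in an$bayesPi) {
    cell <- paste0("BayesC_pi", format(pi, trim = TRUE))
    cfgB <- bayesCConfig(piExcluded = pi,
                         chainLength = config$bayesc$chainLength,
                         burnIn = config$bayesc$burnIn,
                         thin = config$bayesc$thin)
    post <- runBayesC(yGeno, M, cfgB, trait,
                      seed = .deriveSeed(config$baseSeed, replicate, cell))
    uHat[[cell]] <- post@snpEffect
    rows[[cell]] <- cbind(cell = cell,
                          .evaluateCell(post@snpEffect, M, map, chromLengths,
                                        truthTop, nTop, an$windowSize))
  }

  stats <- do.call(rbind, rows)
  stats <- rbind(stats,
                 data.frame(cell = "true",
                            pvarTop = sum(truthTop$share),
                            pvar1st = max(truth$share),
                            nTrue = nTop))
  stats <- cbind(replicate = replicate, stats)
  rownames(stats) <- NULL
  list(stats = stats, truth = truth, uHat = uHat, data = data)
}

#' Run the full experiment
#'
#' Simulates `config$nReplicates` datasets, runs the eight analysis cells on
#' each, and aggregates the detection statistics into a summary table (mean
#' and SD per cell plus the true-value row). A replicate whose analysis fails
#' is recorded as incomplete, excluded from the aggregate, and reported with
#' a warning.
#'
#' @param config an [experimentConfig()].
#' @param outDir optional directory; when given, per-replicate artifacts
#'   (pedigree, PLINK genotypes, phenotypes, QTL truth, SNP effects) and the
#'   summary and log are written there.
#' @param keepReplicates return the per-replicate results as well.
#' @return list: `summary` (aggregated table), `perReplicate` (stats rows),
#'   `failed` (replicate numbers), `log` (character lines).
#' @export
runExperiment <- function(config, outDir = NULL, keepReplicates = FALSE) {
  logLines <- character()
  note <- function(level, ...) {
    line <- sprintf("%s %s %s", format(Sys.time(), "%H:%M:%S"), level,
                    paste0(...))
    logLines <<- c(logLines, line)
    invisible(line)
  }
  note("INFO", "experiment: ld=", config$ldLevel, " scale=", config$scale,
       " replicates=", config$nReplicates, " baseSeed=", config$baseSeed)

  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  perRep <- list(); results <- list(); failed <- integer()
  for (r in seq_len(config$nReplicates)) {
    res <- tryCatch(runReplicate(config, r), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("replicate %d incomplete and excluded: %s", r,
                      conditionMessage(res)))
      note("WARN", "replicate ", r, " failed: ", conditionMessage(res))
      failed <- c(failed, r)
      next
    }
    note("INFO", "replicate ", r, " complete; topQTL=",
         sum(res$truth$top))
    perRep[[length(perRep) + 1L]] <- res$stats
    if (keepReplicates) results[[r]] <- res
    if (!is.null(outDir)) .writeReplicate(res, config, r, outDir)
  }
  if (!length(perRep)) stop("every replicate failed")
  summary <- aggregateReplicates(perRep)

  if (!is.null(outDir)) {
    data.table::fwrite(summary, file.path(outDir, "summary.tsv"), sep = "\t")
    writeLines(logLines, file.path(outDir, "experiment.log"))
  }
  list(summary = summary, perReplicate = do.call(rbind, perRep),
       failed = failed, log = logLines,
       replicates = if (keepReplicates) results else NULL)
}

.writeReplicate <- function(res, config, r, outDir) {
  dir <- file.path(outDir, sprintf("rep-%02d", r))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- res$data$pop
  writePedigreeCsv(pop, file.path(dir, "pedigree.csv"))
  writePhenotypeCsv(pop, file.path(dir, "phenotypes.csv"))
  writePlink(pop, file.path(dir, "genotypes"))
  writeQtlTruth(res$truth, file.path(dir, "qtl_truth.tsv"))
  map <- markerMap(pop@genome)
  for (cell in names(res$uHat)) {
    data.table::fwrite(
      data.frame(chrom = map$chrom, pos = map$pos, uHat = res$uHat[[cell]]),
      file.path(dir, paste0("snp_effects_", cell, ".tsv")), sep = "\t")
  }
  invisible(dir)
}
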