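---
title: "Simulating QTL mapping with phenotypes from non-genotyped animals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating QTL mapping with phenotypes from non-genotyped animals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssqtl)
```

## The question the package addresses

In livestock GWAS, most phenotyped animals are not genotyped. The
weighted single-step GBLUP method (WssGBLUP) can still use their records,
because the mixed model is solved on the combined pedigree-plus-genomic
relationship matrix **H** and SNP effects are back-solved afterwards from
the genotyped animals' predicted breeding values. Whether those extra
records actually improve QTL *detection* — and how the answer depends on
the population's linkage disequilibrium (LD) and on iterative SNP
weighting — is an empirical question. `ssqtl` implements a complete
simulation experiment for it: a forward-in-time population simulator
producing high-LD and low-LD populations with a low-heritability,
sex-limited polygenic trait; WssGBLUP under two phenotyping scenarios;
a Bayes C sampler as a variable-selection contrast; and window-based
detection statistics scored against the simulated ("true") QTLs.

## The simulated populations

Each replicate builds one dataset in four phases.

**Historical phase.** Random union of gametes at constant size, followed
by a gradual linear decline that acts as a bottleneck. The decline length
is the only difference between the two study arms: a long decline yields
the high-LD population (HLD), a short one the low-LD population (LLD).
Biallelic markers start at frequency 0.5; QTLs carry 2–4 alleles starting
at equal frequencies. Recurrent mutation (rate $10^{-4}$ per copy and
generation, i.e. Poisson mean $u = 2\,n_\text{loci}\,10^{-4}$ mutations
per individual) operates in this phase only: a mutated marker flips its
allele, a mutated QTL moves to one of its other alleles uniformly. At
full scale this phase runs 1,000 constant generations at size 1,000 and
then declines to 200 over 2,020 (HLD) or 1,020 (LLD) generations.

**Panel selection.** From the last historical generation, markers with
MAF ≥ 0.02 and segregating QTLs are sampled uniformly (full scale:
335,000 markers of 735,293 simulated; 1,000 QTLs of 7,000). QTL allele
effects are drawn from a gamma distribution with shape 0.4, each allele
receiving an independent random sign, and rescaled once so the variance
of true breeding values (TBV) in the last historical generation equals
$\sigma^2_a = h^2\sigma^2_p = 0.14$.

**Expansion.** Exponential growth under random mating: the number of dams
doubles each generation (full scale 100 → 3,200 over six generations,
five products per dam, 100 % replacement), ending with 16,000 animals.

**Selection.** 240 sires and 6,000 dams found a population bred for 15
generations, one product per dam, 20 % of sires and dams replaced each
generation by the top-EBV candidates of the newest cohort. EBVs come from
a pedigree BLUP (overall mean + animal, the true variance ratio
$\lambda = \sigma^2_e/\sigma^2_a = 0.86/0.14$) refit each generation on
all female records to date; unphenotyped candidates are ranked through
their relatives via the BLUP itself. Phenotypes are sex-limited
(mirroring age at first calving): every female receives
$y = \text{TBV} + e$, $e \sim N(0, 0.86)$, at birth; males carry no
record. 2,000 females of the last three generations are flagged as
genotyped.

Design choices the experiment's description leaves open, fixed here once:

* **Meiosis** follows a Haldane model — crossover count per chromosome
  Poisson(length in Morgans), positions uniform, no interference.
  Markers and QTLs segregate on the same recombination events.
* **Chromosome lengths** are proportional to the bovine physical
  autosome lengths, normalised to the configured genome length
  (2,333 cM at full scale); locus counts per chromosome are proportional
  to length, positions uniform within chromosomes. For window analyses
  of simulated maps, 1 cM is identified with 1 Mb.
* **Cohort sexes** are a random permutation of a balanced vector: each
  animal is male or female with probability ½, but cohort counts are
  exactly half and half. This keeps the deterministic cohort bookkeeping
  of the design (e.g. 100 females among the last 200 historical animals,
  8,000 among the 16,000 expansion animals) and removes the possibility
  that a run aborts because a cohort randomly lacks enough dams.
* **Selection criterion**: "expected breeding value" is implemented as
  pedigree BLUP; parent averages fall out of the BLUP automatically for
  candidates without records.
* **Founder dams of the selection phase are phenotyped**, so the first
  round of selection already has data; expansion animals otherwise carry
  no records, matching their role as a neutral growth phase.
* **Seeding**: every phase and analysis cell derives its own seed from
  (base seed, replicate, stream name), so the SI and SII scenarios of a
  replicate consume byte-identical data and any run is reproducible from
  the configuration alone.

## The analyses

**WssGBLUP.** The mixed model $y = X\beta + Z_a a + e$ with
$\mathrm{var}(a) = H\sigma^2_a$ is solved with $H^{-1} = A^{-1} +
\begin{bmatrix}0&0\\0&G_b^{-1}-A_{22}^{-1}\end{bmatrix}$, where
$G = PDP'/\sum 2p_iq_i$ is the VanRaden genomic matrix on centred
dosages, $D$ the SNP weights, and $G_b = 0.95\,G + 0.05\,A_{22}$ the
blended matrix that guarantees invertibility (the blend fraction is a
configurable default; no additional scaling of the genomic block is
applied). SNP effects are back-solved as
$\hat u = D P' [P D P']^{-1}\hat a_g$ (with the same blend applied
consistently), weights are updated as $d_i \propto \hat u_i^2\,2p_i q_i$
and renormalised so $\sum d_i = m$ — the printed weighting rule omits
the factor 2, which the normalisation absorbs, so the two forms are
equivalent. Three iterations (w1 = identity weights, w2, w3) are run for
scenario **SI** (all phenotypes, including non-genotyped animals) and
**SII** (records of genotyped animals only). For real data with
estimable fixed effects SII phenotypes would be pre-adjusted by the
full-data BLUP solutions (`preadjustPhenotypes()`); the simulated trait
has an overall mean only, so no pre-adjustment is needed.

The mixed-model equations are solved by a sparse Cholesky factorisation
up to 50,000 unknowns and by Jacobi-preconditioned conjugate gradients
(relative residual $10^{-10}$) above; the solver reports its residual.

**Bayes C.** $y = 1\mu + \sum_i g_i b_i \delta_i + e$ on the genotyped
animals only, with $\pi$ (the excluded fraction) held essentially fixed
at 0.99 or 0.999 by beta pseudo-counts oriented to that mean with total
weight $10^{10}$. The printed prior ($\alpha = 10^8, \beta = 10^{10}$)
has mean 0.0099 and so contradicts the stated behaviour of pinning
$\pi \approx 0.99$; the stated behaviour wins here. Scaled inverse
chi-squared priors (df 4.2) are used for both variances, the SNP-effect
scale derived as $\sigma^2_a / ((1-\pi)\sum 2p_iq_i)$. The Gibbs sampler
integrates the effect out of the inclusion update, visits SNPs in fixed
index order for reproducibility, and at full scale runs 550,000
iterations (burn-in 50,000, thinning 50; 10,000 kept samples).

**Scoring.** Per-QTL shares of the genetic variance are the variance of
the QTL's genotypic value across the reference cohort — the phenotyped
females of the generations that supply the genotyped animals (pooling
all selection cohorts would fold the genetic trend into the variances
and shrink every share) — as a percentage of the cohort's TBV variance;
QTLs at or above 1 % are the topQTL. Each analysis contributes the same number
of top 1-Mb windows (`topMRKw` = topQTL count), scored by the share of
the total genomic-value variance across genotyped animals explained by
the window's SNPs. `NtrueQTL` counts topQTL flagged by a top window
within 1 Mb under an exact one-to-one maximum matching (augmenting
paths, candidates examined nearest-first); greedy nearest-first matching
gives the same count except in rare geometries where it strands a
matchable window, which is why the exact matching is used.

## Scale presets and what runs where

Three presets of `experimentConfig()` share the full design's structure:

| preset | genome | markers kept | QTLs kept | historical | selection | chain |
|---|---|---|---|---|---|---|
| `full` | 29 chr, 2,333 cM | 335,000 | 1,000 | 1,000 + 2,020/1,020 gens | 15 × 6,000 | 550k/50k/50 |
| `desk` | 29 chr, 600 cM | 2,750 | 300 | 400 + 804/404 gens | 5 × 2,400 | 55k/5k/5 |
| `mini` | 10 chr, 150 cM | 700 | 60 | 300 + 240/120 gens | 5 × 360 | 5k/1k/4 |

The package's own qualitative checks (LD-curve ordering, the w1→w3
shrinkage pattern, the SI-vs-SII comparison) run ten replicates per LD
level of a desk-type reduction sized between `mini` and `desk`
(15 chromosomes / 300 cM, 1,400 markers, 120 QTLs, 5,000 selection
animals, 300 genotyped — about 9 % of the phenotyped population, keeping
the genotyped share low as in the full design). The presets are the same
code at other sizes. The simulated:selected marker ratios in the
reduced presets are higher than at full scale because drift relative to
locus count is stronger in small populations; the ratios were sized so
the MAF ≥ 0.02 panel is reliably available.

The true-QTL statistics of the headline tables depend only on the QTL
loci, not the marker panel, so they are recomputed at the *full*
demographic scale by treating QTLs as unlinked. `qtlDriftStats()` runs
per-locus multinomial drift through the historical bottleneck (the
exact marginal model of the simulator), samples the segregating panel,
draws the signed gamma effects and computes each QTL's share of the
summed genetic variance — the construction `scripts/acceptance.R` uses.
`qtlStudyStats()` continues from the drifted frequencies with
Hardy–Weinberg founder genotypes and an explicit gene drop through the
expansion and EBV-selection phases at their full sizes, computing shares
within the genotyped-era cohort (the phenotyped females of the last
three generations; pooling across all cohorts would fold the selection
trend into the variances). Linkage between QTLs only adds zero-mean
noise to the total-variance denominator, so the unlinked treatment is
unbiased for share statistics while keeping the full-size schedules
tractable. Selection shrinks the cohort variance (Bulmer's effect)
slightly faster than it erodes the top QTLs' own variances, so the
full-design shares run somewhat above the drift-only ones.

## What passing the checks does and does not show

The generator emulates the study's statistical structure: drift-built
LD, a polygenic sex-limited trait with $h^2 = 0.14$, selection on
pedigree EBV, and genotyping restricted to recent females. It does not
emulate genotyping errors, non-additive gene action, contemporary-group
fixed effects, sex chromosomes, or real linkage maps, so agreement of
the package's statistics with the study's printed values speaks to the
implementation of the methods, not to their behaviour on any particular
real cattle population.

## Numerical choices

* Mixed-model solver tolerances: direct solves are verified to a
  relative residual below $10^{-8}$ (typically $10^{-12}$); the
  conjugate-gradient fallback iterates to $10^{-10}$.
* `buildG` excludes monomorphic SNPs with a warning; `runWssGBLUP` and
  `runBayesC` keep them in the output with zero effects so window maps
  stay aligned.
* Rank-deficient fixed-effect blocks are constrained (dependent columns
  zeroed) with a warning rather than rejected.
* Weight updates error out if every back-solved effect is zero
  (degenerate weighting); panel selection errors, naming the shortfall,
  if fewer eligible loci segregate than requested.
* Ties in window ranking are broken by genomic order, making every
  reported table deterministic under a fixed seed.

## A worked replicate

```{r example, eval = FALSE}
cfg <- experimentConfig("hld", "mini", nReplicates = 10, baseSeed = 1)
res <- runExperiment(cfg)
res$summary
```

The summary table mirrors the experiment's layout: one row per analysis
cell (Bayes C at both $\pi$ values, WssGBLUP SI and SII at w1–w3) with
the mean (SD) over replicates of the variance captured by the top
windows, the largest single-window share, and `NtrueQTL`, plus a
`true` row carrying the same statistics for the QTLs themselves.
`scripts/acceptance.R` recomputes the headline true-QTL statistics at
the full demographic scale with `qtlStudyStats()`.

## Known limitations

* The desk and full presets hold all haplotypes of a replicate in
  memory; the full preset's marker panel is sized for machines with
  tens of gigabytes and is provided as configuration, not exercised by
  the test suite.
* `qtlStudyStats()` treats QTLs as unlinked; it reproduces share
  statistics, not LD-sensitive quantities.
* REML variance estimation is out of scope: the simulation's true
  variance components drive both BLUP and the Bayes C prior scales.
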