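# ssqtl

Simulation-based assessment of how much phenotypic information from
**non-genotyped** animals contributes to QTL mapping of low-heritability
complex traits.

In commercial livestock populations, tens of thousands of animals carry
records but only a small recent cohort is genotyped. Single-step GBLUP
solves the mixed model

y = Xβ + Z_a a + e,  var(a) = H σ²_a,  var(e) = I σ²_e,

on the combined relationship matrix H, whose inverse is
H⁻¹ = A⁻¹ + [0 0; 0 G_b⁻¹ − A₂₂⁻¹] (A the pedigree relationship matrix,
G the VanRaden genomic matrix of the genotyped animals, G_b a 0.95/0.05
blend with A₂₂). SNP effects are back-solved from the genotyped animals'
predicted breeding values, û = D P′ [P D P′]⁻¹ â_g, and iteratively
reweighted with d_i ∝ û_i² 2p_i q_i (WssGBLUP, iterations w1–w3). Because
the model uses every record, the GWAS can be run **with** (scenario SI)
or **without** (scenario SII) the phenotypes of non-genotyped animals —
the contrast the package is built to quantify. A Bayes C Gibbs sampler
(y = 1μ + Σ g_i b_i δ_i + e, π of SNPs excluded a priori, held at 0.99
or 0.999) provides the variable-selection counterpart on the genotyped
animals.

The data come from a forward-in-time simulator: a bottlenecked historical
population (long bottleneck → high LD, short → low LD), exponential
expansion of the dam population, then 15 generations of truncation
selection on pedigree-BLUP EBVs with a sex-limited trait (h² = 0.14,
σ²_p = 1.0, 1,000 QTLs with signed gamma(0.4) allele effects). Detection
is scored on 1-Mb marker windows: the windows' explained-variance shares
and `NtrueQTL`, the number of QTLs with ≥ 1 % of the genetic variance
that are flagged by a top window within 1 Mb.

## A worked example

One replicate of the high-LD experiment at the package's reduced
(`mini`) scale — 10 chromosomes spanning 150 cM, 700 markers, 60 QTLs,
1,800 selection animals of which 240 recent females are genotyped:

```r
library(ssqtl)
cfg <- experimentConfig("hld", "mini", nReplicates = 1, baseSeed = 7)
rep1 <- runReplicate(cfg, 1)
rep1$stats
#>   replicate           cell  pvarTop   pvar1st nTrue
#> 1         1           SIw1 22.86119  6.665794     5
#> 2         1           SIw2 42.08934 17.708590     6
#> 3         1           SIw3 57.58142 20.811768     6
#> 4         1          SIIw1 18.53434  3.873116     5
#> 5         1          SIIw2 34.15525  8.317301     6
#> 6         1          SIIw3 56.08824 10.621620     5
#> 7         1  BayesC_pi0.99 46.32468 13.386492     6
#> 8         1 BayesC_pi0.999 52.85233 27.927041     5
#> 9         1           true 99.84535 17.207044    17
```

Read: 17 QTLs each explained ≥ 1 % of the genetic variance in this
replicate (together 99.8 %, the largest 17.2 %). Each analysis cell was
scored by its 17 best 1-Mb windows: under SI at w1 those windows carried
22.9 % of the genomic variance, the best single window 6.7 %, and 5 of
the 17 true QTLs were flagged within 1 Mb. Shrinking weights (w1 → w3)
concentrates variance in the top windows (23 % → 58 %) without a matching
gain in `nTrue` — the variance a window "explains" and the ability to
localise true QTLs are different things. `runExperiment(cfg)` repeats this over
replicates and aggregates a mean (SD) table in the same layout;
statistics at these reduced sizes are expected to differ from a
full-scale run. (Output shown from `baseSeed = 7`.)

The building blocks are exported individually — `simulateHistorical()`,
`selectSegregatingLoci()`, `assignQtlEffects()`, `simulateExpansion()`,
`simulateSelection()`, `buildA()` / `buildAinv()` / `buildG()` /
`buildHinv()`, `solveMME()`, `runWssGBLUP()`, `runBayesC()`,
`ldDecayProfile()`, `windowVariances()`, `matchTrueQtl()` — with
pedigree CSV, PLINK `.ped`/`.map` and YAML-configuration I/O in
`writePlink()`, `readPlink()`, `readExperimentConfig()`. See the
vignette (`vignettes/wssgblup-simulation.Rmd`) for the model details and
every design choice.

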