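# vmpscan

Detection and characterisation of **age-related variably methylated
positions (aVMPs)** — CpG sites whose DNA methylation *variance*
increases with age, independently of changes in mean methylation and of
blood cell composition.

Most age-associated CpGs track chronological age in their mean
(aDMPs).  aVMPs are a distinct, much rarer class: young individuals are
homogeneous at these sites while old individuals diverge, making them
candidate markers of *biological* age.  Their methylation is frequently
coupled to gene expression in *cis* and — via large correlated hubs — in
*trans*, notably to polycomb (PRC2) biology.  `vmpscan` is aimed at
epigenomics researchers analysing population-scale methylation cohorts
(e.g. Illumina 450k beta values with matched RNA-seq).

## The model

For CpG *i*, sample *j*, beta value `y_ij ∈ [0,1]`, age `a_j`, and
covariates `z_j` (sex, blood cell fractions):

1. **Mean model (stage 1):** `y_ij = α_i + β_i a_j + γ_iᵀ z_j + ε_ij`;
   `10·β_i` is the mean change per decade, Bonferroni-significant `β_i`
   marks an aDMP.
2. **Variance model (stage 2, Breusch–Pagan-type):**
   `ε̂_ij² = γ0_i + γ1_i a_j + δ_iᵀ z_j + u_ij`, with a Wald *t*-test on
   `γ1_i` (covariates adjusted, not tested).
3. **Effect size:** with fitted variance `v̂(a)` at covariate means,
   `ΔSD = √max(v̂(ā+5),0) − √max(v̂(ā−5),0)` — the SD change across the
   decade centred at the mean age.  An aVMP candidate needs Bonferroni
   `p ≤ 0.05` **and** `|ΔSD| ≥ 0.05` beta units per decade.
4. Candidates split into **gain** (hypomethylated young baseline,
   positive slope), **loss** (hypermethylated, negative slope) and
   **constant** (no mean change) subtypes; Z-scores
   `Z_ij = (M_ij − M̄_y,i)/σ_y,i` express deviation from the young
   (<30 y) reference.

Downstream: greedy 1-D clustering into aVMRs (≤1 kb gaps, ≥3 CpGs);
cis eQTM mapping (genes within 500 kb, per-CpG Bonferroni → best gene →
BH-FDR); trans mapping (pairs >5 Mb or cross-chromosome, one BH family,
hub filter at `⌊0.05·n_aVMP⌋` associations, up/down clustering of hub
genes); `log2` odds-ratio enrichment against interval tracks (Fisher
exact, optional permutations); cross-cohort replication with
direction-concordance statistics.  A synthetic-cohort generator with
exact planted truth (heteroscedastic beta-scale noise, cell-composition
confounding, cis links and correlated trans hubs) backs the test suite.

## Worked example

```r
library(vmpscan)
design <- simulationDesign(
  nSamples = 800, nCpgs = 400,
  classMix = c(null = 0.7, admp = 0.1, gain = 0.07, loss = 0.07,
               constant = 0.06),
  sdSlopePerDecade = 0.08, nGenes = 50, cisLinkFraction = 0.1,
  exprNoiseSd = 0.3, rngSeed = 7)
cohort <- simulateCohort(design)
cohort$beta
#> BetaSet with 400 CpGs and 800 samples
#>   positioned CpGs: 400
#>   age: 18.1-87.9 years
#>   cell fractions: neutro, lympho, mono, eos, baso

cfg <- vmpConfig(minYoung = 2, effectThresholdPerDecade = 0.02)
scan <- classifyAvmps(scanVariability(cohort$beta, cfg), cfg)
table(scan$class_label)
#> constant     gain     loss     none
#>       24       28       28      320
```

All 80 planted aVMP-class CpGs are flagged and classified (320 null/aDMP
CpGs stay `none`).  The effect filter is set to 0.02 here because
beta-scale truncation caps realized SD growth in long-range synthetic
cohorts (see the methods vignette); estimated effects for the planted
0.08/decade slope concentrate near the saturation point:

```r
summary(scan$sd_change_per_decade[scan$is_avmp_candidate])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.03548 0.03952 0.04072 0.04067 0.04220 0.04552
```

Mapping the detected aVMPs to simulated expression recovers every
planted cis link (8 of 8) as the top gene of its CpG:

```r
avmps <- scan$cpg_id[scan$is_avmp_candidate & scan$direction == "increase"]
expr <- simulateExpression(cohort, design)
cis <- cisMap(cohort$beta, expr$expr, avmps, cfg)
head(cis[, c("cpg_id", "gene_id", "beta_coefficient", "p_fdr")], 3)
#>     cpg_id  gene_id beta_coefficient         p_fdr
#> 1 cg000340 gene0019        0.9836409 2.310498e-102
#> 2 cg000353 gene0013        0.9926853 1.874175e-100
#> 3 cg000354 gene0037        1.0216570 1.714796e-113
nrow(merge(cis, expr$truth$cis, by = c("cpg_id", "gene_id")))
#> [1] 8
```

The `beta_coefficient` column is expression change per unit methylation
(planted effect: 1.0).  `runPipeline()` chains all stages (entropy,
scan, classify, zscore, regions, eqtm, enrich, replicate) over files or
a simulation design and writes seeded, re-runnable outputs plus a log of
every threshold applied.

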