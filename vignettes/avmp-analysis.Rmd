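---
title: "Detecting age-related variably methylated positions with vmpscan"
author: "vmpscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-related variably methylated positions with vmpscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA methylation at many CpG dinucleotides tracks chronological age in its
*mean* (age-related differentially methylated positions, aDMPs).  A
distinct and biologically more interesting class of sites shows an
age-related increase in *between-individual variance*: two old
individuals may carry very different methylation levels at such a CpG
while young individuals are homogeneous.  These age-related variably
methylated positions (aVMPs) are candidate markers of biological rather
than chronological age, and their methylation is frequently coupled to
gene expression, both locally (*cis*) and across the genome (*trans*),
notably to polycomb-repressive-complex biology.

`vmpscan` implements the full discovery pipeline on methylation beta
values (fractions in $[0,1]$): per-sample methylome entropy, a two-stage
heteroscedasticity scan, subtype classification, Z-scores against a
young reference, aggregation into regions (aVMRs), hierarchical cis and
trans expression mapping (eQTM), odds-ratio enrichment against interval
annotations, and cross-cohort replication.  A synthetic-cohort generator
with exact planted truth makes every stage testable without restricted
cohort data.

## Data model

A `BetaSet` wraps a `SummarizedExperiment`: the `"beta"` assay holds the
CpG $\times$ sample matrix, `rowData` the 1-based CpG point coordinates
(BED input is 0-based half-open; the point is the BED `end`), and
`colData` the covariates: `age` (years), `sex` (0/1, the textual coding
declared in the configuration), optional `batch`, and one column per
blood cell-type fraction.  An `ExprSet` holds normalized log-scale
expression with gene coordinates.  Expression is used exactly as
provided; normalization pipelines live upstream.

CpGs may carry missing values; a CpG enters an analysis only when
non-missing in at least 95\% of samples (configurable).  CpGs without
coordinates take part in all matrix-level analyses and are excluded from
positional stages only.

Because the cell fractions are compositional, one fraction (the largest
on average) is dropped from every design matrix; its name is recorded in
the scan attributes and the pipeline log.

## The variance scan

For CpG $i$ with beta values $y_{ij}$, stage 1 fits by OLS

$$y_{ij} = \alpha_i + \beta_i\,\mathrm{age}_j + \gamma_i^\top z_j +
\varepsilon_{ij},$$

with $z_j$ the sex and cell-fraction covariates.  $10\hat\beta_i$ is the
mean change per decade; a Bonferroni-significant age term marks an aDMP.
Stage 2 regresses the squared residuals $\hat\varepsilon_{ij}^2$ on the
same design — the Breusch–Pagan construction — and tests the age
coefficient with a Wald $t$-test.  We deliberately test *only* the age
coefficient rather than the classical global $nR^2$
Lagrange-multiplier statistic: sex and cell composition must be
*adjusted for* in the variance model, not *tested*.  The classical LM
variant remains available via `vmpConfig(bpMethod = "lm")` for
comparison.

The effect size converts the fitted linear variance function
$\hat v(a)$ (other covariates at their means) into a change of standard
deviation across the decade centred at the mean age $\bar a$:

$$\Delta\mathrm{SD} = \sqrt{\max(\hat v(\bar a + 5), 0)} -
\sqrt{\max(\hat v(\bar a - 5), 0)}.$$

Negative fitted variances (possible under a linear variance model) are
floored at zero before the square root; a CpG whose fitted variance is
zero across the whole age range is never a candidate.

A CpG is an aVMP candidate when the Bonferroni-corrected stage-2
p-value is at most `alphaBonferroni` (0.05) *and*
$|\Delta\mathrm{SD}|$ reaches `effectThresholdPerDecade` (0.05 beta
units per decade, i.e. "5\% per 10 years").  We read that threshold as
an absolute change on the beta scale because methylation levels are
reported as percentages throughout this literature; a relative reading
(fraction of the fitted SD at the mean age) is available via
`effectRelative = TRUE`.  The Bonferroni denominator is always the
number of CpGs actually scanned in the run, and is logged.

Candidates whose variability *decreases* with age are reported but
excluded from classification and every downstream stage; such CpGs are
rare and behave differently.

```{r scan}
library(vmpscan)
design <- simulationDesign(nSamples = 1000, nCpgs = 500,
                           classMix = c(null = 0.8, constant = 0.2),
                           sdSlopePerDecade = 0.08)
cohort <- simulateCohort(design)
cfg <- vmpConfig()
scan <- scanVariability(cohort$beta, cfg)
scan <- classifyAvmps(scan, cfg)
```

## Classification, entropy, Z-scores

The three aVMP subtypes are encoded as deterministic rules over the scan
output rather than an unsupervised clustering, for reproducibility:
among increase-direction candidates, **gain** requires a hypomethylated
young baseline ($<0.3$) with mean slope above $+0.01$/decade, **loss** a
hypermethylated baseline ($>0.7$) with slope below $-0.01$/decade, and
**constant** an absolute slope within $0.01$/decade.  Any remaining
candidate is assigned the class with the nearest baseline-interval
midpoint ($0.15/0.50/0.85$) — a documented tie rule rather than a
hidden one.  All four thresholds are configuration fields.

Per-sample Shannon entropy summarises global methylome order.  After
residualizing on age, sex and cell fractions and re-centering by the
CpG means, values are clipped to $[\epsilon, 1-\epsilon]$,
$\epsilon = 10^{-6}$, and

$$S_j = \frac{\sum_i b_{ij}\log b_{ij} + (1-b_{ij})\log(1-b_{ij})}
{N \log(1/2)},$$

so $S=1$ at uniform half-methylation and $S\to 0$ for a fully ordered
methylome.  The natural log is used; the normalization cancels the
base.

Z-scores express each individual's deviation from the young reference
(age $<30$ years by default):
$Z_{ij} = (M_{ij} - \bar M_{y,i})/\sigma_{y,i}$ with the young SD on
$n-1$ degrees of freedom.  When fewer than 20 young samples exist the
youngest decile substitutes, with a warning; a zero young SD yields a
missing row with a log entry.

## Regions

aVMRs are called by greedy one-dimensional chaining: consecutive
positioned aVMPs on a chromosome merge while the inter-CpG gap is at
most 1 kb, and chains of at least 3 members become regions.  The
reference method for region calling publishes no reusable parameter
set, so this explicit gap/min-count rule (both configurable) is the
package's documented stand-in; it reproduces clustered fixtures such as
a protocadherin-like arrangement of 26 CpGs in 8 tight clusters exactly.
Regions are annotated with the nearest protein-coding gene by body
distance; exact distance ties resolve toward the nearer transcription
start site, then lexicographically.

## cis/trans expression mapping

Associations between aVMP methylation and expression adjust for sex and
cell composition but *not* age: the age signal in methylation is the
object of study.  Both modes use the Frisch–Waugh reduction
(residualize methylation and expression on the covariates, then test
the pairwise association on $n - p - 1$ degrees of freedom), which is
algebraically identical to the full multiple regression.

* **cis** — candidate genes lie within 500 kb of the CpG (distance to
  the nearest gene-body boundary; a TSS mode is available).  P-values
  are Bonferroni-corrected within each aVMP for its candidate count;
  the single best gene is retained when corrected $p \le 0.05$ (ties
  break by distance, then gene id); Benjamini–Hochberg FDR then runs
  across the retained pairs.
* **trans** — all pairs on different chromosomes or $>5$ Mb apart are
  tested, BH-corrected in one family; genes associated with at most
  $\lfloor 0.05\,n_\mathrm{aVMP} \rfloor$ retained aVMPs are discarded
  (with 6366 aVMPs that threshold is 318).  Surviving hub genes are
  clustered on $1 - r$ (average linkage, cut at $k = 2$) and labelled
  `up`/`down` by the sign of their mean methylation coefficient.

Protein-coding restriction of trans genes is available
(`codingOnlyTrans`) and is applied before testing when enabled.

## Enrichment and replication

Enrichment of a CpG set against interval tracks uses the
set-vs-background odds ratio $(a d)/(b c)$ (Haldane–Anscombe $+0.5$ on
zero cells) on the $\log_2$ scale with a two-sided Fisher exact test;
the background is all scanned CpGs, not the genome.  An optional
permutation p resamples the set uniformly from the background
(one-sided, $+1$ correction); permutations are *not* position- or
methylation-matched by default, matched resampling being exposed as a
flag since no canonical scheme exists.  Multi-segmentation annotation
assigns each CpG the modal label across cell types, ties broken by a
fixed priority order.

Replication re-runs the scan on a validation cohort restricted to the
discovery aVMPs and applies BH-FDR across that set (`replicated` =
FDR $\le 0.05$ *and* sign agreement), reporting the replicated
fraction, the direction-concordance fraction with its exact binomial
p-value, and the Pearson correlation of effects.  The
refined-cell-fraction sensitivity re-scan reuses the same machinery
with an extended covariate set.

## The synthetic generator

`simulateCohort()` draws ages uniformly (18–88 years by default, the
adult range of large blood cohorts), blood-like cell fractions from a
symmetric Dirichlet (optionally with a linear age trend on one
component, renormalized), and CpGs in five classes.  For a CpG of class
$c$ and a sample of age $a$:

$$y = \mu_c(a) + \lambda\,(f_1(a) - \bar f_1) + \varepsilon,\qquad
\varepsilon \sim N\!\big(0, \sigma_c(a)^2\big),$$

with $\sigma_c(a) = \mathrm{sd}_0 + s\,(a - a_\min)/10$ for the three
aVMP classes and constant otherwise, truncated to $[0.001, 0.999]$.
Gain CpGs start hypomethylated ($U[0.05,0.25]$), loss hypermethylated
($U[0.75,0.95]$), constant intermediate ($U[0.35,0.65]$); aDMPs drift
toward intermediate methylation so that a pure mean trend never runs
into a beta bound (a drift into a bound would itself induce variance
changes and contaminate the class).  Defaults: $\mathrm{sd}_0 = 0.04$
beta units (a typical residual SD of variable blood CpGs), mean slope
0.02/decade, SD slope 0.05/decade — the detection threshold itself.

Simulation happens on the beta scale with truncation rather than on the
logit (M-value) scale because the variance test operates on beta
residuals, and behaviour near the bounds is exactly the regime that
matters for intermediate-methylation biology.  An optional
`divergentSubset` mode gives only a random fraction of individuals the
age-growing variance, mimicking the observation that some individuals
diverge while others do not.

Trans-hub structure requires correlated aVMPs: a gene whose expression
sums hundreds of *independent* CpGs would show a per-pair correlation
of order $1/\sqrt{K}$ and no pair would ever be detectable, which
contradicts the hub phenomenon being modelled (many mutually correlated
aVMPs tracking a shared epigenetic-drift state).  Hub members therefore
share a per-sample latent factor whose SD grows linearly with age, on
top of independent baseline noise, and the hub gene's expression loads
on the members' mean methylation.  Hub gene anchors are placed first
and members drawn from CpGs in trans of them (the synthetic genome is
5 chromosomes of 50 Mb, sufficient for all distance logic).
`simulateExpression()` places cis genes (plus decoys) inside the cis
window of their CpG and returns exact truth tables for every planted
link.

What the generator does *not* emulate: probe chemistry and batch
effects, spatial correlation between neighbouring CpGs (beyond an
optional clustered-placement mode for region tests), non-Gaussian
divergence, and realistic gene density.  Passing tests demonstrate the
statistical machinery, not robustness to array artefacts.

## Numerical choices and known limitations

* **Effect attenuation at the beta bounds.**  The realized SD of a
  bounded variable cannot exceed $\sqrt{m(1-m)} \le 0.5$.  A linear
  latent SD growth of 0.05/decade sustained over seven decades implies
  latent SDs near 0.4, which truncation compresses to roughly 0.33 —
  so the realized (and hence estimated) SD change saturates around
  0.04–0.047/decade at intermediate baselines, lower at extreme ones.
  Together with the convexity of the true variance function under a
  linear fit, planted slopes at exactly the 0.05 threshold are
  estimated near 0.036: unbiased detection (the p-value has essentially
  full power at these scales) but conservative effect estimates, and
  essentially no synthetic CpG passes the absolute 0.05/decade filter.
  Real cohorts, whose variance growth is local rather than linear over
  seven decades, are less affected; for synthetic end-to-end runs the
  variance-test significance defines the working aVMP set.
* The stage-2 Wald test is asymptotic on skewed squared residuals; at
  $n = 1000$ its type-I error sits slightly below nominal (0.042 at
  0.05), within the 99\% binomial band used for calibration checks.
* Fitted-variance flooring at zero, BH via `stats::p.adjust`, Fisher
  via `stats::fisher.test`; all tie rules (cis gene selection, class
  assignment, nearest-gene, modal labels) are deterministic and
  documented above.
* Test and calibration problem sizes (5000 null CpGs at $n = 1000$;
  200 planted CpGs at $n = 2000$; hub recovery with 400 links among
  600 CpGs at $n = 1000$) were chosen to give stable Monte-Carlo
  estimates in seconds on one core.

## Interfaces

The package is function-first: `runPipeline()` chains the stages over
files or a simulated design with dependency resolution, deterministic
seeded outputs, an effective-config dump and a log of every threshold
applied — this, rather than a shell wrapper, is the intended entry
point for scripted use.  All tabular outputs are tab-delimited with
full-precision numerics so write/read round-trips are exact.
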