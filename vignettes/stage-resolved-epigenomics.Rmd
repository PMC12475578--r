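---
title: "Stage-resolved epigenomic integration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved epigenomic integration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageomics)
```

## The problem

Lung adenocarcinoma progresses through recognizable stages — adenocarcinoma
in situ (AIS), minimally invasive (MIA) and invasive (IAC) — and its
epigenome changes along the way: CpG methylation shifts, chromatin opens or
closes, and expression follows. `stageomics` implements the analysis chain
that turns per-stage molecular snapshots into stage-resolved features:
which CpGs, peaks and genes change, *when* they first change, and whether
the regions where methylation and accessibility change together carry
diagnostic and prognostic signal.

The pipeline operates on four inputs: per-sample per-CpG
methylated/total read counts (bisulfite sequencing output), a peak x sample
and a gene x sample raw count matrix, a sample sheet with ordered stage
labels (CTL < AIS < MIA < IAC) and survival columns, and per-TF motif-site
interval sets. Because real patient cohorts are not redistributable, the
package ships a synthetic cohort generator with planted, recorded effects;
every downstream stage is validated by recovering that planted truth.

## Differential methylation: the credible difference

For a CpG, reads are pooled across samples within each group and each
group's methylation level gets a Beta posterior with a Jeffreys prior,
`Beta(methylated + 0.5, unmethylated + 0.5)`. The *credible difference* is
the bound of the central 95% credible interval of (case − control) nearest
zero, or 0 when the interval spans zero. It behaves like a
conservatively shrunken effect size: its magnitude never exceeds the raw
pooled level difference, it is antisymmetric under group swap, and it
converges to the raw difference as coverage grows. A CpG is a DMC when
|credible difference| ≥ 0.20.

The distribution of a difference of two Beta variables has no closed form;
the implementation computes its CDF by adaptive quadrature over the
control posterior (`integrate`, relative tolerance 1e-7) and finds the
interval bounds by root-finding to an absolute tolerance of 1e-5
(documented working tolerance 1e-4). The test suite keeps a 10^6-draw
Monte Carlo sampler from the two posteriors as an independent oracle.
Because the credible bound is dominated by the raw difference, sites whose
raw pooled difference is below the threshold are screened out without
quadrature; this is exact, not an approximation.

Two parameters matter:

* `min_credible_dif` (default **0.20**, dimensionless methylation-level
  difference) — the DMC calling threshold.
* `cred_level` (default **0.95**) — the central credible level. The prior
  and level are package defaults; pooling reads within groups (rather
  than a per-sample hierarchical model) keeps the statistic a function of
  pooled counts only.

DMCs merge into DMRs per chromosome and per direction: maximal runs with
consecutive start-coordinate gaps ≤ **200 bp** and ≥ **3** member DMCs; a
DMR spans `[first member, last member + 1)`. Hyper and hypo runs never
merge, and stage categories are merged separately (an interleaved
hyper-AIS/hyper-MIA run yields two DMRs, not one).

## Differential counts: one NB engine for peaks and genes

Peak and gene counts share a negative-binomial Wald test:

1. **Normalization** — median-of-ratios size factors over features nonzero
   in every sample, rescaled to geometric mean 1 (total-count fallback
   with a warning when no such feature exists).
2. **Dispersion** — per-feature method of moments from pooled within-group
   variance, `alpha = max((s² − mu)/mu², 0)`, averaged 50/50 with a
   log-linear mean–dispersion trend fitted across features; floor 1e-8.
   The arithmetic blend matters: blending on the log scale drags the many
   floored (Poisson-looking) features to effectively zero dispersion and
   inflates type-I error.
3. **Test** — log2 fold change of normalized group means with pseudocount
   0.5; delta-method variance from `Var(K/s) = mu/s + alpha mu²`; the Wald
   statistic is referred to a t distribution with **2 × (n₁ + n₂ − 2)**
   degrees of freedom. The doubling credits the information the trend
   contributes through the 50/50 shrinkage (moderated-t reasoning); with a
   plain normal reference the test is visibly anticonservative at n = 5
   per group, and with the undoubled residual df slightly conservative.
   Under the calibration simulation (2,000 features, n = 5 vs 5, mean 100,
   dispersion 0.1) empirical type-I at nominal 0.05 lands at ~0.043–0.055
   across seeds.

Calling thresholds are strict inequalities: differentially accessible
regions (DARs) need |log2FC| > 2 and raw p < 0.001; differentially
expressed genes (DEGs) need |log2FC| > 0.58 and Benjamini–Hochberg
adjusted p < 0.05. Raw p for DARs and adjusted p for DEGs mirrors the two
thresholds' provenance; BH is the package's reading of "adjusted p-value".

## Earliest-onset stage categories

Each feature is tested at AIS, MIA and IAC against control, giving a
stage-result vector over {hyper, hypo, ns}. The feature is assigned to the
**earliest** stage with a significant call, keeping the direction observed
there; later calls are not considered, even if they flip direction. This
yields six mutually exclusive categories ({hyper, hypo} × {AIS, MIA, IAC})
that provably partition the ever-significant features; never-significant
features are "unassigned". The rule is applied literally: a feature with a
sub-threshold same-direction change before its first significant stage is
assigned to the significant stage.

## Integration and the panel

* **Peak-level coupling** — Kendall tau-b (tie-corrected) between
  normalized accessibility (`log2(count/size factor + 1)`) and the
  methylation level of the peak interval, across samples; classes
  positive/negative at two-sided p < 0.05, else "none". The 0.05 class
  threshold is a package default.
* **Within-sample coupling** — repeated subsampling of peaks (defaults
  2,000 peaks, 100 repeats, seeded) and Kendall tau across peaks within
  one sample, reported mean ± SD.
* **The panel** — srDARs overlapping srDMRs by ≥ 1 base. Each overlapping
  pair carries three per-sample metrics: srDMR methylation, srDAR
  methylation (both read-weighted region levels: pooled methylated /
  pooled total, never a mean of per-CpG ratios) and srDAR accessibility.
  One srDAR overlapping two srDMRs yields two records; a per-srDAR
  deduplicated view backs the classifier. Per-sample Pearson correlations
  among the three metrics quantify coupling region-wise.
* **Co-expression** — Pearson r for each TF–gene pair across samples;
  co-expressed at p < 0.05, signed by r.

## TF enrichment and co-localization

Enrichment is a region-containment hypergeometric test: the number of
target regions containing ≥ 1 motif site, drawn from a background region
universe (upper tail, BH across the table). This deliberately stands in
for motif-discovery enrichment tools; it asks the same question at region
resolution. Epi TFs are those significantly enriched (q < 0.05, fold > 1)
in at least one srDMR set *and* one srDAR set. At desk scale the
per-category region counts (~13 regions) give the hypergeometric little
to work with, so the worked example pools the six categories into one
srDMR and one srDAR target set; both shapes are supported.

Co-localization between two TFs is the Jaccard index of the region sets
each occupies, computed inside srDARs and genome-wide; their elementwise
ratio is the ratio change. "Proportion of shared sites" is read at region
level because the co-localization heatmap is symmetric, which an
asymmetric conditional proportion could not produce. Average-linkage
hierarchical clustering on 1 − proportion, cut at k (default 6, the
figure's group count; linkage configurable), groups TFs into co-binding
clusters; TFs are sorted lexicographically first so the partition is
input-order invariant.

Motif sites can be filtered by evidence tracks (e.g. ChIP peaks and a
histone mark): a site survives only if it overlaps every evidence list —
an intersection filter, monotone by construction.

## Classification and survival

The classifier features are the panel's **srDAR methylation** levels (the
metric most correlated with the other two). A random forest (500 trees)
is trained on a stratified 70/30 split with a fixed seed; performance is
ROC/AUC, with AUC computed as the Mann–Whitney probability (ties
half-credited) and the multi-class "average AUC" the unweighted macro
mean of one-vs-rest AUCs. Absent metric values are imputed at the
uninformative midpoint 0.5 before training. Split ratio, tree count and
seed are exposed; none were reported for the original analysis.

Survival stratification median-splits samples by mean panel methylation
(quantile configurable), compares the groups with the log-rank test
(1 df chi-square from observed-vs-expected event tabulation, via the
survival package with a hand tabulation as test oracle) and emits
Kaplan–Meier step curves. With no events the statistic is flagged
undefined rather than 0.

## The synthetic cohort

The generator emulates the study's data shapes at desk scale. Its genome
is one chromosome of regularly spaced loci; each locus carries five CpGs
(50 bp apart) and one 300 bp peak covering them, so methylation regions
and peaks overlap by construction.

* **Cohort** — default 10 samples per stage (the study had 38/33/37/43;
  10 keeps the full test suite and examples inside desk runtimes).
* **Methylation** — totals Poisson with mean **25.8** (the study's mean
  CpG coverage), floored at 1 read; methylated counts beta-binomial with
  precision **30** (moderate biological overdispersion; no per-group
  variance estimates were available to fit this, so it is a documented
  default, not a fitted value) around baseline **0.5**.
* **Counts** — negative binomial, baseline mean **100** with lognormal
  per-feature spread (sd 0.5), dispersion **0.1**, lognormal size factors
  (sd 0.15, geometric mean exactly 1).
* **Planted effects** — each effect switches on at its onset stage and
  persists through IAC (matching the earliest-onset classification; no
  reversals are simulated — reversals are exercised as unit inputs to the
  assignment rule). Default sizes are twice the calling thresholds:
  methylation delta ±0.40, peak |log2FC| 4, gene |log2FC| 1.16. Panel
  loci carry a methylation effect and an opposite-direction accessibility
  effect (hypomethylated-and-opening or the reverse), emulating negative
  coupling. Means pushed outside [0, 1] are clipped with a recorded
  warning.
* **TF sites** — TFs occupy loci so that within-cluster region Jaccard
  hits a target (default 0.8) inside accessibility-effect loci and a
  lower uniform value (default 0.1) across clusters and genome-wide,
  using an exact shared-fraction construction (`shared/total =
  2J/(1+J)`). Panel loci sit at the head of the in-DAR pool and shared
  sets are allocated in tiers, so shared occupancy — the epi-TF signal —
  concentrates where both methylation and accessibility change.
  Per-locus site positions are drawn once and reused by every TF
  occupying the locus, so site-level sharing mirrors locus-level sharing.
* **Survival** — event times exponential with hazard
  `baseline · exp(−link · mean panel methylation)` (positive link ⇒ low
  methylation ⇒ high hazard), censoring uniform on [0, 60] months.
* **Determinism** — each modality draws from its own stream seeded from
  the master seed by a fixed offset, so enlarging one modality never
  perturbs another; identical configs give bit-identical cohorts.

What the generator does **not** emulate: real genome annotation (CpG
islands and TSSs are abstract loci), read-level errors and mapping bias,
batch effects, covariate structure (age, sex, smoking), and effect-size
heterogeneity beyond the planted values. Passing recovery tests therefore
demonstrates the *pipeline logic* — calling, onset assignment, panel
construction, classification — under the stated noise models, not
performance on real cohorts.

## Problem sizes in tests and the acceptance script

Unit tests run reduced instances (hundreds of features, tens of samples).
The calibration and recovery experiments use the sizes stated with each
check: the null DMC cohort is 5,000 CpGs at n = 10/group and coverage
25.8; NB calibration is 2,000 features at n = 5 vs 5. The stage-recovery
cohort runs at **20 samples per stage**: a Wald power computation
(`se_log2 = sqrt(2(1/mu + alpha)/n)/ln2`, so ~0.15 at n = 20 against a
BH-adjusted cutoff near |t| ≈ 4) puts per-stage detection power above 99%
at the planted effect sizes, which makes the experiment measure the
earliest-onset assignment logic rather than borderline detection power —
at n = 10 the gene arm sits at ~85–94% purely from detection noise.

## Known limitations

* The credible difference uses pooled counts; sample-level overdispersion
  widens the *sampling* spread of the pooled difference but not the
  posterior, so the effective specificity margin depends on the
  overdispersion level. The null-rate check pins this empirically.
* The NB engine supports two-group comparisons only (no covariates, no
  GLM designs).
* Enrichment ignores GC/background matching; it is a region-containment
  test, not a motif-model test.
* Survival is a median-split log-rank comparison; no Cox modeling.
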