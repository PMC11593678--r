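---
title: "FolrSig: methods and design notes"
author: "FolrSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FolrSig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FolrSig)
```

# The scientific problem

Folate receptor alpha (FRα, encoded by *FOLR1*) is a membrane folate
transporter overexpressed in a large fraction of ovarian carcinomas and the
target of the antibody–drug conjugate mirvetuximab soravtansine. Assessing
FRα status from transcriptomic data requires pooling many public expression
cohorts profiled on heterogeneous platforms (Affymetrix, Agilent, spotted
cDNA arrays, RNA-seq), asking how *FOLR1* expression relates to
clinicopathological features, and — since *FOLR1* expression by itself is not
prognostic — deriving an mRNA signature of the *FOLR1*-high state whose
prognostic value can be tested in independent samples.

FolrSig implements that analysis as a reusable pipeline:

1. **Harmonization** — per-cohort quantile normalization, most-variant-probe
   collapse to genes, strict gene intersection, and per-dataset
   standardization against the primary-tumor reference.
2. **Dichotomization** — the target gene is split high/low at its median over
   the pooled tumor series.
3. **Association battery** — odds ratios with Woolf CIs and Fisher exact
   p-values, Welch t-tests, one-way ANOVA, Pearson correlations.
4. **Differential expression** — empirical-Bayes moderated t with BH FDR and
   the gates p < 0.05, q < 0.01, |FC| > 1.25×.
5. **Signature** — per-gene median centroid of the high class on the learning
   set; independent samples classified by the sign of their Pearson
   correlation with the centroid.
6. **Survival** — Kaplan–Meier/Greenwood, log-rank, Cox regression (Efron
   ties, Wald tests), time-stratified hazard ratios and subtype interactions.

Because the real pooled compendium cannot be redistributed, the package
ships a synthetic-data generator that reproduces the statistical *structure*
the analysis assumes, so every stage is testable end to end.

# The models, stage by stage

## Harmonization

Quantile normalization maps every sample onto the common reference
distribution given by the row means of the column-sorted matrix; within-column
ranks are preserved and ties receive the mean of the reference values their
ranks span. It is idempotent and equivariant under column permutation — both
properties are tested.

Probe collapse keeps, per gene, the probe with the largest sample variance
(n−1 denominator) in that cohort: the most variant probe carries the most
signal on that platform, and per-cohort selection respects platform
differences.

Standardization is the step that makes cohorts comparable: within each
cohort, every gene is centered and scaled by the mean and SD **of that
cohort's primary-tumor reference samples only**. Normal-tissue samples are
transformed with the same parameters, so "normal vs tumor" contrasts remain
meaningful in standardized units. The pooled object therefore satisfies, for
every cohort and gene, reference mean 0 and SD 1 (tolerance 1e−9, enforced
by test). Genes with zero reference SD in any cohort cannot be scaled and
are dropped with a message. Missing values are handled before pooling: a
gene with any NA in a cohort is excluded from that cohort, and the pooled
gene universe is the strict intersection.

What is deliberately **not** implemented: probe-level RMA for raw Affymetrix
arrays. RMA needs CEL-level data; cohorts tagged `raw_array` must be supplied
at summarized probe scale and are then quantile-normalized like processed
arrays. RNA-seq input on a linear TPM-like scale is transformed as
`log2(x + 1)`; the pseudo-count is configurable.

## Median split

The cutoff is the median over the pooled *tumor reference* series; a sample
is "high" only when strictly above it, so ties go to "low". This makes the
split deterministic and keeps the two groups within one tied sample of each
other. An all-equal expression vector cannot be split and is an error.

## Moderated t and the variance prior

The empirical-Bayes model places a scaled inverse chi-square prior with
parameters (d0, s0²) on the gene-wise residual variances. The prior is fitted
by the method of moments on z = log s²: under the model z is, up to a
constant, the log of a scaled F variate, so

  E[z] = log s0² + ψ(df/2) − log(df/2) − ψ(d0/2) + log(d0/2)
  Var[z] = ψ′(df/2) + ψ′(d0/2)

with ψ, ψ′ the digamma/trigamma functions. d0 solves the trigamma equation by
Newton iteration with a bisection fallback on [1e−6, 1e6] (tolerance 1e−8);
when the observed Var[z] does not exceed ψ′(df/2) the prior is degenerate and
d0 = ∞. Per gene, the posterior variance is the df-weighted blend
(d0·s0² + df·s²)/(d0 + df) and the moderated t is referred to a t
distribution on d0 + df degrees of freedom (capped at 1e6 when d0 = ∞). Two
limits anchor the implementation: d0 = 0 reproduces the classical pooled
two-sample t exactly, and d0 = ∞ uses s0² everywhere. On common inputs the
fitted prior and statistics agree with the independent limma implementation
to machine precision; that agreement is a cross-check in the test suite, not
the implementation.

Fold change is computed as the difference of class means on the
*standardized* log2 scale — the only scale on which the pooled data exist —
and the |1.25×| linear gate maps to |Δ| > log2 1.25 ≈ 0.322. A gene is
selected only when all three gates hold (p < 0.05, BH q < 0.01, FC gate).
The learning/validation split is by cohort; the largest cohort is the
default learning set, mirroring the use of the biggest series (TCGA-sized)
for supervised analysis.

## The signature classifier

The "high-like" model is a nearest-centroid classifier with a single
centroid: the per-gene **median** over high-class learning samples of the
selected genes, in standardized units. A sample is called high-like when its
Pearson correlation with the centroid is positive and low-like otherwise;
r = 0 exactly is called low-like (a deterministic tie-break for a
measure-zero event). Correlation makes the call invariant to any positive
affine rescaling of the sample vector, which is the property that lets the
model transfer across independently standardized cohorts. Genes are matched
by id, never by position; validation samples may be missing up to 10% of the
model genes (correlation on the intersection), beyond which classification
refuses to proceed. A centroid built only from high samples is the default; a
`method = "difference"` variant (high median minus low median) exists for
sensitivity analysis.

## Survival

Kaplan–Meier estimation uses the product-limit estimator with Greenwood
variance (log-scale CIs); the median is the earliest time with S(t) ≤ 0.5;
five-year rates are read at t = 60 months. Group comparison is the standard
log-rank O−E statistic with hypergeometric variance. Cox models maximize the
Efron-tie partial likelihood, report per-coefficient Wald tests, and support
interaction terms (expression class × molecular subtype). Time-stratified
hazard ratios use episode-splitting at 6 and 12 months with an
interval × covariate interaction and no main effect, giving one hazard ratio
per window; an interval without events yields an undefined (NA) estimate.
The multivariate screen enters every candidate in a univariate model and
refits jointly those with Wald p < 0.05. All of this is computed through the
survival package; the package's own contribution is the analysis surface and
its validation against hand-computed oracles on small worked examples.

# The synthetic-data generator

The generator is first-class, tested code. It emulates the features of the
pooled compendium the analysis relies on:

- **Gene-wise Gaussian expression on the log2 scale**, with per-gene
  variances drawn from a scaled inverse chi-square with d0 = 4, s0² = 0.25 —
  so the variance prior the moderated t assumes is a well-specified
  estimation target and its recovery can be measured.
- **A latent anchor**: each tumor draws a standard-normal anchor value; the
  true anchor class is its sign (the population median of the latent is 0),
  and the observed anchor gene is latent + N(0, `anchorNoiseSd`). Defining
  truth pre-noise makes median-split recovery measurable.
- **A planted module** of `nModuleGenes` genes (default 187, the size of the
  signature in the motivating study) whose means shift by `moduleLog2FC` in
  anchor-high samples, half up and half down.
- **Covariates at stated odds ratios**: each binary covariate keeps its
  anchor-low prevalence at a realistic baseline (serous 0.89, advanced stage
  0.85, high grade 0.71, platinum-sensitive 0.88) and shifts its log-odds by
  log(OR) in anchor-high samples; the default ORs are 2.45, 1.71, 1.45 and
  1.03 — the association strengths the pipeline is expected to detect.
- **Proportional-hazards survival**: exponential event times with hazard
  `baselineHazard × signatureHr^{module-high}` (defaults 0.02/month and
  0.71), with independent exponential censoring whose rate is solved
  numerically so the expected censored fraction equals `censorRate`
  (default 0.3). Progression-free survival uses a 1.5× baseline hazard.
  Independent exponential censoring is the simplest mechanism satisfying the
  non-informative-censoring assumption of KM and Cox.
- **Cohort effects applied after the biology**: a per-cohort additive shift
  ~ N(0, `cohortShiftSd`) and multiplicative scale ~ U(`cohortScaleRange`),
  which per-dataset standardization must (and does) remove exactly.
- **Normal tissue**: `nNormal` samples (default 30, the size of the normal
  arm in the motivating compendium) with the anchor shifted down by
  `normalOffset` log2 units, no module shift and no survival. The published
  analysis reports only an odds ratio for the tumor/normal median split, not
  an effect size, so the offset is an exposed parameter rather than a fixed
  constant. Normals are appended to the *first* cohort rather than forming a
  cohort of their own: standardization requires every cohort to contain
  primary-tumor reference samples, and in the real compendium normals sit
  inside datasets that also contain tumors.

Default study size is 4 cohorts × 150 tumors. Randomness comes from a single
master seed; each stage (gene parameters, biology, covariates, survival,
cohort effects) derives its own substream deterministically from it, so
outputs are byte-identical under a fixed seed and stages stay reproducible
if upstream stages are reconfigured.

What the generator does **not** emulate — and therefore what passing tests do
not show about real data: probe-level raw intensities, gene–gene correlation
beyond the planted module (real co-expression is pervasive), non-Gaussian
heavy tails, batch effects that interact with biology rather than acting
additively per cohort, informative censoring, and covariates that confound
the expression–survival relation. Results on simulated data validate the
*machinery*, not the biology.

# Numerical choices and degenerate inputs

- SD estimator everywhere: sample SD with n−1 denominator.
- Quantile normalization with fewer than two columns returns its input with
  a warning (nothing to equalize); missing values are an error at that stage
  because NA policy is handled at pooling.
- Odds ratios with a zero cell use the Haldane–Anscombe +0.5 correction for
  the point estimate and CI (flagged in the result); the Fisher exact p is
  computed on the uncorrected table. The Woolf log-method CI is reported;
  exact conditional CIs are slightly wider, which is consistent with the
  intervals printed in the motivating study — point estimates, not CI
  methodology, are the reproducibility surface.
- Odds-ratio orientation: odds of the clinical feature in the high class
  versus the low class. Multi-level variables are collapsed
  level-vs-rest for per-level ORs; the overall p comes from the full R × 2
  Fisher test with a chi-square fallback for large tables.
- Cox fits error on collinear covariates (NA coefficients) and on monotone
  likelihood (|coef| > 15 is treated as separation); convergence is capped
  at 100 iterations.
- Zero-variance genes get t = 0, p = 1 and a flag; they can never pass the
  gates.

# Problem sizes used by the tests

The suite validates at deliberately modest scales chosen to keep each
property measurable: planted-recovery runs use 2 cohorts × 150 tumors with
2000 genes and a 150-gene module; FDR and concordance are asserted as means
over 10 replicate studies because the BH gate controls the false-discovery
*rate in expectation* — a single draw of V/R scatters around 1% with Poisson
noise and is not the quantity the procedure guarantees. Covariate odds-ratio
convergence is checked at 2200 tumors (within 3 SE of the log-OR); Cox
recovery of HR = 0.71 at n = 1500 (point estimate within 10%) and CI
coverage over 200 replicates at n = 500 (≥ 93%). Fisher exact p-values are
compared against full hypergeometric enumeration for every 2×2 table with
margins ≤ 30 (163,680 tables).

# Known limitations

- RMA is out of scope; raw-array cohorts must arrive summarized.
- The signature score is the correlation sign only; no probabilistic
  calibration or single-sample enrichment scoring.
- The association battery drops NA per variable (complete-case per row of
  the table), matching the per-variable N convention of clinical tables;
  no imputation.
- Episode-splitting is one documented choice of time-stratified analysis,
  not the only one.
- Ontology enrichment of the selected genes and derivation of molecular
  subtype centroids are consumed as external inputs, never computed here.
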