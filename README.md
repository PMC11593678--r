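# FolrSig

Pooled transcriptomic analysis of *FOLR1* (folate receptor alpha) expression
in ovarian carcinoma, and derivation of a prognostic "FOLR1-high-like"
metagene signature.

## The problem

FRα, encoded by *FOLR1*, is the target of the antibody–drug conjugate
mirvetuximab soravtansine in platinum-resistant ovarian cancer, but FRα
status is hard to assess consistently. Pooling public expression cohorts
(microarray and RNA-seq) makes it possible to (i) relate *FOLR1* mRNA levels
to clinicopathological features at scale and (ii) derive an mRNA signature of
the *FOLR1*-high state — which, unlike *FOLR1* expression itself, carries
prognostic information. FolrSig packages that analysis for anyone working
with multi-cohort expression compendia and a target gene: computational
oncologists reproducing or extending the FRα work, and methodologists who
need a tested reference implementation of the pipeline.

## The method

For cohorts \(c = 1..K\) with gene × sample matrices on the log2 scale:

1. **Harmonization.** Quantile normalization within each cohort; per-gene
   probe collapse keeping the most variant probe; per-dataset
   standardization: for gene *g*, sample *j* in cohort *c*,
   `z[g,j] = (x[g,j] − mean_ref(g,c)) / sd_ref(g,c)`, where the reference is
   the cohort's primary tumors; genes restricted to the cross-cohort
   intersection.
2. **Median split.** Sample *j* is *FOLR1*-high iff
   `z[FOLR1, j] > median` over the pooled tumor series (ties → low).
3. **Association battery.** For each clinical feature, odds ratio
   `OR = (a·d)/(b·c)` of the feature in high vs low with the Woolf 95% CI
   `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))` and two-sided Fisher exact p;
   Welch t for continuous variables; one-way ANOVA for k > 2 groups.
4. **Moderated t.** Gene-wise residual variances are shrunk toward an
   empirical-Bayes scaled-inverse-χ² prior (d0, s0²) fitted by method of
   moments on log s²; `t_g = Δmean_g / √(s̃²_g (1/n1 + 1/n2))` on d0 + df
   degrees of freedom, with Benjamini–Hochberg q-values. A gene enters the
   signature when p < 0.05, q < 0.01 and |FC| > 1.25× (|Δ| > log2 1.25 on
   the standardized log2 scale).
5. **Signature.** Centroid = per-gene median of the selected genes over
   *FOLR1*-high learning samples; any sample is called *high-like* iff its
   Pearson correlation with the centroid is positive.
6. **Survival.** Kaplan–Meier with Greenwood variance, log-rank tests, Cox
   proportional-hazards models (Efron ties, Wald tests), time-stratified
   hazard ratios (episode splitting at 6/12 months) and an expression ×
   subtype interaction model; univariate screen at p < 0.05 feeding a
   multivariate model.

A synthetic multi-cohort generator (`simulateCohorts()`) with planted module
genes, covariate odds ratios and proportional-hazards survival makes every
stage testable without downloading data; see the methods vignette
(`vignettes/folrsig-methods.Rmd`) for the model and its limits.

## Worked example

Reproducing a published contingency statistic from its printed counts
(serous histology in *FOLR1*-high vs -low tumors):

```r
library(FolrSig)
oddsRatio2x2(480, 24, 449, 55)
#> ContingencyResult: OR = 2.45 [1.491-4.025], p = 0.00038 (fisher)
```

Running the whole pipeline on a simulated three-cohort study (360 tumors,
1000 genes, a planted 100-gene module, planted hazard ratio 0.71):

```r
res <- runPipeline(list(
  simulate = list(nCohorts = 3, samplesPerCohort = 120,
                  nGenes = 1000, nModuleGenes = 100, seed = 5),
  outputDir = "run1"))

res$de
#> DEResult: 1000 genes (61 high vs 59 low); 99 selected
head(selectedGenes(res$de), 3)
#>     gene    log2fc            p            q direction
#> 1 G00715  1.661765 4.470119e-24 4.470119e-21        up
#> 2 G00486 -1.627627 5.734877e-23 2.602156e-20      down
#> 3 G00639  1.623408 7.806467e-23 2.602156e-20        up
res$model
#> SignatureModel: 99 genes, learning set 'C01'
head(res$calls, 3)
#>   sample_id         r     label flagged
#> 1     T0121 0.6437115 high_like   FALSE
#> 2     T0122 0.7085596 high_like   FALSE
#> 3     T0123 0.7700403 high_like   FALSE
res$survival$signature$cox$table
#>               term      coef       hr   ci_low ci_high     wald_p
#> 1 sigClasslow_like 0.3494559 1.418296 1.033086 1.94714 0.03067402
```

Reading the output: the learning cohort (C01, 120 tumors split 61/59 at the
*FOLR1* median) yields 99 signature genes, 97% of the planted module; the
centroid classifier labels the two held-out cohorts with 100% concordance to
the simulated truth; and the Cox model on the held-out calls estimates a
hazard ratio of 1.42 for *low-like* vs *high-like* — i.e. 1/1.42 ≈ 0.71 for
the high-like class, recovering the planted protective effect (log-rank
p = 0.03 at this sample size).

Stage artifacts (`pooled.tsv`, `de_results.tsv`, `signature_model.json`,
`signature_calls.tsv`, `associations.tsv`, `survival_cox.tsv`,
`manifest.json`) are written to `outputDir`; a thin command-line wrapper
with `simulate` / `harmonize` / `associate` / `de` / `signature` /
`classify` / `survive` / `run-all` subcommands is at
`inst/scripts/folrsig.R`.

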