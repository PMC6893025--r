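# popdiverge

Population-divergence analysis of brain lipidome and metabolome peak
tables.

Untargeted LC-MS lipidomics and GC-MS metabolomics of postmortem prefrontal
cortex yield compound × sample intensity matrices in which the signal of
interest — systematic abundance differences among human populations — is
entangled with donor age (the dominant factor), acquisition run order,
extraction batch, postmortem interval (PMI) and tissue quality (RIN).
`popdiverge` is an R package for analysts working with such peak tables. It
implements:

* **Peak-table QC**: retention-time/mass windows, detection floors,
  contaminant series removal, SVR-based run-order drift exclusion,
  PMI-correlation and RIN filters, upper-quartile and quantile
  normalization with per-compound batch regression.
* **Variance partitioning**: per-compound sequential ANOVA aggregated over
  the table (age as a natural cubic spline), reporting the fraction of
  total variance per covariate.
* **Population specificity**: equal-n subsampled one-vs-rest Welch tests
  with Benjamini–Hochberg correction; for focal population *f* and compound
  *c*, the statistic is Welch's *t* between samples of *f* and the pooled
  other populations, and a compound is *f*-specific when BH-adjusted
  *p* < 0.05.
* **Classification**: one-vs-rest lasso logistic regression (inverse
  regularization C, AUC by the rank statistic) and stability selection —
  ranking compounds by how often the lasso selects them across resampled
  train/test splits.
* **Age-resolved divergence**: age-unbiased compound selection and the
  Spearman correlation distance `1 − ρ` between population mean abundance
  vectors, profiled across six age groups (split at 1/5/15/25/45 y).
* **Cross-dataset validation**: anchor-based retention-time alignment,
  5 ppm / 6 s one-to-one feature matching, fold-change consistency, and
  external classification of an independent cohort.
* **Annotation & enrichment**: adduct-aware neutral-mass lookup (5 ppm) and
  upper-tail hypergeometric pathway enrichment on compound-linked genes.
* **A synthetic-data generator** that emulates the statistical structure of
  a 303-donor, three-population (HC/WE/AA) brain cohort — dominant age
  effect, an HC-specific shift that is absent in infancy and peaks in young
  adulthood, run-order drift, batch, PMI and detection-floor artifacts —
  with ground-truth labels for parameter-recovery testing.

## Worked example

```r
library(popdiverge)

cfg    <- generator_config(seed = 1)          # default study conditions
cohort <- generate_cohort(cfg)                # 303 samples, 146/97/60 HC/WE/AA
dat    <- generate_intensities(cohort, cfg)   # two lipid modes + metabolites

fcfg <- lipid_filter_config(drift_exclude_pos = 69, drift_exclude_neg = 51)
pos  <- preprocess_lipids(dat$lipids_pos, fcfg)
neg  <- preprocess_lipids(dat$lipids_neg, fcfg)
lip  <- intensity_matrix(rbind(pos$matrix$values, neg$matrix$values),
                         rbind(pos$matrix$features, neg$matrix$features),
                         pos$matrix$samples, scale = "log2")

variance_explained(lip)[1:2, ]
#>       factor   fraction
#> 1        age 0.27798...   # age dominates, ~28% of lipid variance
#> 2 population 0.01688...

st    <- assign_dataset(lip$samples)
adult <- im_subset(lip, samples = st$dataset == "DS:5-71")
subsampled_specificity(adult, subsampling_design(n_per_pop = 25,
                                                 n_iter = 100, seed = 2))
#> <subsampling_result> 100 iterations, n_per_pop = 25
#>   median counts: HC=51, WE=1.5, AA=0
```

The median of 51 HC-specific lipids against ~0 for WE and AA reproduces the
planted structure: only the HC population carries a shifted compound set,
and equal-n subsampling makes the three counts directly comparable. The
same data classified with `ovr_auc_curve(adult, "HC", ...)` at C = 1000
gives mean AUC ≈ 0.88 for HC versus ≈ 0.60/0.58 for WE/AA, and
`stability_selection()` places ≈ 86% of the planted compounds in its
top-200 ranking.

A full orchestrated run (simulate → preprocess → variance → specificity →
classify → age dynamics), with per-stage seeds and an output manifest:

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

or from a shell: `Rscript inst/cli/popdiverge.R run --out out/ --seed 1`.

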