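---
title: "Methods: population divergence analysis of brain lipidome and metabolome peak tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population divergence analysis of brain lipidome and metabolome peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Untargeted LC-MS lipidomics and GC-MS metabolomics of postmortem brain
tissue produce peak tables — compounds-by-samples intensity matrices — whose
variation mixes the biology of interest (here: differences among human
populations) with strong technical and demographic confounders: donor age,
acquisition run order, extraction batch, postmortem interval (PMI) and
tissue quality (RIN). `popdiverge` implements a complete analysis chain for
asking whether one population's prefrontal-cortex lipidome and metabolome
diverge from others, how that divergence depends on age, and whether it
replicates in an independent dataset. The motivating setting is a cohort of
303 donors from three populations (Han Chinese, HC; Western European, WE;
African American, AA) with ages spanning birth to 71 years.

Because such cohorts are rarely publicly deposited, the package carries a
first-class synthetic-data generator that emulates the statistical structure
of this setting with known ground truth, so every stage can be validated by
parameter recovery rather than by eyeballing.

# Quality control and confounder removal

Lipid peaks pass, in order:

1. a retention-time window (closed interval, default 1.5–18 min) and an
   upper m/z cutoff (1400 Da, which covers the common brain lipid classes
   while excluding four-chain species such as cardiolipins);
2. a detection filter: intensity strictly greater than the floor (200
   counts) in at least 75% of samples (boundary inclusive). Sub-floor values
   on surviving peaks are set to the floor, so downstream statistics never
   see values the instrument could not quantify;
3. a contaminant rule: one m/z (within 5 ppm) recurring at four or more
   retention times separated by more than 0.5 min is treated as a chemical
   background series and all its peaks are dropped. The counts are
   configurable because "numerous retention times" is a judgment call;
4. run-order drift exclusion: per peak, the three highest-intensity samples
   are set aside and a Gaussian-kernel support vector regression
   (C = 1e5, epsilon = 0.1, gamma = 1e-4) predicts intensity from run order;
   the in-sample coefficient of determination scores how much of the peak's
   variation tracks the acquisition sequence. The top-scoring peaks per
   ionization mode are excluded. The score is deliberately in-sample: the
   aim is to describe dependence in the data at hand, not to generalize.

Metabolite tables instead drop compounds detected in under half the samples,
fill remaining missing values with the matrix minimum (GC-MS missingness is
censoring at the detection limit, so the minimum is the least-wrong fill),
log2-transform, remove the extraction batch by per-compound linear
regression (residuals plus the compound mean), and quantile-normalize with
ties averaged.

Both kinds of table then pass a PMI filter: Spearman correlation between
compound abundance and PMI over the older (age ≥ 5) samples with non-missing
PMI, dropping compounds with two-sided p below the threshold (0.01 by
default; 0.1 as a sensitivity analysis). Only older samples are used because
the dominant age effect would otherwise masquerade as a PMI association.
Two-sided p-values are used; the thresholds are p-value-driven and the
correlation magnitude is recorded alongside.

Lipid intensities are upper-quartile normalized (each sample scaled so its
75th percentile equals the grand mean 75th percentile) and log2-transformed.
Normalization is a per-sample rescaling, so within-sample rank order is
untouched.

# Sample partitions

Two partitions of the cohort recur throughout: the infant/older split at 5
years (`DS:0-4` vs `DS:5-71`) and six age groups `A1`–`A6` split at 1, 5,
15, 25 and 45 years. All boundaries are half-open with the upper bound
exclusive: age 5.0 belongs to `DS:5-71` and age 45.0 to `A6`. This is the
only convention under which the partitions are exhaustive and disjoint and
the default cohort's group sizes (24/50/41/56/56/76; 74 + 229 = 303) are
reproduced exactly.

# Variance partitioning

`variance_explained()` runs a per-compound sequential (type-I) ANOVA in a
stated factor order — age, population, sex, RIN, PMI by default — and
aggregates as the ratio of summed factor sums-of-squares to summed total
sums-of-squares. Age enters as a natural cubic spline with 3 degrees of
freedom: brain lipid trajectories are strongly curved in infancy and a
linear age term would understate the age share (a `"linear"` switch exists).
Sequential sums of squares are order-dependent in unbalanced designs, so the
order is recorded in the output. Samples missing any included covariate are
excluded; with the default generator's ~30% missing PMI this costs about a
third of the cohort, which is acceptable for an aggregate descriptive
statistic.

# Population specificity

The core statistic is deliberately simple: for a focal population, a Welch
(unequal-variance) two-sided t-test per compound against the two other
populations pooled, with Benjamini–Hochberg correction across compounds, and
adjusted p < 0.05 declared specific. Welch is chosen over the pooled-variance
test because the pooled "rest" group is a mixture of two populations and its
variance is inflated by construction; a config switch restores the pooled
test. Both directions of difference count, and the sign of the focal-minus-
rest mean difference is recorded.

Because the three populations differ in size, raw counts of significant
compounds are not comparable across focal populations. The pipeline
therefore subsamples an equal number per population (25 in the older
dataset, 13 in the infant dataset) without replacement, re-tests, applies BH
within each iteration, and repeats 100 times, summarizing the per-population
distribution of significant-compound counts by its median. Equal-n
subsampling makes the three focal tests exchangeable under the null.

# Classification and stability selection

One-vs-rest lasso logistic regression asks whether populations are
separable at all. Each repetition draws 31 samples per population, splits
two-thirds/one-third into train and test stratified by population (a
largest-remainder allocation hits 62/31 exactly), standardizes both sets
with train-derived means and standard deviations (no leakage), fits at each
inverse-regularization value C in a grid, and scores the held-out ROC AUC
via the rank (Mann–Whitney) statistic with midrank ties. C is the inverse
regularization strength; internally the lasso is solved along a log-spaced
warm-start path from the all-zero solution down to the target penalty
(`lambda = 1/(n C)` in glmnet's parameterization), which is the canonical
way to reach an accurate solution at weak regularization. Results are
reported at C = 1000; the AUC curve across the grid shows the choice is not
load-bearing.

Stability selection ranks compounds by how often the lasso assigns them a
nonzero coefficient (|beta| > 1e-8, configurable) over repeated
draw/split/fit cycles at C = 1000. The production default is 10,000
iterations; tests and the acceptance checks run 200, which this package's
recovery experiments show is already informative. The top-200 lipids (or
top-50 metabolites) form the predictor set. Two properties of this procedure
are worth knowing. First, correlated true predictors split selection counts
— the lasso picks representatives — so a planted-truth recovery of 75–95%
into the top-200 is the realistic ceiling at these conditions, not a defect.
Second, near-unpenalized fits select a few dozen features per iteration, so
pure-noise compounds accumulate nonzero counts too; the ranking, not the raw
count, carries the signal.

# Age-resolved divergence

Age-unbiased compound selection equalizes both population and age-group
sample sizes: for each population pair and age group, 4 samples per
population are drawn 1,000 times; per compound, iterations with a pairwise
Welch p < 0.1 (nominal, uncorrected — this is a ranking device, not an
inference) are counted separately for positive and negative differences;
the top 25 lipids (10 metabolites) per direction are kept and everything is
unioned. Ties in occurrence counts break by larger mean absolute difference,
then compound id.

Divergence per age group is then `1 - rho`, the Spearman correlation
distance between population mean vectors over the selected compounds, each
mean built from 4 subsampled samples per population, 10,000 times (500 in
the scaled-down acceptance checks), summarized by median and quartiles. The
distance lives in [0, 2]; note that even identical populations sit at a
small positive noise floor determined by the subsample size, so "near
baseline" comparisons are made against the flat WE–AA profile, which
carries the same floor.

The classification-based view holds out all infants plus one sample per
adult age group, stability-selects on the rest, fits one-vs-rest models on
the union of the per-focal top-100 compounds, and predicts each held-out
sample by the highest-scoring model (argmax over the three one-vs-rest
scores; predicting a single population identity from three one-vs-rest
models does not fix a combiner, and argmax is the standard one). Held-out adults rotate through
per-group random permutations, so every sample is predicted after
max-group-size iterations without coupon-collector waste. Accuracy is
summarized per sample and as a median over a 10-sample sliding window after
age-sorting.

# Cross-dataset consistency

Matching against an independently measured lipid table proceeds by aligning
retention times through user-supplied anchor pairs (piecewise-linear, with
terminal segments extended; anchor choice is an explicit input because no
principled default exists), then pairing features within 5 ppm and 6 s.
Any feature with more than one candidate is discarded entirely — one
ambiguous match is worse than none. Fold-change consistency correlates
(Spearman) the HC-minus-rest mean log2 differences of the HC-specific
compounds across the two datasets; "rest" pools the WE and AA samples
rather than averaging per-population means. External validation normalizes
the current data by averaged centering/scaling over 1,000 draws of 31 per
population (so the parameters are population-balanced), the external data
by its own mean/sd, restricts stability selection to matched compounds, and
reports the external HC-vs-rest AUC as a function of the number of
top-ranked predictors.

# Annotation and enrichment

Mass annotation inverts the standard singly charged adduct offsets
([M+H]+ 1.007276, [M+Na]+ 22.989218, [M+NH4]+ 18.033823, [M−H]− −1.007276,
formate 44.998201, acetate 59.013851 Da) and reports reference entries
within 5 ppm of the implied neutral mass, tagged with adduct and signed ppm
error; multiple candidates are all kept and flagged ambiguous. Enrichment is
an upper-tail hypergeometric test per pathway on the genes linked to
foreground compounds against the genes linked to all annotated compounds,
BH-corrected. Genes in no pathway contribute to the universe only;
compounds with several annotations contribute the union of their genes.

# The synthetic-data generator

Per compound, log2 abundance is

    baseline + a * g(age) + delta * w(age) * [pop == HC]
             + b * batch + d * s(run_order) + c * PMI + noise

with `g` a centered logarithmic age trajectory (steepest in infancy), `w`
the HC-effect age window — zero below age 1, a gamma-density shape (shape 3,
per-compound scale drawn uniformly from 7–10, normalized to peak at 1) so
individual compounds peak between roughly 14 and 18 years — `s` a centered
logistic drift in run order, and Gaussian noise. Raw intensities are
`2^log2`; lipid values below the 200-count floor are reported at the floor,
metabolite values below it are reported missing (GC-MS-style censoring).
Cohort ages follow the six age-group proportions via largest-remainder
apportionment per population, so the default 303-sample cohort reproduces
the target group sizes exactly; ~30% of PMI values are masked after the
latent PMI has influenced the intensities, which is exactly the situation a
PMI filter faces in practice.

Default parameters and why:

* `n_per_population = (146, 97, 60)`, ages 0–71 — the motivating cohort's
  shape.
* `age_effect_sd = 0.185`, `noise_sd = 0.55` — calibrated once, by running
  the package's own ANOVA on generated data over several seeds, so that age
  explains ≈ 28% of lipid variance (observed 24–29% across seeds), the
  dominant-age regime the analysis assumes. Population identity lands at
  ≈ 1.5% under the default effect size.
* `hc_effect_size = 1.0` (log2 units at the window peak, random sign per
  compound), `n_hc_specific = 100` of ~1,400 pre-filter lipids — strong
  enough that the HC-specific median count dwarfs WE/AA and the HC AUC
  clearly exceeds the others, weak enough that recovery is a real test.
  Larger effects are counterproductive for stability-selection recovery:
  they concentrate the lasso on fewer representatives of the correlated
  planted block.
* `n_drift = 120`, `drift_effect = 1.5`; `n_pmi = 60`, `pmi_effect = 0.03`
  per hour over a 2–40 h PMI range — artifacts large enough to be clearly
  recoverable, matching their role as QC targets.
* Planted effect sets are disjoint and placed on well-detected compounds so
  that recovery rates are unambiguous.

What the generator does not emulate: correlated lipid classes (compounds
are independent given the shared covariates), heavy-tailed intensity noise,
retention-time drift within a run, isotope patterns, and any
chromatogram-level structure. Passing the planted-recovery tests therefore
shows the pipeline's statistics behave as designed under the stated
covariance structure — it does not certify performance on the correlation
structure of real lipidomes.

# Numerical choices and scaled-down problem sizes

Spearman p-values use the t approximation with midranks; degenerate
zero-variance Welch comparisons with equal means return p = 1; quantile
normalization averages tied quantiles; stability-selection ties break by
compound id for determinism; all subsampling is without replacement; every
stochastic routine takes an explicit seed, and the pipeline derives
per-stage seeds from one global seed by fixed offsets recorded in its run
manifest.

The package's own validation runs at deliberately reduced sizes chosen to
keep the full suite in a few minutes on one core: 100 specificity
iterations, 20 AUC repeats, 200 stability iterations, 200–1,000 age-window
iterations, 500 distance iterations. The production-scale defaults (10,000
stability iterations, 10,000 distance subsamples) remain the function
defaults; the reduced sizes are arguments, not forks of the code.

# Known limitations

* Drift scoring refits one SVR per compound; on very large tables this is
  the slowest QC step (~10 ms per compound).
* The agewise classification view re-runs stability selection inside every
  hold-out iteration; at production iteration counts this is expensive, and
  the implementation's rotation scheme (random permutations per age group)
  is the cheapest faithful coverage of "every sample predicted at least
  once".
* The contaminant rule quantifies a qualitative description; its two
  parameters (≥ 4 distinct retention times, > 0.5 min apart) are exposed in
  the configuration rather than hidden.
* `exclude_top_drift` with the production-scale counts (300/250) removes many
  clean peaks when applied to smaller simulated tables; the pipeline
  configuration therefore scales the exclusion count to the simulated drift
  prevalence.
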