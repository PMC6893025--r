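# Shared fixtures, built once per test run and cached.
#
# `small_study()` keeps the full 303-sample cohort (age-stratified analyses
# need every population represented in every age group) but few compounds,
# which is what drives runtime. `full_study()` is the generator at its
# default study conditions, used by the acceptance checks.

.fixture_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 11L, ...) {
  generator_config(n_lipids_pos = 120, n_lipids_neg = 80, n_metabolites = 60,
                   n_hc_specific = 20, n_hc_specific_met = 8,
                   n_drift = 16, n_pmi = 10, seed = seed, ...)
}

small_filter_cfg <- function() {
  # drift exclusion scaled to the simulated drift prevalence
  lipid_filter_config(drift_exclude_pos = 9, drift_exclude_neg = 7)
}

merge_lipids <- function(pos, neg) {
  intensity_matrix(rbind(pos$values, neg$values),
                   rbind(pos$features, neg$features),
                   pos$samples, scale = "log2")
}

adult_subset <- function(m) {
  st <- assign_dataset(m$samples)
  im_subset(m, samples = st$dataset == "DS:5-71")
}

small_study <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- small_cfg()
  cohort <- generate_cohort(cfg)
  dat <- generate_intensities(cohort, cfg)
  fcfg <- small_filter_cfg()
  pos <- preprocess_lipids(dat$lipids_pos, fcfg)
  neg <- preprocess_lipids(dat$lipids_neg, fcfg)
  lip <- merge_lipids(pos$matrix, neg$matrix)
  met <- preprocess_metabolites(dat$metabolites)$matrix
  .fixture_cache$small <- list(cfg = cfg, cohort = cohort, dat = dat,
                               lipids = lip, metabolites = met,
                               adult = adult_subset(lip))
  .fixture_cache$small
}

full_filter_cfg <- function(cfg = generator_config()) {
  frac_pos <- cfg$n_lipids_pos / (cfg$n_lipids_pos + cfg$n_lipids_neg)
  k_pos <- round(cfg$n_drift * frac_pos)
  lipid_filter_config(drift_exclude_pos = k_pos,
                      drift_exclude_neg = cfg$n_drift - k_pos)
}

full_study <- function() {
  if (!is.null(.fixture_cache$full)) return(.fixture_cache$full)
  cfg <- generator_config(seed = 1L)
  cohort <- generate_cohort(cfg)
  dat <- generate_intensities(cohort, cfg)
  fcfg <- full_filter_cfg(cfg)
  pos <- preprocess_lipids(dat$lipids_pos, fcfg)
  neg <- preprocess_lipids(dat$lipids_neg, fcfg)
  lip <- merge_lipids(pos$matrix, neg$matrix)
  .fixture_cache$full <- list(cfg = cfg, cohort = cohort, dat = dat,
                              lipids = lip, adult = adult_subset(lip))
  .fixture_cache$full
}

# planted HC-specific lipids still present in a processed matrix
planted_in <- function(truth, m) {
  intersect(truth$hc_specific_ids, m$features$compound_id)
}

# Hand-enumerated 20-peak toy table: every basic filter rule and boundary.
toy_lipid_table <- function() {
  st <- sample_table(data.frame(
    sample_id = paste0("s", 1:8), population = rep(c("HC", "WE"), 4),
    age = seq(10, 45, length.out = 8), run_order = 1:8))
  ids <- sprintf("P%02d", 1:20)
  rt <- c(1.4, 1.5, 18.0, 18.1, 5, 5,           # P01-P06 rt/mz boundaries
          6, 6, 7,                               # P07-P09 detection / floor
          2, 4, 6, 8,                            # P10-P13 contaminant group
          3, 10,                                 # P14-P15 same mz, 2 RTs only
          9, 11, 12, 13, 14)                     # P16-P20 plain keepers
  mz <- c(500, 501, 502, 503, 1400, 1400.5,
          504, 505, 506,
          600.000, 600.0005, 600.001, 599.9995,  # within 5 ppm of each other
          700, 700.0001,
          800, 810, 820, 830, 840)
  vals <- matrix(1000 + 10 * (1:20) + rep(1:8, each = 20), 20, 8,
                 dimnames = list(ids, st$sample_id))
  vals["P07", ] <- c(rep(1000, 6), 150, 180)     # >200 in exactly 6/8 = 75%
  vals["P08", ] <- c(rep(1000, 5), 150, 160, 170) # >200 in 5/8 < 75%
  vals["P09", ] <- c(150, rep(1000, 7))          # kept, one sub-floor value
  feat <- data.frame(compound_id = ids, kind = "lipid", mz = mz, rt = rt,
                     ion_mode = "positive", name = NA)
  intensity_matrix(vals, feat, st, scale = "raw")
}

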