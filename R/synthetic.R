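#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a three-population
#' postmortem prefrontal-cortex cohort profiled by untargeted LC-MS
#' (lipids, positive and negative ionization) and GC-MS (polar metabolites):
#' a dominant age effect, a subset of compounds shifted specifically in the
#' HC population with an age-dependent window (absent in infancy, peaking in
#' young adulthood, declining thereafter), plus run-order drift, extraction
#' batch, PMI-correlated, and below-detection-floor artifacts. Ground-truth
#' labels of every planted effect are returned for recovery testing.
#'
#' @param n_per_population named counts for populations HC, WE, AA.
#' @param n_lipids_pos,n_lipids_neg number of lipid peaks per ionization mode
#'   before quality filtering.
#' @param n_metabolites number of polar metabolites before filtering.
#' @param n_hc_specific number of lipid peaks carrying a planted HC-specific
#'   shift; `n_hc_specific_met` is the metabolite analogue.
#' @param hc_effect_size absolute HC shift in log2 units at the peak of the
#'   age window (random sign per compound).
#' @param age_effect_sd standard deviation of per-compound age slopes applied
#'   to the common age trajectory (log2 units per unit trajectory).
#' @param n_drift number of lipid peaks with planted run-order drift (split
#'   across modes proportionally); `drift_effect` is the drift amplitude in
#'   log2 units.
#' @param n_pmi number of lipid peaks with planted PMI correlation;
#'   `n_pmi_met` the metabolite analogue; `pmi_effect` the slope in log2
#'   units per hour.
#' @param n_contaminant_groups number of planted contaminant groups (one m/z
#'   recurring at many retention times) per ionization mode;
#'   `contaminant_group_size` peaks per group.
#' @param batch_sd magnitude of the two-level batch effect (log2 units).
#' @param floor raw detection floor; lipid intensities below it are reported
#'   at the floor, metabolite intensities below it are reported missing.
#' @param noise_sd residual standard deviation in log2 units.
#' @param seed integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_population = c(HC = 146, WE = 97, AA = 60),
                             n_lipids_pos = 800,
                             n_lipids_neg = 600,
                             n_metabolites = 300,
                             n_hc_specific = 100,
                             n_hc_specific_met = 30,
                             hc_effect_size = 1.0,
                             age_effect_sd = 0.185,
                             n_drift = 120,
                             drift_effect = 1.5,
                             n_pmi = 60,
                             n_pmi_met = 20,
                             pmi_effect = 0.03,
                             n_contaminant_groups = 2,
                             contaminant_group_size = 5,
                             batch_sd = 0.2,
                             floor = 200,
                             noise_sd = 0.55,
                             seed = 1L) {
  cfg <- list(n_per_population = n_per_population, n_lipids_pos = n_lipids_pos,
              n_lipids_neg = n_lipids_neg, n_metabolites = n_metabolites,
              n_hc_specific = n_hc_specific,
              n_hc_specific_met = n_hc_specific_met,
              hc_effect_size = hc_effect_size, age_effect_sd = age_effect_sd,
              n_drift = n_drift, drift_effect = drift_effect, n_pmi = n_pmi,
              n_pmi_met = n_pmi_met, pmi_effect = pmi_effect,
              n_contaminant_groups = n_contaminant_groups,
              contaminant_group_size = contaminant_group_size,
              batch_sd = batch_sd, floor = floor, noise_sd = noise_sd,
              seed = as.integer(seed))
  counts <- c(cfg$n_lipids_pos, cfg$n_lipids_neg, cfg$n_metabolites,
              cfg$n_hc_specific, cfg$n_drift, cfg$n_pmi)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(!is.finite(c(cfg$hc_effect_size, cfg$age_effect_sd, cfg$noise_sd))))
    stop("effect sizes must be finite")
  if (cfg$n_hc_specific > cfg$n_lipids_pos + cfg$n_lipids_neg)
    stop("n_hc_specific exceeds number of lipids")
  if (!all(c("HC", "WE", "AA") %in% names(cfg$n_per_population)))
    stop("n_per_population must name HC, WE and AA")
  class(cfg) <- "generator_config"
  cfg
}

# Age-group proportions the cohort emulates (groups split at 1/5/15/25/45 y).
AGE_GROUP_WEIGHTS <- c(A1 = 24, A2 = 50, A3 = 41, A4 = 56, A5 = 56, A6 = 76)
AGE_GROUP_RANGES <- list(A1 = c(0, 1), A2 = c(1, 5), A3 = c(5, 15),
                         A4 = c(15, 25), A5 = c(25, 45), A6 = c(45, 71))

# Largest-remainder apportionment of n into the age-group proportions, so a
# default-sized cohort reproduces the target group sizes exactly.
apportion <- function(n, weights) {
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic cohort
#'
#' Draws a sample table whose age distribution follows the study's six
#' age-group proportions (dense infant sampling, coverage to 71 years), with
#' RIN in `[4, 10]`, PMI in `[2, 40]` hours (~30% missing), a two-level
#' extraction batch, and a random run-order permutation.
#'
#' @param cfg a [generator_config()].
#' @return A `sample_table` with `dataset` and `age_group` labels attached.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  pops <- rep(c("HC", "WE", "AA"), times = cfg$n_per_population[c("HC", "WE", "AA")])
  n <- length(pops)
  # per-population apportionment keeps every population represented in every
  # age group, which downstream equal-n subsampling relies on
  ages <- unlist(lapply(c("HC", "WE", "AA"), function(p) {
    np <- cfg$n_per_population[[p]]
    counts <- apportion(np, AGE_GROUP_WEIGHTS)
    unlist(lapply(seq_along(counts), function(g) {
      rg <- AGE_GROUP_RANGES[[g]]
      stats::runif(counts[g], rg[1], rg[2])
    }))
  }), use.names = FALSE)
  pmi_latent <- stats::runif(n, 2, 40)
  pmi <- pmi_latent
  pmi[stats::runif(n) < 0.3] <- NA
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = pops,
    age = ages,
    sex = sample(c("M", "F"), n, replace = TRUE),
    rin = round(stats::runif(n, 4, 10), 1),
    pmi = round(pmi, 1),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    run_order = sample.int(n),
    stringsAsFactors = FALSE
  )
  st <- sample_table(df)
  attr(st, "pmi_latent") <- pmi_latent
  assign_age_group(assign_dataset(st))
}

# Age window of the HC-specific effect: zero during the first year of life,
# rising to a peak in young adulthood and decaying thereafter. Scaled gamma
# density (shape 3, default scale 8), normalized to max 1 (mode at
# (shape-1)*scale years, 16 by default). Individual compounds peak at
# slightly different ages, so the generator draws a per-compound scale.
hc_age_window <- function(age, shape = 3, scale = 8) {
  w <- stats::dgamma(age, shape = shape, scale = scale) /
    stats::dgamma((shape - 1) * scale, shape = shape, scale = scale)
  w[age < 1] <- 0
  w
}

# Common age trajectory: logarithmic in age, steep in infancy, centered so
# slopes translate directly into cross-cohort variance.
age_trajectory <- function(age) {
  g <- log2(age + 0.5)
  g - mean(g)
}

# Smooth monotone run-order drift shape, centered, range ~1.
drift_shape <- function(run_order, n) {
  stats::plogis((run_order - (n + 1) / 2) / (n / 8)) - 0.5
}

simulate_block <- function(cohort, cfg, n_compounds, prefix, kind, ion_mode,
                           plant_hc, plant_drift, plant_pmi, plant_contam,
                           baseline_range) {
  n_samp <- nrow(cohort)
  ids <- sprintf("%s%04d", prefix, seq_len(n_compounds))
  baseline <- stats::runif(n_compounds, baseline_range[1], baseline_range[2])

  # planted effects go on reliably detected compounds; the three planted sets
  # are disjoint so recovery rates are unambiguous
  eligible <- which(baseline >= baseline_range[1] + 0.25 * diff(baseline_range))
  need <- plant_hc + plant_drift + plant_pmi
  if (need > length(eligible)) stop("not enough well-detected compounds to plant effects")
  chosen <- sample(eligible, need)
  hc_idx <- chosen[seq_len(plant_hc)]
  drift_idx <- chosen[plant_hc + seq_len(plant_drift)]
  pmi_idx <- chosen[plant_hc + plant_drift + seq_len(plant_pmi)]

  a <- stats::rnorm(n_compounds, 0, cfg$age_effect_sd)
  delta <- numeric(n_compounds)
  delta[hc_idx] <- cfg$hc_effect_size * sample(c(-1, 1), plant_hc, replace = TRUE)
  d <- numeric(n_compounds)
  d[drift_idx] <- cfg$drift_effect * sample(c(-1, 1), plant_drift, replace = TRUE)
  cc <- numeric(n_compounds)
  cc[pmi_idx] <- cfg$pmi_effect * sample(c(-1, 1), plant_pmi, replace = TRUE)
  b <- cfg$batch_sd * sample(c(-1, 1), n_compounds, replace = TRUE)

  g <- age_trajectory(cohort$age)
  # per-compound window scale: planted compounds peak at (shape-1)*scale
  # years, i.e. between 14 and 18, rather than all at exactly the same age
  window_scale <- rep(8, n_compounds)
  window_scale[hc_idx] <- stats::runif(plant_hc, 7, 10)
  w_by_compound <- matrix(0, n_compounds, n_samp)
  for (i in hc_idx)
    w_by_compound[i, ] <- hc_age_window(cohort$age, scale = window_scale[i])
  hc <- as.numeric(cohort$population == "HC")
  batch_sign <- ifelse(cohort$batch == "b1", -0.5, 0.5)
  s <- drift_shape(cohort$run_order, n_samp)
  pmi_latent <- attr(cohort, "pmi_latent")
  if (is.null(pmi_latent)) pmi_latent <- ifelse(is.na(cohort$pmi), mean(cohort$pmi, na.rm = TRUE), cohort$pmi)
  pmi_c <- pmi_latent - mean(pmi_latent)

  log2v <- baseline +
    outer(a, g) +
    sweep(delta * w_by_compound, 2, hc, `*`) +
    outer(b, batch_sign) +
    outer(d, s) +
    outer(cc, pmi_c) +
    matrix(stats::rnorm(n_compounds * n_samp, 0, cfg$noise_sd),
           n_compounds, n_samp)
  raw <- 2^log2v

  if (kind == "lipid") {
    raw[raw < cfg$floor] <- cfg$floor
    mz <- stats::runif(n_compounds, 250, 1200)
    # a few peaks beyond the mass cutoff and outside the RT window exercise
    # the basic filters
    n_out <- max(1, round(0.02 * n_compounds))
    mz[sample.int(n_compounds, n_out)] <- stats::runif(n_out, 1400.5, 1600)
    rt <- stats::runif(n_compounds, 1.6, 17.5)
    out_rt <- sample.int(n_compounds, n_out)
    rt[out_rt] <- sample(c(stats::runif(n_out, 0.3, 1.45),
                           stats::runif(n_out, 18.1, 19.5)), n_out)
    contam_idx <- integer(0)
    if (plant_contam > 0) {
      gs <- cfg$contaminant_group_size
      pool <- setdiff(seq_len(n_compounds), c(chosen, which(mz > 1400)))
      contam_idx <- sample(pool, plant_contam * gs)
      for (gi in seq_len(plant_contam)) {
        members <- contam_idx[(gi - 1) * gs + seq_len(gs)]
        mz0 <- stats::runif(1, 300, 900)
        mz[members] <- mz0 * (1 + stats::rnorm(gs, 0, 1e-6))
        rt[members] <- seq(2, 16, length.out = gs) + stats::runif(gs, -0.2, 0.2)
      }
    }
    features <- data.frame(compound_id = ids, kind = "lipid", mz = mz, rt = rt,
                           ion_mode = ion_mode, name = NA_character_,
                           stringsAsFactors = FALSE)
  } else {
    raw[raw < cfg$floor] <- NA  # GC-MS below-floor values are reported missing
    contam_idx <- integer(0)
    features <- data.frame(compound_id = ids, kind = "metabolite",
                           mz = NA_real_, rt = NA_real_, ion_mode = "none",
                           name = paste0("met_", seq_len(n_compounds)),
                           stringsAsFactors = FALSE)
  }
  dimnames(raw) <- list(ids, cohort$sample_id)
  list(matrix = intensity_matrix(raw, features, cohort, scale = "raw"),
       hc_ids = ids[hc_idx], drift_ids = ids[drift_idx],
       pmi_ids = ids[pmi_idx], contaminant_ids = ids[contam_idx],
       params = data.frame(compound_id = ids, baseline = baseline,
                           age_slope = a, hc_delta = delta,
                           hc_window_scale = window_scale, drift_amp = d,
                           pmi_slope = cc, stringsAsFactors = FALSE))
}

#' Generate synthetic intensity matrices with ground truth
#'
#' Per compound, log2 abundance follows
#' `baseline + a*g(age) + delta*w(age)*[pop == HC] + b*batch + d*s(run) +
#' c*pmi + noise`, where `g` is a logarithmic age trajectory, `w` the
#' HC-effect age window (zero below age 1, gamma-shaped peak in young
#' adulthood), and `s` a smooth monotone run-order drift. Raw intensities are
#' `2^log2`; lipid values below the detection floor are reported at the
#' floor, metabolite values below it are reported missing.
#'
#' @param cohort a `sample_table` from [generate_cohort()].
#' @param cfg the same [generator_config()].
#' @return list with `lipids_pos`, `lipids_neg`, `metabolites`
#'   (`intensity_matrix` objects, raw scale) and `truth` (planted id sets and
#'   per-compound parameters).
#' @export
generate_intensities <- function(cohort, cfg = generator_config()) {
  set.seed(cfg$seed + 1L)
  n_lip <- cfg$n_lipids_pos + cfg$n_lipids_neg
  frac_pos <- cfg$n_lipids_pos / n_lip
  hc_pos <- round(cfg$n_hc_specific * frac_pos)
  drift_pos <- round(cfg$n_drift * frac_pos)
  pmi_pos <- round(cfg$n_pmi * frac_pos)
  pos <- simulate_block(cohort, cfg, cfg$n_lipids_pos, "LP", "lipid", "positive",
                        hc_pos, drift_pos, pmi_pos,
                        cfg$n_contaminant_groups, c(8, 20))
  neg <- simulate_block(cohort, cfg, cfg$n_lipids_neg, "LN", "lipid", "negative",
                        cfg$n_hc_specific - hc_pos, cfg$n_drift - drift_pos,
                        cfg$n_pmi - pmi_pos,
                        cfg$n_contaminant_groups, c(8, 20))
  met <- simulate_block(cohort, cfg, cfg$n_metabolites, "MT", "metabolite", "none",
                        cfg$n_hc_specific_met, 0, cfg$n_pmi_met, 0, c(7, 18))
  truth <- list(
    hc_specific_ids = c(pos$hc_ids, neg$hc_ids, met$hc_ids),
    drift_ids = c(pos$drift_ids, neg$drift_ids),
    pmi_ids = c(pos$pmi_ids, neg$pmi_ids, met$pmi_ids),
    contaminant_ids = c(pos$contaminant_ids, neg$contaminant_ids),
    params = rbind(pos$params, neg$params, met$params)
  )
  list(lipids_pos = pos$matrix, lipids_neg = neg$matrix,
       metabolites = met$matrix, truth = truth)
}

#' Simulate a full study to disk
#'
#' Writes the cohort table, the three intensity matrices and the
#' ground-truth labels under `dir`.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the list of written paths.
#' @export
simulate_study <- function(cfg = generator_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cfg)
  dat <- generate_intensities(cohort, cfg)
  paths <- list(
    samples = file.path(dir, "samples.tsv"),
    lipids_pos = file.path(dir, "lipids_positive.tsv"),
    lipids_neg = file.path(dir, "lipids_negative.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_sample_tsv(cohort, paths$samples)
  write_intensity_tsv(dat$lipids_pos, paths$lipids_pos)
  write_intensity_tsv(dat$lipids_neg, paths$lipids_neg)
  write_intensity_tsv(dat$metabolites, paths$metabolites)
  jsonlite::write_json(dat$truth[c("hc_specific_ids", "drift_ids", "pmi_ids",
                                   "contaminant_ids")],
                       paths$truth, pretty = TRUE)
  invisible(paths)
}

#' Simulate an independent replication cohort from existing ground truth
#'
#' Re-measures a set of previously generated compounds in a new cohort, as an
#' independent laboratory would: identical per-compound baselines, age
#' slopes, HC effects (with their age windows), drift amplitudes and PMI
#' slopes are reused from `truth`, while noise, batch structure, run order
#' and the chromatographic scale are fresh. Retention times are warped by an
#' affine map and m/z values are jittered by a small ppm error to emulate
#' cross-instrument differences, so recovering the correspondence requires
#' retention-time alignment and tolerance matching.
#'
#' @param cohort a `sample_table` for the replication cohort (e.g. from
#'   [generate_cohort()] with small `n_per_population`).
#' @param cfg the [generator_config()] the original study used (noise and
#'   floor settings are reused).
#' @param truth the `truth` element returned by [generate_intensities()].
#' @param features feature table of the compounds to re-measure (lipids of
#'   one or both ionization modes, e.g. `dat$lipids_pos$features`).
#' @param seed integer seed.
#' @param rt_warp affine retention-time warp `c(intercept, slope)` applied to
#'   the source retention times.
#' @param mz_ppm_sd standard deviation of the per-feature m/z error in ppm.
#' @return An `intensity_matrix` (raw scale) whose compound ids carry a
#'   `"R_"` prefix; the id correspondence is recoverable only through mass
#'   and retention-time matching.
#' @export
generate_replica <- function(cohort, cfg, truth, features,
                             seed = cfg$seed + 1000L,
                             rt_warp = c(0.2, 1.02), mz_ppm_sd = 1) {
  set.seed(seed)
  params <- truth$params[match(features$compound_id, truth$params$compound_id), ]
  if (anyNA(params$compound_id))
    stop("features contain compounds absent from the ground truth")
  n_samp <- nrow(cohort)
  n_comp <- nrow(features)
  g <- age_trajectory(cohort$age)
  hc <- as.numeric(cohort$population == "HC")
  batch_sign <- ifelse(cohort$batch == "b1", -0.5, 0.5)
  s <- drift_shape(cohort$run_order, n_samp)
  pmi_latent <- attr(cohort, "pmi_latent")
  if (is.null(pmi_latent))
    pmi_latent <- ifelse(is.na(cohort$pmi), mean(cohort$pmi, na.rm = TRUE), cohort$pmi)
  pmi_c <- if (all(is.na(pmi_latent))) rep(0, n_samp) else pmi_latent - mean(pmi_latent)
  w_by_compound <- matrix(0, n_comp, n_samp)
  for (i in which(params$hc_delta != 0))
    w_by_compound[i, ] <- hc_age_window(cohort$age, scale = params$hc_window_scale[i])
  b <- cfg$batch_sd * sample(c(-1, 1), n_comp, replace = TRUE)
  log2v <- params$baseline +
    outer(params$age_slope, g) +
    sweep(params$hc_delta * w_by_compound, 2, hc, `*`) +
    outer(b, batch_sign) +
    outer(params$drift_amp, s) +
    outer(params$pmi_slope, pmi_c) +
    matrix(stats::rnorm(n_comp * n_samp, 0, cfg$noise_sd), n_comp, n_samp)
  raw <- 2^log2v
  raw[raw < cfg$floor] <- cfg$floor
  new_feat <- features
  new_feat$compound_id <- paste0("R_", features$compound_id)
  new_feat$rt <- rt_warp[1] + rt_warp[2] * features$rt
  new_feat$mz <- features$mz * (1 + stats::rnorm(n_comp, 0, mz_ppm_sd * 1e-6))
  dimnames(raw) <- list(new_feat$compound_id, cohort$sample_id)
  intensity_matrix(raw, new_feat, cohort, scale = "raw")
}
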