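#' Default pipeline configuration
#'
#' Every threshold of the analysis in one nested list, suitable for
#' serialization to YAML. Stage-specific seeds are derived from the single
#' global seed by fixed offsets and recorded in the run manifest.
#'
#' @param seed global integer seed.
#' @param n_iter_specificity subsampling iterations for the specificity
#'   stage.
#' @param n_repeats_auc resampled splits for the AUC curve.
#' @param n_stab stability-selection iterations.
#' @param n_iter_distance subsampling iterations per age group for the
#'   distance profile.
#' @param generator overrides passed to [generator_config()].
#' @return A nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, n_iter_specificity = 100,
                            n_repeats_auc = 20, n_stab = 200,
                            n_iter_distance = 1000, generator = list()) {
  gen <- do.call(generator_config, c(generator, list(seed = seed)))
  # drift exclusion scaled to the simulated drift prevalence (one excluded
  # peak per planted drifting peak, split across modes like the generator)
  frac_pos <- gen$n_lipids_pos / (gen$n_lipids_pos + gen$n_lipids_neg)
  k_pos <- round(gen$n_drift * frac_pos)
  list(
    seed = as.integer(seed),
    generator = gen,
    lipid_filters = lipid_filter_config(drift_exclude_pos = k_pos,
                                        drift_exclude_neg = gen$n_drift - k_pos),
    pmi_p = 0.01,
    specificity = list(n_per_pop = 25, n_iter = n_iter_specificity,
                       alpha = 0.05),
    classify = list(n_per_pop = 31, C_final = 1000,
                    n_repeats = n_repeats_auc, n_stab = n_stab, top_k = 200),
    age_dynamics = list(n_per_pop = 4, n_iter = 250, top_k = 25,
                        n_iter_distance = n_iter_distance)
  )
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 0L, preprocess = 101L, variance = 202L,
               specificity = 303L, classify = 404L, age_dynamics = 505L)
  cfg$seed + offsets[[stage]]
}

#' Run the full analysis workflow
#'
#' Executes simulate -> preprocess -> variance -> specificity -> classify ->
#' age dynamics in dependency order on generator output, writing stage
#' outputs as TSV/JSON under `out_dir` together with a run manifest (config
#' snapshot, per-stage seeds, MD5 hash of every output file, package
#' version). Re-running with an identical configuration reproduces identical
#' outputs and manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param stages subset of stages to run (dependencies must already have run
#'   into the same `out_dir`).
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "preprocess", "variance",
                                    "specificity", "classify", "age_dynamics")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("simulate", "preprocess", "variance", "specificity", "classify",
             "age_dynamics")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  written <- character(0)
  log_stage <- function(s) message("[popdiverge] stage: ", s)
  state <- new.env(parent = emptyenv())

  reload <- function(what) {
    # stages can be re-run individually; upstream outputs are reloaded from disk
    path <- file.path(out_dir, what)
    if (!file.exists(path))
      stop("missing upstream output '", what, "' in ", out_dir,
           "; run the earlier stages first")
    path
  }

  if ("simulate" %in% stages) {
    log_stage("simulate")
    cfg <- config$generator
    cfg$seed <- as.integer(stage_seed(config, "simulate"))
    paths <- simulate_study(cfg, out_dir)
    state$cohort <- read_sample_tsv(paths$samples)
    state$lipids_pos <- read_intensity_tsv(paths$lipids_pos, state$cohort, "raw")
    state$lipids_neg <- read_intensity_tsv(paths$lipids_neg, state$cohort, "raw")
    state$metabolites <- read_intensity_tsv(paths$metabolites, state$cohort, "raw")
    written <- c(written, unlist(paths))
  } else if (any(c("preprocess", "variance", "specificity", "classify",
                   "age_dynamics") %in% stages)) {
    state$cohort <- read_sample_tsv(reload("samples.tsv"))
    state$lipids_pos <- read_intensity_tsv(reload("lipids_positive.tsv"),
                                           state$cohort, "raw")
    state$lipids_neg <- read_intensity_tsv(reload("lipids_negative.tsv"),
                                           state$cohort, "raw")
    state$metabolites <- read_intensity_tsv(reload("metabolites.tsv"),
                                            state$cohort, "raw")
  }

  need_lipids <- function() {
    if (is.null(state$lipids)) {
      pos <- preprocess_lipids(state$lipids_pos, config$lipid_filters,
                               pmi_p = config$pmi_p)
      neg <- preprocess_lipids(state$lipids_neg, config$lipid_filters,
                               pmi_p = config$pmi_p)
      vals <- rbind(pos$matrix$values, neg$matrix$values)
      feats <- rbind(pos$matrix$features, neg$matrix$features)
      state$lipids <- intensity_matrix(vals, feats, pos$matrix$samples,
                                       scale = "log2")
      state$lipid_report <- rbind(pos$report, neg$report)
    }
    state$lipids
  }

  if ("preprocess" %in% stages) {
    log_stage("preprocess")
    lip <- need_lipids()
    met <- preprocess_metabolites(state$metabolites)
    state$met <- pmi_filter(met$matrix, p_threshold = config$pmi_p)$matrix
    p1 <- file.path(out_dir, "lipids_log2.tsv")
    p2 <- file.path(out_dir, "metabolites_log2.tsv")
    p3 <- file.path(out_dir, "lipid_filter_report.tsv")
    write_intensity_tsv(lip, p1)
    write_intensity_tsv(state$met, p2)
    utils::write.table(state$lipid_report, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, p1, p2, p3)
  } else if (any(c("variance", "specificity", "classify", "age_dynamics") %in% stages)) {
    state$lipids <- read_intensity_tsv(reload("lipids_log2.tsv"),
                                       state$cohort, "log2")
    state$met <- read_intensity_tsv(reload("metabolites_log2.tsv"),
                                    state$cohort, "log2")
  }

  adult <- function(m) {
    st <- assign_dataset(m$samples)
    im_subset(m, samples = st$dataset == "DS:5-71")
  }

  if ("variance" %in% stages) {
    log_stage("variance")
    vp <- variance_explained(state$lipids)
    p <- file.path(out_dir, "variance_partition.tsv")
    utils::write.table(vp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }

  if ("specificity" %in% stages) {
    log_stage("specificity")
    des <- subsampling_design(n_per_pop = config$specificity$n_per_pop,
                              n_iter = config$specificity$n_iter,
                              alpha = config$specificity$alpha,
                              seed = stage_seed(config, "specificity"))
    res <- subsampled_specificity(adult(state$lipids), des)
    p1 <- file.path(out_dir, "specificity_counts.tsv")
    utils::write.table(
      data.frame(iteration = seq_len(nrow(res$counts)), res$counts),
      p1, sep = "\t", quote = FALSE, row.names = FALSE)
    full <- population_specific_set(adult(state$lipids),
                                    alpha = config$specificity$alpha)
    p2 <- file.path(out_dir, "hc_specific_lipids.tsv")
    utils::write.table(full$HC, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p1, p2)
  }

  if ("classify" %in% stages) {
    log_stage("classify")
    ccfg <- classifier_config(n_per_pop = config$classify$n_per_pop,
                              C_final = config$classify$C_final,
                              n_repeats = config$classify$n_repeats,
                              n_stab = config$classify$n_stab,
                              top_k = config$classify$top_k,
                              seed = stage_seed(config, "classify"))
    lip_adult <- adult(state$lipids)
    auc <- do.call(rbind, lapply(POPULATIONS, function(p) {
      cbind(population = p, ovr_auc_curve(lip_adult, focal = p, cfg = ccfg))
    }))
    p1 <- file.path(out_dir, "auc_curve.tsv")
    utils::write.table(auc, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    rk <- stability_selection(lip_adult, focal = "HC", cfg = ccfg)
    p2 <- file.path(out_dir, "stability_ranking.tsv")
    utils::write.table(
      data.frame(compound_id = names(rk$counts), count = rk$counts,
                 in_top_k = names(rk$counts) %in% rk$top_k),
      p2, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p1, p2)
  }

  if ("age_dynamics" %in% stages) {
    log_stage("age_dynamics")
    acfg <- age_unbiased_config(n_per_pop = config$age_dynamics$n_per_pop,
                                n_iter = config$age_dynamics$n_iter,
                                top_k = config$age_dynamics$top_k,
                                seed = stage_seed(config, "age_dynamics"))
    set_ids <- age_unbiased_compounds(state$lipids, cfg = acfg)
    prof <- correlation_distance_profile(
      state$lipids, set_ids, n_iter = config$age_dynamics$n_iter_distance,
      n_per_pop = config$age_dynamics$n_per_pop,
      seed = stage_seed(config, "age_dynamics") + 1L)
    p1 <- file.path(out_dir, "age_unbiased_compounds.txt")
    writeLines(set_ids, p1)
    p2 <- file.path(out_dir, "distance_profile.tsv")
    utils::write.table(prof, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p1, p2)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("popdiverge")),
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = known), function(s) stage_seed(config, s)),
    stages_run = stages,
    config = config,
    outputs = as.list(tools::md5sum(sort(unique(written))))
  )
  names(manifest$outputs) <- basename(sort(unique(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Validate a sample table and intensity matrices on disk
#'
#' Reads the TSVs and runs every construction-time invariant; intended as
#' the `validate` entry point of the command-line interface.
#'
#' @param samples_tsv path to the sample table.
#' @param intensity_tsvs optional character vector of intensity matrix paths.
#' @return `TRUE` invisibly on success (errors otherwise).
#' @export
validate_inputs <- function(samples_tsv, intensity_tsvs = character(0)) {
  st <- read_sample_tsv(samples_tsv)
  for (p in intensity_tsvs) read_intensity_tsv(p, st)
  message("validated ", samples_tsv,
          if (length(intensity_tsvs) > 0)
            paste0(" and ", length(intensity_tsvs), " intensity matrix file(s)"))
  invisible(TRUE)
}
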