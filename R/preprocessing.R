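#' Lipid peak-table filter configuration
#'
#' Thresholds for the basic LC-MS lipid quality filters and the run-order
#' drift exclusion.
#'
#' @param rt_min,rt_max retention-time window in minutes (closed interval).
#' @param mz_max upper m/z cutoff in Da.
#' @param floor raw detection floor; values at or below it count as
#'   undetected, and sub-floor values on kept peaks are replaced by the floor.
#' @param detect_frac minimum fraction of samples in which a peak must exceed
#'   the floor (boundary inclusive).
#' @param dup_mz_tol_ppm,dup_rt_count,dup_rt_gap contaminant rule: peaks whose
#'   m/z recurs (within `dup_mz_tol_ppm`) at `dup_rt_count` or more retention
#'   times separated by more than `dup_rt_gap` minutes are dropped.
#' @param drift_exclude_pos,drift_exclude_neg number of top drift-scored peaks
#'   excluded per ionization mode.
#' @param svr_C,svr_epsilon,svr_gamma Gaussian-kernel support vector
#'   regression hyperparameters for the drift fit.
#' @param drift_trim number of highest-intensity samples dropped before the
#'   drift fit.
#' @return A `lipid_filter_config` list.
#' @export
lipid_filter_config <- function(rt_min = 1.5, rt_max = 18, mz_max = 1400,
                                floor = 200, detect_frac = 0.75,
                                dup_mz_tol_ppm = 5, dup_rt_count = 4,
                                dup_rt_gap = 0.5,
                                drift_exclude_pos = 300,
                                drift_exclude_neg = 250,
                                svr_C = 1e5, svr_epsilon = 0.1,
                                svr_gamma = 1e-4, drift_trim = 3) {
  stopifnot(detect_frac > 0, detect_frac <= 1,
            drift_exclude_pos >= 0, drift_exclude_neg >= 0)
  structure(list(rt_min = rt_min, rt_max = rt_max, mz_max = mz_max,
                 floor = floor, detect_frac = detect_frac,
                 dup_mz_tol_ppm = dup_mz_tol_ppm, dup_rt_count = dup_rt_count,
                 dup_rt_gap = dup_rt_gap,
                 drift_exclude_pos = drift_exclude_pos,
                 drift_exclude_neg = drift_exclude_neg,
                 svr_C = svr_C, svr_epsilon = svr_epsilon,
                 svr_gamma = svr_gamma, drift_trim = drift_trim),
            class = "lipid_filter_config")
}

filter_report_row <- function(ids, rule, statistic, keep) {
  data.frame(compound_id = ids, rule = rule, statistic = statistic,
             decision = ifelse(keep, "keep", "drop"),
             stringsAsFactors = FALSE)
}

#' Basic lipid peak filters
#'
#' Applies, in order: the retention-time window, the upper m/z cutoff, the
#' detection filter (intensity strictly greater than the floor in at least
#' `detect_frac` of samples), the floor replacement (sub-floor values on kept
#' peaks are set to the floor), and the contaminant rule (one m/z recurring
#' at many distinct retention times).
#'
#' @param raw a raw-scale lipid `intensity_matrix`.
#' @param cfg a [lipid_filter_config()].
#' @return list with the filtered `matrix` and a `report` data.frame holding
#'   one row per compound per rule (rule, statistic, keep/drop).
#' @export
basic_lipid_filters <- function(raw, cfg = lipid_filter_config()) {
  stopifnot(inherits(raw, "intensity_matrix"), raw$scale == "raw")
  feat <- raw$features
  report <- list()

  keep_rt <- feat$rt >= cfg$rt_min & feat$rt <= cfg$rt_max
  report$rt <- filter_report_row(feat$compound_id, "rt_window", feat$rt, keep_rt)
  keep_mz <- feat$mz <= cfg$mz_max
  report$mz <- filter_report_row(feat$compound_id, "mz_max", feat$mz, keep_mz)

  det_frac <- rowMeans(raw$values > cfg$floor, na.rm = TRUE)
  keep_det <- det_frac >= cfg$detect_frac
  report$detect <- filter_report_row(feat$compound_id, "detection", det_frac,
                                     keep_det)

  # contaminant rule: same m/z (within ppm tolerance) at >= dup_rt_count
  # retention times more than dup_rt_gap apart
  ord <- order(feat$mz)
  grp <- integer(nrow(feat))
  gid <- 0L
  last_mz <- -Inf
  for (i in ord) {
    if ((feat$mz[i] - last_mz) / feat$mz[i] * 1e6 > cfg$dup_mz_tol_ppm) gid <- gid + 1L
    grp[i] <- gid
    last_mz <- feat$mz[i]
  }
  n_distinct_rt <- vapply(split(feat$rt, grp), function(rts) {
    rts <- sort(rts)
    sum(c(TRUE, diff(rts) > cfg$dup_rt_gap))
  }, numeric(1))
  rt_count <- n_distinct_rt[as.character(grp)]
  keep_dup <- rt_count < cfg$dup_rt_count
  report$dup <- filter_report_row(feat$compound_id, "contaminant", rt_count,
                                  keep_dup)

  keep <- keep_rt & keep_mz & keep_det & keep_dup
  if (!any(keep)) stop("no lipid peaks remain after basic filters")
  out <- im_subset(raw, compounds = keep)
  out$values[out$values < cfg$floor] <- cfg$floor
  list(matrix = out, report = do.call(rbind, unname(report)))
}

#' Run-order drift scores
#'
#' For each compound, drops the `drift_trim` samples with the highest
#' intensity, fits a Gaussian-kernel support vector regression of intensity
#' on run order, and returns the in-sample coefficient of determination of
#' the fit. High scores flag peaks whose measured intensity tracks the
#' acquisition sequence.
#'
#' @param m a raw-scale `intensity_matrix` whose samples all carry a run
#'   order.
#' @param cfg a [lipid_filter_config()] (SVR hyperparameters).
#' @return Named numeric vector of R-squared values, one per compound.
#' @export
runorder_drift_scores <- function(m, cfg = lipid_filter_config()) {
  stopifnot(inherits(m, "intensity_matrix"))
  ro <- m$samples$run_order
  if (anyNA(ro)) stop("run order missing for some samples")
  vals <- m$values
  scores <- vapply(seq_len(nrow(vals)), function(i) {
    y <- vals[i, ]
    keep <- seq_along(y)
    if (cfg$drift_trim > 0)
      keep <- order(y, decreasing = TRUE)[-seq_len(cfg$drift_trim)]
    yk <- y[keep]; xk <- ro[keep]
    if (stats::var(yk) == 0) return(0)
    fit <- e1071::svm(x = matrix(as.numeric(xk), ncol = 1), y = yk,
                      type = "eps-regression", kernel = "radial",
                      cost = cfg$svr_C, epsilon = cfg$svr_epsilon,
                      gamma = cfg$svr_gamma, scale = FALSE)
    pred <- stats::predict(fit, matrix(as.numeric(xk), ncol = 1))
    1 - sum((yk - pred)^2) / sum((yk - mean(yk))^2)
  }, numeric(1))
  names(scores) <- m$features$compound_id
  scores
}

#' Exclude the peaks with strongest run-order dependency
#'
#' Removes the `k` top-scoring compounds per ionization mode (`k` from
#' `cfg$drift_exclude_pos` / `cfg$drift_exclude_neg`, capped at the number of
#' compounds available in that mode). Ties are broken by compound id order.
#'
#' @param m an `intensity_matrix`.
#' @param scores drift scores from [runorder_drift_scores()] (named by
#'   compound id).
#' @param cfg a [lipid_filter_config()].
#' @return list with the reduced `matrix` and a `report` data.frame.
#' @export
exclude_top_drift <- function(m, scores, cfg = lipid_filter_config()) {
  stopifnot(inherits(m, "intensity_matrix"))
  feat <- m$features
  scores <- scores[feat$compound_id]
  drop <- logical(nrow(feat))
  for (mode in c("positive", "negative")) {
    k <- if (mode == "positive") cfg$drift_exclude_pos else cfg$drift_exclude_neg
    in_mode <- which(feat$ion_mode == mode)
    k <- min(k, length(in_mode))
    if (k == 0) next
    ord <- in_mode[order(-scores[in_mode], feat$compound_id[in_mode])]
    drop[ord[seq_len(k)]] <- TRUE
  }
  report <- filter_report_row(feat$compound_id, "runorder_drift", scores, !drop)
  out <- if (any(drop)) im_subset(m, compounds = !drop) else m
  list(matrix = out, report = report)
}

#' Upper-quartile normalization and log2 transform
#'
#' Scales each sample so its 75th-percentile intensity equals the grand
#' (across-sample mean) 75th percentile, then log2-transforms.
#'
#' @param m a raw-scale `intensity_matrix`.
#' @return A log2-scale `intensity_matrix`.
#' @export
normalize_lipids <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"), m$scale == "raw")
  uq <- apply(m$values, 2, stats::quantile, probs = 0.75, na.rm = TRUE)
  if (any(uq <= 0)) stop("zero upper quartile in sample(s): ",
                         paste(colnames(m$values)[uq <= 0], collapse = ", "))
  target <- mean(uq)
  m$values <- log2(sweep(m$values, 2, target / uq, `*`))
  m$scale <- "log2"
  m
}

#' Preprocess a polar metabolite table
#'
#' Drops compounds detected in fewer than half of the samples (boundary: a
#' compound detected in exactly 50% is kept), fills remaining missing values
#' with the minimum of the matrix, log2-transforms, removes the extraction
#' batch effect by per-compound linear regression (residuals plus compound
#' mean), and quantile-normalizes across samples.
#'
#' @param raw a raw-scale metabolite `intensity_matrix` with `NA` for
#'   undetected values; batch labels come from its sample table.
#' @param detect_frac_min minimum detection fraction (default 0.5).
#' @return list with the log2 `matrix` and a `report` data.frame for the
#'   detection rule.
#' @export
preprocess_metabolites <- function(raw, detect_frac_min = 0.5) {
  stopifnot(inherits(raw, "intensity_matrix"), raw$scale == "raw")
  det_frac <- rowMeans(!is.na(raw$values))
  keep <- det_frac >= detect_frac_min
  report <- filter_report_row(raw$features$compound_id, "detection_50",
                              det_frac, keep)
  if (!any(keep)) stop("no metabolites remain after the detection filter")
  m <- im_subset(raw, compounds = keep)
  fill <- min(m$values, na.rm = TRUE)
  m$values[is.na(m$values)] <- fill
  v <- log2(m$values)

  batch <- m$samples$batch
  if (length(unique(batch)) > 1) {
    X <- stats::model.matrix(~ factor(batch))
    P <- X %*% solve(crossprod(X), t(X))   # hat matrix over samples
    v <- v - v %*% P + rowMeans(v)
  } else {
    message("single batch: batch regression is an identity step")
  }
  v <- as.matrix(limma::normalizeQuantiles(v, ties = TRUE))
  dimnames(v) <- dimnames(m$values)
  m$values <- v
  m$scale <- "log2"
  list(matrix = m, report = report)
}

#' PMI confounder filter
#'
#' Drops compounds whose abundance correlates with postmortem interval.
#' Spearman correlation and its two-sided p-value are computed over the older
#' dataset (`DS:5-71`) samples with non-missing PMI, since the strong age
#' effect would otherwise dominate.
#'
#' @param m a log2 `intensity_matrix`.
#' @param p_threshold p-value below which a compound is dropped
#'   (`0.01` strict, `0.1` relaxed).
#' @param min_n minimum number of usable adult samples.
#' @return list with the filtered `matrix` and a `report` data.frame carrying
#'   rho, p and n per compound.
#' @export
pmi_filter <- function(m, p_threshold = 0.01, min_n = 10) {
  stopifnot(inherits(m, "intensity_matrix"))
  st <- assign_dataset(m$samples)
  use <- st$dataset == "DS:5-71" & !is.na(st$pmi)
  if (sum(use) < min_n)
    stop("only ", sum(use), " adult samples with PMI; need >= ", min_n)
  pmi <- st$pmi[use]
  vals <- m$values[, use, drop = FALSE]
  rp <- rank(pmi)
  n <- length(pmi)
  ranks <- t(apply(vals, 1, rank))
  rho <- as.numeric(stats::cor(t(ranks), rp))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[abs(rho) >= 1] <- 0
  keep <- p >= p_threshold
  report <- filter_report_row(m$features$compound_id, "pmi_spearman", rho, keep)
  report$p <- p
  report$n <- n
  out <- if (all(keep)) m else im_subset(m, compounds = keep)
  list(matrix = out, report = report)
}

#' Restrict to well-preserved samples
#'
#' Keeps samples with RNA integrity number at or above `rin_min` (boundary
#' inclusive).
#'
#' @param m an `intensity_matrix`.
#' @param rin_min RIN threshold.
#' @return The subsetted `intensity_matrix`.
#' @export
rin_subset <- function(m, rin_min = 7) {
  stopifnot(inherits(m, "intensity_matrix"))
  keep <- !is.na(m$samples$rin) & m$samples$rin >= rin_min
  if (!any(keep)) stop("no samples with RIN >= ", rin_min)
  im_subset(m, samples = keep)
}

#' Full lipid preprocessing chain
#'
#' Convenience wrapper running [basic_lipid_filters()],
#' [runorder_drift_scores()], [exclude_top_drift()], [normalize_lipids()] and
#' [pmi_filter()] in the prescribed order.
#'
#' @param raw raw lipid `intensity_matrix` (one ionization mode).
#' @param cfg a [lipid_filter_config()].
#' @param pmi_p PMI p-value threshold.
#' @return list with the log2 `matrix`, the combined `report`, and the drift
#'   `scores`.
#' @export
preprocess_lipids <- function(raw, cfg = lipid_filter_config(), pmi_p = 0.01) {
  basic <- basic_lipid_filters(raw, cfg)
  scores <- runorder_drift_scores(basic$matrix, cfg)
  drift <- exclude_top_drift(basic$matrix, scores, cfg)
  normed <- normalize_lipids(drift$matrix)
  pmi <- pmi_filter(normed, p_threshold = pmi_p)
  report <- rbind(basic$report, drift$report,
                  pmi$report[, c("compound_id", "rule", "statistic", "decision")])
  list(matrix = pmi$matrix, report = report, drift_scores = scores)
}
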