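#' Retention-time alignment by anchor interpolation
#'
#' Maps retention times from a source chromatographic scale onto a target
#' scale by piecewise-linear interpolation through user-supplied anchor
#' pairs. Outside the anchor range, the terminal segments are extended
#' (linear extrapolation with the first/last segment slope). Anchors must be
#' strictly increasing in both coordinates, which makes the map monotone.
#'
#' @param rt numeric retention times (source scale, minutes).
#' @param anchors two-column matrix or data.frame: source and target
#'   retention times of the anchor points (at least 2 rows).
#' @return Aligned retention times on the target scale.
#' @export
align_rt <- function(rt, anchors) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2) stop("need at least 2 anchor points")
  if (any(diff(anchors[, 1]) <= 0) || any(diff(anchors[, 2]) <= 0))
    stop("anchors must be strictly increasing in both coordinates")
  src <- anchors[, 1]; tgt <- anchors[, 2]
  out <- stats::approx(src, tgt, xout = rt, rule = 1)$y
  k <- nrow(anchors)
  slope_lo <- (tgt[2] - tgt[1]) / (src[2] - src[1])
  slope_hi <- (tgt[k] - tgt[k - 1]) / (src[k] - src[k - 1])
  lo <- rt < src[1]; hi <- rt > src[k]
  out[lo] <- tgt[1] + slope_lo * (rt[lo] - src[1])
  out[hi] <- tgt[k] + slope_hi * (rt[hi] - src[k])
  out
}

#' Match lipid features across datasets
#'
#' Pairs source and target features of the same ionization mode whose m/z
#' agree within `ppm_tol` and whose (aligned) retention times agree within
#' `rt_tol_sec`. Any source or target feature participating in more than one
#' candidate pair is removed entirely, so the result is strictly one-to-one.
#'
#' @param source,target data.frames with `compound_id`, `mz`, `rt` (minutes;
#'   the source retention times should already be aligned to the target
#'   scale, see [align_rt()]) and optionally `ion_mode`.
#' @param ppm_tol relative mass tolerance, parts per million.
#' @param rt_tol_sec retention-time tolerance in seconds.
#' @return data.frame of `source_id`, `target_id`, `ppm_error`,
#'   `rt_error_sec`.
#' @export
match_lipids <- function(source, target, ppm_tol = 5, rt_tol_sec = 6) {
  stopifnot(ppm_tol > 0, rt_tol_sec > 0)
  if (is.null(source$ion_mode)) source$ion_mode <- "any"
  if (is.null(target$ion_mode)) target$ion_mode <- "any"
  cand <- list()
  for (i in seq_len(nrow(source))) {
    dmz_ppm <- abs(target$mz - source$mz[i]) / source$mz[i] * 1e6
    drt_sec <- abs(target$rt - source$rt[i]) * 60
    hit <- which(dmz_ppm <= ppm_tol & drt_sec <= rt_tol_sec &
                   target$ion_mode == source$ion_mode[i])
    if (length(hit) > 0)
      cand[[length(cand) + 1]] <- data.frame(
        source_id = source$compound_id[i], target_id = target$compound_id[hit],
        ppm_error = dmz_ppm[hit], rt_error_sec = drt_sec[hit],
        stringsAsFactors = FALSE)
  }
  if (length(cand) == 0)
    return(data.frame(source_id = character(0), target_id = character(0),
                      ppm_error = numeric(0), rt_error_sec = numeric(0)))
  cand <- do.call(rbind, cand)
  dup_src <- cand$source_id[duplicated(cand$source_id)]
  dup_tgt <- cand$target_id[duplicated(cand$target_id)]
  keep <- !(cand$source_id %in% dup_src) & !(cand$target_id %in% dup_tgt)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold-change consistency between datasets
#'
#' For each matched compound, the HC fold change within one dataset is the
#' mean log2 intensity of HC samples minus the mean over the pooled WE and
#' AA samples. The consistency statistic is the Spearman correlation of
#' these fold-change vectors between the two datasets.
#'
#' @param m_current,m_published log2 `intensity_matrix` objects.
#' @param matches data.frame from [match_lipids()] (`source_id` referring to
#'   `m_current`, `target_id` to `m_published`).
#' @param compound_ids compound ids (current-dataset ids) to use, e.g. the
#'   HC-specific set; only those present among the matches are used.
#' @param min_n minimum number of usable matched compounds.
#' @return list with `rho`, `p`, `n`, and the per-compound fold changes.
#' @export
foldchange_consistency <- function(m_current, m_published, matches,
                                   compound_ids, min_n = 5) {
  use <- matches[matches$source_id %in% compound_ids, , drop = FALSE]
  if (nrow(use) < min_n)
    stop("only ", nrow(use), " matched compounds available; need >= ", min_n)
  fc <- function(m, ids) {
    hc <- m$samples$population == "HC"
    rowMeans(m$values[ids, hc, drop = FALSE]) -
      rowMeans(m$values[ids, !hc, drop = FALSE])
  }
  fc_cur <- fc(m_current, use$source_id)
  fc_pub <- fc(m_published, use$target_id)
  ct <- spearman_test(fc_cur, fc_pub)
  list(rho = ct$rho, p = ct$p, n = nrow(use),
       fold_changes = data.frame(source_id = use$source_id,
                                 target_id = use$target_id,
                                 fc_current = fc_cur, fc_published = fc_pub,
                                 stringsAsFactors = FALSE))
}

#' Averaged centering/scaling parameters for cross-experiment normalization
#'
#' Draws `n_per_pop` samples per population `n_iter` times and averages the
#' per-compound means and standard deviations over draws, giving
#' population-balanced normalization parameters that do not depend on the
#' cohort's population imbalance.
#'
#' @param m a log2 `intensity_matrix`.
#' @param n_per_pop samples per population per draw.
#' @param n_iter number of draws.
#' @param seed integer seed.
#' @return list with `center` and `scale`, named by compound.
#' @export
averaged_scaling <- function(m, n_per_pop = 31, n_iter = 1000, seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"))
  idx_by_pop <- lapply(POPULATIONS, function(p) which(m$samples$population == p))
  if (any(lengths(idx_by_pop) < n_per_pop))
    stop("need at least ", n_per_pop, " samples per population")
  set.seed(seed)
  ctr <- 0; scl <- 0
  for (it in seq_len(n_iter)) {
    take <- unlist(lapply(idx_by_pop, sample, size = n_per_pop))
    sub <- m$values[, take, drop = FALSE]
    ctr <- ctr + rowMeans(sub)
    scl <- scl + apply(sub, 1, stats::sd)
  }
  list(center = ctr / n_iter, scale = scl / n_iter)
}

#' External validation of the population classifier
#'
#' Normalizes the current dataset with population-balanced averaged
#' centering/scaling parameters (see [averaged_scaling()]) and the published
#' dataset with its own per-compound mean and standard deviation, runs
#' stability selection restricted to the matched compounds, and, for each
#' predictor count `k` in `top_k_grid`, fits an HC-vs-rest lasso logistic
#' model (fixed `C`) on the full current dataset using the top-`k` matched
#' compounds and scores the published samples.
#'
#' @param m_current,m_published log2 `intensity_matrix` objects.
#' @param matches data.frame from [match_lipids()].
#' @param cfg a [classifier_config()]; `cfg$n_stab` stability iterations are
#'   used for the ranking and `cfg$C_final` for the models.
#' @param top_k_grid predictor counts to evaluate (values beyond the number
#'   of matched compounds are truncated with a warning).
#' @param norm_iter draws used for the averaged scaling.
#' @return list with `auc` (data.frame `k`, `auc`), `ranking` (the matched
#'   stability ranking), `best_k`, `best_auc`.
#' @export
external_validation <- function(m_current, m_published, matches,
                                cfg = classifier_config(),
                                top_k_grid = c(1, 2, 5, 10, 22, 50),
                                norm_iter = 1000) {
  matched_src <- intersect(matches$source_id, m_current$features$compound_id)
  if (length(matched_src) < 2) stop("need at least 2 matched compounds")
  matches <- matches[matches$source_id %in% matched_src, , drop = FALSE]
  over <- top_k_grid > length(matched_src)
  if (any(over)) {
    warning("top_k_grid values beyond ", length(matched_src),
            " matched compounds truncated")
    top_k_grid <- unique(pmin(top_k_grid, length(matched_src)))
  }
  ranking <- stability_selection(m_current, focal = "HC", cfg = cfg,
                                 compounds = matched_src)
  ranked_ids <- names(ranking$counts)
  norm <- averaged_scaling(im_subset(m_current,
                                     compounds = m_current$features$compound_id %in% matched_src),
                           n_per_pop = cfg$n_per_pop, n_iter = norm_iter,
                           seed = cfg$seed + 13L)
  cur <- im_subset(m_current, compounds = m_current$features$compound_id %in% matched_src)
  x_cur <- sweep(sweep(t(cur$values), 2, norm$center[colnames(t(cur$values))]),
                 2, norm$scale[colnames(t(cur$values))], `/`)
  y_cur <- as.numeric(cur$samples$population == "HC")

  tgt_of <- stats::setNames(matches$target_id, matches$source_id)
  pub_vals <- t(m_published$values)
  pub_center <- colMeans(pub_vals)
  pub_scale <- apply(pub_vals, 2, stats::sd); pub_scale[pub_scale == 0] <- 1
  pub_x_all <- sweep(sweep(pub_vals, 2, pub_center), 2, pub_scale, `/`)
  pub_pos <- m_published$samples$population == "HC"

  aucs <- vapply(top_k_grid, function(k) {
    ids <- ranked_ids[seq_len(k)]
    model <- lasso_logistic(x_cur[, ids, drop = FALSE], y_cur, C = cfg$C_final)
    sc <- lasso_scores(model, pub_x_all[, tgt_of[ids], drop = FALSE])
    roc_auc(sc, pub_pos)
  }, numeric(1))
  best <- which.max(aucs)
  list(auc = data.frame(k = top_k_grid, auc = aucs), ranking = ranking,
       best_k = top_k_grid[best], best_auc = aucs[best])
}
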