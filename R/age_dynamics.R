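#' Configuration for age-unbiased compound selection
#'
#' @param n_per_pop samples drawn per population within each age group.
#' @param n_iter subsampling iterations per population pair and age group.
#' @param p_threshold nominal (uncorrected) p-value threshold for counting an
#'   occurrence.
#' @param top_k compounds retained per direction (positive/negative
#'   difference) per pair and age group: 25 for lipids, 10 for metabolites in
#'   the default study layout.
#' @param seed integer seed.
#' @return An `age_unbiased_config` list.
#' @export
age_unbiased_config <- function(n_per_pop = 4, n_iter = 1000,
                                p_threshold = 0.1, top_k = 25, seed = 1L) {
  stopifnot(n_per_pop >= 2, n_iter >= 1, p_threshold > 0, p_threshold < 1)
  structure(list(n_per_pop = n_per_pop, n_iter = n_iter,
                 p_threshold = p_threshold, top_k = top_k,
                 seed = as.integer(seed)),
            class = "age_unbiased_config")
}

POP_PAIRS <- list(c("HC", "WE"), c("HC", "AA"), c("WE", "AA"))

group_pop_index <- function(samples, scheme) {
  if (is.null(samples$age_group)) samples <- assign_age_group(samples, scheme)
  idx <- list()
  for (g in scheme$labels)
    for (p in POPULATIONS)
      idx[[paste(g, p)]] <- which(samples$age_group == g & samples$population == p)
  idx
}

#' Age-unbiased population-distinguishing compounds
#'
#' For each population pair and age group, draws `n_per_pop` samples per
#' population `n_iter` times, Welch-tests every compound between the two
#' subsampled populations, and counts, separately, iterations with a
#' positive and a negative difference at nominal `p < p_threshold`. The
#' `top_k` compounds per direction (ranked by occurrence count; ties broken
#' by larger mean absolute difference, then compound id) are collected, and
#' the union over all pairs, groups and directions is returned. Because every
#' group contributes the same subsample size, the resulting set is not biased
#' toward well-sampled ages.
#'
#' @param m a log2 `intensity_matrix`.
#' @param scheme an [age_group_scheme()].
#' @param cfg an [age_unbiased_config()].
#' @return Character vector of compound ids (the age-unbiased set).
#' @export
age_unbiased_compounds <- function(m, scheme = age_group_scheme(),
                                   cfg = age_unbiased_config()) {
  stopifnot(inherits(m, "intensity_matrix"))
  idx <- group_pop_index(m$samples, scheme)
  short <- names(idx)[lengths(idx) < cfg$n_per_pop]
  if (length(short) > 0)
    stop("fewer than ", cfg$n_per_pop, " samples in group/population: ",
         paste(short, collapse = "; "))
  set.seed(cfg$seed)
  ids <- m$features$compound_id
  n_comp <- length(ids)
  selected <- character(0)
  for (g in scheme$labels) {
    for (pair in POP_PAIRS) {
      pos_count <- integer(n_comp)
      neg_count <- integer(n_comp)
      delta_sum <- numeric(n_comp)
      ii1 <- idx[[paste(g, pair[1])]]
      ii2 <- idx[[paste(g, pair[2])]]
      for (it in seq_len(cfg$n_iter)) {
        s1 <- sample(ii1, cfg$n_per_pop)
        s2 <- sample(ii2, cfg$n_per_pop)
        res <- row_welch(m$values, s1, s2)
        hit <- res$p < cfg$p_threshold
        pos_count <- pos_count + (hit & res$delta > 0)
        neg_count <- neg_count + (hit & res$delta < 0)
        delta_sum <- delta_sum + res$delta
      }
      mean_abs <- abs(delta_sum / cfg$n_iter)
      for (cnt in list(pos_count, neg_count)) {
        ord <- order(-cnt, -mean_abs, ids)
        take <- ord[seq_len(min(cfg$top_k, sum(cnt > 0)))]
        selected <- c(selected, ids[take])
      }
    }
  }
  sort(unique(selected))
}

#' Age-resolved correlation-distance profile
#'
#' Within each age group and iteration, draws `n_per_pop` samples per
#' population, averages the abundance of the supplied compound set within
#' each population, and computes pairwise Spearman correlations between the
#' population mean vectors. The divergence measure is `1 - rho` (0 for
#' identical rankings, 2 for perfectly anti-ranked vectors); the median and
#' quartiles over iterations are reported per age group and population pair.
#' Iterations producing a constant mean vector (undefined correlation) are
#' redrawn and counted.
#'
#' @param m a log2 `intensity_matrix`.
#' @param compound_ids compound set to profile (non-empty).
#' @param scheme an [age_group_scheme()].
#' @param n_iter subsampling iterations per age group.
#' @param n_per_pop samples per population per draw.
#' @param seed integer seed.
#' @return A `distance_profile` data.frame: `age_group`, `pair`, `median`,
#'   `q25`, `q75`; the number of redrawn iterations is an attribute.
#' @export
correlation_distance_profile <- function(m, compound_ids,
                                         scheme = age_group_scheme(),
                                         n_iter = 10000, n_per_pop = 4,
                                         seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"), length(compound_ids) > 0)
  missing_ids <- setdiff(compound_ids, m$features$compound_id)
  if (length(missing_ids) > 0)
    stop("compound id(s) not in matrix: ", paste(utils::head(missing_ids, 5), collapse = ", "))
  vals <- m$values[compound_ids, , drop = FALSE]
  idx <- group_pop_index(m$samples, scheme)
  short <- names(idx)[lengths(idx) < n_per_pop]
  if (length(short) > 0)
    stop("fewer than ", n_per_pop, " samples in group/population: ",
         paste(short, collapse = "; "))
  set.seed(seed)
  pair_names <- vapply(POP_PAIRS, paste, collapse = "-", FUN.VALUE = character(1))
  out <- list()
  redraws <- 0L
  for (g in scheme$labels) {
    d <- matrix(NA_real_, n_iter, length(POP_PAIRS),
                dimnames = list(NULL, pair_names))
    it <- 1L
    while (it <= n_iter) {
      means <- vapply(POPULATIONS, function(p) {
        rowMeans(vals[, sample(idx[[paste(g, p)]], n_per_pop), drop = FALSE])
      }, numeric(nrow(vals)))
      if (any(apply(means, 2, stats::sd) == 0)) {
        redraws <- redraws + 1L
        if (redraws > 100 * n_iter)
          stop("too many degenerate subsamples (constant mean vectors) in ", g)
        next
      }
      rho <- stats::cor(apply(means, 2, rank))
      for (k in seq_along(POP_PAIRS))
        d[it, k] <- 1 - rho[POP_PAIRS[[k]][1], POP_PAIRS[[k]][2]]
      it <- it + 1L
    }
    qs <- apply(d, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
    out[[g]] <- data.frame(age_group = g, pair = pair_names,
                           median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_redrawn") <- redraws
  class(res) <- c("distance_profile", class(res))
  res
}

#' Age-resolved classification accuracy
#'
#' Repeatedly holds out all infant samples (age groups A1-A2) plus one sample
#' from each adult age group (A3-A6), runs stability selection on the
#' remaining samples, fits one-vs-rest lasso logistic models on the
#' top-ranked compounds, and predicts the population of every held-out
#' sample as the class whose model scores highest. Held-out adult samples
#' rotate through random permutations of each group so every sample is
#' predicted at least once. Per-sample mean accuracy and an age-sorted
#' sliding-window median accuracy curve summarize how separability changes
#' with age.
#'
#' Stability selection runs once per focal population; each one-vs-rest model
#' is fit on the union of the per-focal top-`top_k_predictors` sets.
#'
#' @param m a log2 `intensity_matrix` covering all six age groups.
#' @param scheme an [age_group_scheme()].
#' @param cfg a [classifier_config()]; `cfg$n_stab` controls the inner
#'   stability-selection iterations and `cfg$n_per_pop` its subsample size.
#' @param top_k_predictors compounds per focal model (default 100).
#' @param window sliding-window width in samples.
#' @param seed integer seed.
#' @return list with `per_sample` (sample_id, age, population, n_predictions,
#'   accuracy) and `window_curve` (age-sorted data.frame of window median
#'   age and accuracy, `n - window + 1` rows).
#' @export
agewise_classification_accuracy <- function(m, scheme = age_group_scheme(),
                                            cfg = classifier_config(n_stab = 50),
                                            top_k_predictors = 100,
                                            window = 10, seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"))
  st <- assign_age_group(assign_dataset(m$samples), scheme)
  if (window > nrow(st)) stop("window wider than the number of samples")
  infant <- which(st$age_group %in% c("A1", "A2"))
  adult_groups <- setdiff(scheme$labels, c("A1", "A2"))
  group_idx <- lapply(adult_groups, function(g) which(st$age_group == g))
  names(group_idx) <- adult_groups
  if (any(lengths(group_idx) == 0)) stop("empty adult age group")
  set.seed(seed)
  rotations <- lapply(group_idx, function(ii) ii[sample.int(length(ii))])
  n_outer <- max(lengths(group_idx))
  correct <- stats::setNames(numeric(nrow(st)), st$sample_id)
  n_pred <- stats::setNames(integer(nrow(st)), st$sample_id)
  iter_seeds <- derive_seeds(seed, n_outer, salt = 97L)
  for (it in seq_len(n_outer)) {
    held <- c(infant, vapply(rotations, function(ii) ii[(it - 1L) %% length(ii) + 1L],
                             integer(1)))
    train_m <- im_subset(m, samples = -held)
    preds <- character(0)
    predictor_union <- character(0)
    models <- list()
    for (p in POPULATIONS) {
      rk <- stability_selection(train_m, focal = p,
                                cfg = classifier_config(
                                  n_per_pop = cfg$n_per_pop,
                                  train_frac = cfg$train_frac,
                                  C_final = cfg$C_final,
                                  n_stab = cfg$n_stab,
                                  top_k = top_k_predictors,
                                  coef_tol = cfg$coef_tol,
                                  seed = iter_seeds[it]))
      predictor_union <- union(predictor_union, rk$top_k)
    }
    tr <- im_subset(train_m, compounds = train_m$features$compound_id %in% predictor_union)
    x_tr <- t(tr$values)
    ctr <- colMeans(x_tr); scl <- apply(x_tr, 2, stats::sd); scl[scl == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2, ctr), 2, scl, `/`)
    x_te <- t(m$values[tr$features$compound_id, held, drop = FALSE])
    x_te <- sweep(sweep(x_te, 2, ctr), 2, scl, `/`)
    score <- vapply(POPULATIONS, function(p) {
      model <- lasso_logistic(x_tr, as.numeric(tr$samples$population == p),
                              C = cfg$C_final)
      lasso_scores(model, x_te)
    }, numeric(length(held)))
    pred_pop <- POPULATIONS[max.col(score, ties.method = "first")]
    hit <- pred_pop == st$population[held]
    correct[held] <- correct[held] + hit
    n_pred[held] <- n_pred[held] + 1L
  }
  per_sample <- data.frame(sample_id = st$sample_id, age = st$age,
                           population = st$population,
                           n_predictions = n_pred,
                           accuracy = ifelse(n_pred > 0, correct / n_pred, NA),
                           stringsAsFactors = FALSE)
  ord <- order(per_sample$age)
  acc <- per_sample$accuracy[ord]
  ages <- per_sample$age[ord]
  nw <- length(acc) - window + 1
  curve <- data.frame(
    age = vapply(seq_len(nw), function(i) stats::median(ages[i:(i + window - 1)]), numeric(1)),
    accuracy = vapply(seq_len(nw), function(i) stats::median(acc[i:(i + window - 1)], na.rm = TRUE), numeric(1))
  )
  list(per_sample = per_sample, window_curve = curve)
}
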