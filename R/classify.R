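#' Classifier configuration
#'
#' Settings for the one-vs-rest lasso logistic regression analysis. `C` is
#' the inverse regularization strength (larger C = weaker penalty); the
#' lasso penalty is `(1/C) * |beta|_1` on the summed deviance scale.
#'
#' @param n_per_pop samples drawn per population before the train/test split.
#' @param train_frac fraction of drawn samples assigned to training.
#' @param C_grid inverse-regularization grid for the AUC curve.
#' @param C_final fixed C used for stability selection and final models.
#' @param n_repeats resampled splits per point of the AUC curve.
#' @param n_stab stability-selection iterations.
#' @param top_k predictors retained from the stability ranking (200 for
#'   lipids, 50 for metabolites in the default study layout).
#' @param coef_tol absolute coefficient threshold above which a compound
#'   counts as selected.
#' @param seed integer seed.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_per_pop = 31, train_frac = 2 / 3,
                              C_grid = c(0.01, 0.1, 1, 10, 100, 500, 1000,
                                         2500, 5000, 10000),
                              C_final = 1000, n_repeats = 100,
                              n_stab = 10000, top_k = 200,
                              coef_tol = 1e-8, seed = 1L) {
  stopifnot(all(C_grid > 0), C_final > 0, train_frac > 0, train_frac < 1)
  structure(list(n_per_pop = n_per_pop, train_frac = train_frac,
                 C_grid = C_grid, C_final = C_final, n_repeats = n_repeats,
                 n_stab = n_stab, top_k = top_k, coef_tol = coef_tol,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Draw, split and standardize samples for classification
#'
#' Draws `n_per_pop` samples per population, splits them into train and test
#' stratified by population (train share `train_frac`), and standardizes
#' every compound using the training-set mean and standard deviation only —
#' the test set is transformed with the train-derived parameters, so no
#' information leaks from test to train.
#'
#' @param m a log2 `intensity_matrix`.
#' @param cfg a [classifier_config()].
#' @param seed seed for this particular draw (defaults to `cfg$seed`).
#' @return list with `train_x`, `test_x` (samples x compounds, standardized),
#'   `train_pop`, `test_pop` (population labels), `center`, `scale`.
#' @export
split_and_scale <- function(m, cfg = classifier_config(), seed = cfg$seed) {
  stopifnot(inherits(m, "intensity_matrix"))
  st <- m$samples
  set.seed(seed)
  idx_by_pop <- lapply(POPULATIONS, function(p) which(st$population == p))
  names(idx_by_pop) <- POPULATIONS
  if (any(lengths(idx_by_pop) < cfg$n_per_pop))
    stop("need at least ", cfg$n_per_pop, " samples per population")
  drawn <- lapply(idx_by_pop, function(ii) sample(ii, cfg$n_per_pop))
  # largest-remainder allocation of the train quota across populations keeps
  # the split stratified while hitting the global train count exactly
  n_train_total <- round(cfg$train_frac * cfg$n_per_pop * length(drawn))
  quota <- rep(cfg$train_frac * cfg$n_per_pop, length(drawn))
  base <- floor(quota)
  rem <- n_train_total - sum(base)
  train_idx <- integer(0); test_idx <- integer(0)
  extra <- if (rem > 0) sample.int(length(drawn), rem) else integer(0)
  for (i in seq_along(drawn)) {
    k <- base[i] + (i %in% extra)
    tr <- sample(drawn[[i]], k)
    train_idx <- c(train_idx, tr)
    test_idx <- c(test_idx, setdiff(drawn[[i]], tr))
  }
  x <- t(m$values)
  train_x <- x[train_idx, , drop = FALSE]
  test_x <- x[test_idx, , drop = FALSE]
  center <- colMeans(train_x)
  scale <- apply(train_x, 2, stats::sd)
  zero_sd <- scale == 0
  if (any(zero_sd)) {
    warning(sum(zero_sd), " compound(s) constant in the training set; scale set to 1")
    scale[zero_sd] <- 1
  }
  train_x <- sweep(sweep(train_x, 2, center), 2, scale, `/`)
  test_x <- sweep(sweep(test_x, 2, center), 2, scale, `/`)
  list(train_x = train_x, test_x = test_x,
       train_pop = st$population[train_idx], test_pop = st$population[test_idx],
       center = center, scale = scale)
}

#' One-vs-rest AUC across the regularization grid
#'
#' For each C in the grid and each of `n_repeats` resampled splits, fits an
#' L1-penalized logistic regression separating the focal population from the
#' other two combined on the training set, and evaluates the ROC AUC of the
#' predicted scores on the held-out test set.
#'
#' @param m a log2 `intensity_matrix`.
#' @param focal focal population (`"HC"`, `"WE"` or `"AA"`).
#' @param cfg a [classifier_config()].
#' @return data.frame with `C`, `mean_auc`, `sd_auc`.
#' @export
ovr_auc_curve <- function(m, focal = "HC", cfg = classifier_config()) {
  stopifnot(focal %in% POPULATIONS)
  seeds <- derive_seeds(cfg$seed, cfg$n_repeats, salt = 7L)
  aucs <- matrix(NA_real_, cfg$n_repeats, length(cfg$C_grid))
  for (r in seq_len(cfg$n_repeats)) {
    sp <- split_and_scale(m, cfg, seed = seeds[r])
    y <- as.numeric(sp$train_pop == focal)
    n <- nrow(sp$train_x)
    lambdas <- sort(1 / (n * cfg$C_grid), decreasing = TRUE)
    fit <- glmnet::glmnet(sp$train_x, y, family = "binomial", alpha = 1,
                          lambda = unique(c(max(lambdas) * c(100, 10), lambdas)),
                          standardize = FALSE, maxit = 5e5)
    test_pos <- sp$test_pop == focal
    for (ci in seq_along(cfg$C_grid)) {
      sc <- as.numeric(stats::predict(fit, newx = sp$test_x,
                                      s = 1 / (n * cfg$C_grid[ci]),
                                      type = "link"))
      aucs[r, ci] <- roc_auc(sc, test_pos)
    }
  }
  data.frame(C = cfg$C_grid, mean_auc = colMeans(aucs),
             sd_auc = apply(aucs, 2, stats::sd))
}

#' Stability selection of population predictors
#'
#' Repeats the draw/split/standardize/fit cycle `n_stab` times at the fixed
#' `C_final`; in each iteration the compounds with a nonzero lasso
#' coefficient (absolute value above `coef_tol`) count as selected. Compounds
#' are ranked by how often they were selected (ties broken by compound id),
#' and the `top_k` highest-ranked form the predictor set.
#'
#' @param m a log2 `intensity_matrix`.
#' @param focal focal population.
#' @param cfg a [classifier_config()].
#' @param compounds optional character vector restricting the procedure to a
#'   subset of compounds (used for cross-dataset validation).
#' @return A `stability_ranking`: list with `counts` (named, full ranking
#'   order), `top_k` ids, `n_stab`.
#' @export
stability_selection <- function(m, focal = "HC", cfg = classifier_config(),
                                compounds = NULL) {
  stopifnot(focal %in% POPULATIONS)
  if (!is.null(compounds))
    m <- im_subset(m, compounds = m$features$compound_id %in% compounds)
  seeds <- derive_seeds(cfg$seed, cfg$n_stab, salt = 31L)
  ids <- m$features$compound_id
  counts <- stats::setNames(integer(length(ids)), ids)
  for (r in seq_len(cfg$n_stab)) {
    sp <- split_and_scale(m, cfg, seed = seeds[r])
    y <- as.numeric(sp$train_pop == focal)
    model <- lasso_logistic(sp$train_x, y, C = cfg$C_final)
    beta <- lasso_coefs(model)
    counts <- counts + (abs(beta) > cfg$coef_tol)
  }
  ord <- order(-counts, ids)
  counts <- counts[ord]
  k <- min(cfg$top_k, sum(counts > 0))
  structure(list(counts = counts, top_k = names(counts)[seq_len(k)],
                 n_stab = cfg$n_stab, focal = focal),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("<stability_ranking> focal", x$focal, "-", x$n_stab, "iterations;",
      length(x$top_k), "predictors retained\n")
  invisible(x)
}
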