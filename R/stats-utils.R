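#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test for a difference in means, vectorized over the rows
#' of a matrix. Degrees of freedom follow the Welch-Satterthwaite
#' approximation. When both groups have zero variance and equal means the
#' p-value is defined as 1 (no evidence of difference).
#'
#' @param x,y numeric vectors, one group each (at least 2 values per group).
#' @return `welch_t_pvalue()`: list with `t`, `df`, `p`.
#' @export
welch_t_pvalue <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  res <- row_welch(matrix(c(x, y), nrow = 1),
                   seq_along(x), length(x) + seq_along(y))
  list(t = res$t[1], df = res$df[1], p = res$p[1])
}

#' @rdname welch_t_pvalue
#' @param values numeric matrix (features in rows).
#' @param idx1,idx2 column indices of the two groups.
#' @return `row_welch()`: list of vectors `t`, `df`, `p`, `delta` (mean of
#'   group 1 minus mean of group 2), one element per row.
#' @export
row_welch <- function(values, idx1, idx2) {
  x <- values[, idx1, drop = FALSE]
  y <- values[, idx2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    # zero variance in both groups: identical means carry no evidence
    tt[degenerate & (m1 == m2)] <- 0
    p[degenerate & (m1 == m2)] <- 1
    tt[degenerate & (m1 != m2)] <- sign(m1 - m2)[degenerate & (m1 != m2)] * Inf
    p[degenerate & (m1 != m2)] <- 0
    df[degenerate] <- n1 + n2 - 2
  }
  list(t = tt, df = df, p = p, delta = m1 - m2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; a thin wrapper over
#' [stats::p.adjust()] kept as the pipeline's single multiple-testing entry
#' point.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' ROC AUC from scores via the rank statistic
#'
#' Computes the area under the ROC curve as the Mann-Whitney probability that
#' a positive-class score exceeds a negative-class score, with ties counted
#' as 1/2 (midranks). Invariant under monotone transformations of the scores.
#'
#' @param scores numeric predicted scores, larger = more positive.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman correlation with a two-sided p-value
#'
#' Midranks for ties, p-value from the t approximation on
#' `r * sqrt((n-2)/(1-r^2))`. Pairs with a missing value in either vector are
#' dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

# L1-penalized logistic regression at sklearn-style inverse regularization
# strength C. glmnet minimizes (1/n)*deviance/2 + lambda*|beta|_1 while the
# C-parameterization minimizes sum-deviance/2 + (1/C)*|beta|_1, so
# lambda = 1 / (n * C). The fit descends a log-spaced warm-start path from
# the all-zero lambda down to the target, the canonical way to reach an
# accurate lasso solution at weak regularization.
lasso_logistic <- function(x, y, C = 1000, lambda_extra = NULL) {
  n <- nrow(x)
  lam <- 1 / (n * C)
  if (ncol(x) < 2) {
    # single predictor: the penalty is negligible at these C values
    fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                           family = stats::binomial()))
    return(list(glm_coef = fit$coefficients, lambda = lam))
  }
  lam_max <- max(max(abs(crossprod(x, y - mean(y)))) / n, lam * 2)
  path <- exp(seq(log(lam_max), log(lam), length.out = 25))
  path <- sort(unique(c(path, lambda_extra)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = path,
                        standardize = FALSE, maxit = 5e5)
  list(fit = fit, lambda = lam)
}

lasso_coefs <- function(model) {
  if (!is.null(model$glm_coef)) return(unname(model$glm_coef[-1]))
  beta <- stats::coef(model$fit, s = model$lambda)
  as.numeric(beta)[-1]  # drop intercept
}

lasso_scores <- function(model, newx) {
  if (!is.null(model$glm_coef))
    return(as.numeric(cbind(1, newx) %*% model$glm_coef))
  as.numeric(stats::predict(model$fit, newx = newx, s = model$lambda,
                            type = "link"))
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + salt + 1000003L * seq_len(n)) %% 2000000011L
}
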