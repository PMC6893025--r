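#' Variance explained by sample covariates
#'
#' Per-compound sequential (type-I) analysis of variance over the stated
#' factor order, aggregated across compounds as
#' `sum_compounds SS_factor / sum_compounds SS_total`. Age enters as a
#' natural cubic spline (3 df) by default, since abundance trajectories are
#' strongly non-linear in infancy; populations, sex and batch enter as
#' factors, RIN and PMI as numeric covariates. Samples with a missing value
#' in any included factor are excluded; sequential sums of squares are
#' order-dependent, so the order used is recorded in the result.
#'
#' @param m a log2 `intensity_matrix`.
#' @param factors character vector of covariates in the order they should
#'   enter the model; any of `"age"`, `"population"`, `"sex"`, `"rin"`,
#'   `"pmi"`, `"batch"`.
#' @param age_model `"spline"` (natural cubic, 3 df) or `"linear"`.
#' @return A `variance_partition`: data.frame of `factor` and `fraction`
#'   (including `residual`), with the factor order and number of samples/
#'   compounds as attributes. Fractions sum to 1.
#' @export
variance_explained <- function(m,
                               factors = c("age", "population", "sex", "rin", "pmi"),
                               age_model = c("spline", "linear")) {
  stopifnot(inherits(m, "intensity_matrix"))
  age_model <- match.arg(age_model)
  st <- as.data.frame(m$samples)
  known <- c("age", "population", "sex", "rin", "pmi", "batch")
  bad <- setdiff(factors, known)
  if (length(bad) > 0) stop("unknown factor(s): ", paste(bad, collapse = ", "))

  cols <- lapply(factors, function(f) st[[f]])
  complete <- Reduce(`&`, lapply(cols, function(x) !is.na(x)))
  if (sum(complete) < length(factors) + 2)
    stop("too few samples with complete covariates")
  st <- st[complete, , drop = FALSE]
  Y <- m$values[, complete, drop = FALSE]
  n <- nrow(st)

  block_matrix <- function(f) {
    x <- st[[f]]
    if (f == "age") {
      if (age_model == "spline") splines::ns(x, df = 3) else matrix(x, ncol = 1)
    } else if (f %in% c("rin", "pmi")) {
      matrix(x, ncol = 1)
    } else {
      x <- factor(x)
      if (nlevels(x) < 2) {
        warning("factor '", f, "' is constant; zero sum of squares")
        return(matrix(numeric(0), nrow = n, ncol = 0))
      }
      stats::model.matrix(~x)[, -1, drop = FALSE]
    }
  }

  # sequential orthogonalization: each factor's SS is the squared projection
  # of the (row-centered) data onto the part of its design block orthogonal
  # to everything entered before it
  Q <- matrix(1 / sqrt(n), nrow = n, ncol = 1)
  Yc <- Y - rowMeans(Y)
  ss_total <- sum(Yc^2)
  fractions <- numeric(length(factors))
  for (i in seq_along(factors)) {
    X <- block_matrix(factors[i])
    if (ncol(X) == 0) { fractions[i] <- 0; next }
    R <- X - Q %*% crossprod(Q, X)
    qr_r <- qr(R)
    rank <- qr_r$rank
    if (rank == 0) { fractions[i] <- 0; next }
    Qi <- qr.Q(qr_r)[, seq_len(rank), drop = FALSE]
    fractions[i] <- sum((Y %*% Qi)^2) / ss_total
    Q <- cbind(Q, Qi)
  }
  out <- data.frame(factor = c(factors, "residual"),
                    fraction = c(fractions, 1 - sum(fractions)),
                    stringsAsFactors = FALSE)
  attr(out, "order") <- factors
  attr(out, "n_samples") <- n
  attr(out, "n_compounds") <- nrow(Y)
  class(out) <- c("variance_partition", class(out))
  out
}
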