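#' Equal-n subsampling design for population specificity
#'
#' @param n_per_pop samples drawn per population in each iteration (13 for
#'   the infant dataset, 25 for the older dataset in the default study
#'   layout).
#' @param n_iter number of subsampling iterations.
#' @param alpha significance threshold on BH-adjusted p-values.
#' @param seed integer seed.
#' @return A `subsampling_design` list.
#' @export
subsampling_design <- function(n_per_pop = 25, n_iter = 100, alpha = 0.05,
                               seed = 1L) {
  stopifnot(n_per_pop >= 2, n_iter >= 1, alpha > 0, alpha < 1)
  structure(list(n_per_pop = n_per_pop, n_iter = n_iter, alpha = alpha,
                 seed = as.integer(seed)),
            class = "subsampling_design")
}

#' Subsampled one-vs-rest population specificity
#'
#' In each iteration, draws `n_per_pop` samples per population without
#' replacement; for each focal population, Welch-tests every compound between
#' the focal samples and the two other populations combined; applies
#' Benjamini-Hochberg correction across compounds within the iteration; and
#' counts compounds with adjusted p below `alpha`. Equalizing the group sizes
#' removes the statistical-power imbalance among populations.
#'
#' @param m a log2 `intensity_matrix`.
#' @param design a [subsampling_design()]; `n_per_pop` must not exceed the
#'   smallest population.
#' @return A `subsampling_result`: list with `counts` (iterations x
#'   populations matrix of significant-compound counts), `frequency`
#'   (per-compound, per-population fraction of iterations significant),
#'   `median_counts` and `mean_counts`.
#' @export
subsampled_specificity <- function(m, design = subsampling_design()) {
  stopifnot(inherits(m, "intensity_matrix"))
  st <- m$samples
  pops <- POPULATIONS
  idx_by_pop <- lapply(pops, function(p) which(st$population == p))
  names(idx_by_pop) <- pops
  sizes <- lengths(idx_by_pop)
  if (any(sizes < design$n_per_pop))
    stop("population(s) smaller than n_per_pop = ", design$n_per_pop, ": ",
         paste(pops[sizes < design$n_per_pop], collapse = ", "))
  if (any(sizes == 0)) stop("all three populations must be present")
  set.seed(design$seed)
  n_comp <- nrow(m$values)
  counts <- matrix(0L, design$n_iter, length(pops),
                   dimnames = list(NULL, pops))
  freq <- matrix(0, n_comp, length(pops),
                 dimnames = list(m$features$compound_id, pops))
  for (it in seq_len(design$n_iter)) {
    drawn <- lapply(idx_by_pop, function(ii) sample(ii, design$n_per_pop))
    for (p in pops) {
      focal <- drawn[[p]]
      rest <- unlist(drawn[setdiff(pops, p)], use.names = FALSE)
      res <- row_welch(m$values, focal, rest)
      sig <- bh_adjust(res$p) < design$alpha
      counts[it, p] <- sum(sig)
      freq[, p] <- freq[, p] + sig
    }
  }
  structure(list(counts = counts, frequency = freq / design$n_iter,
                 median_counts = apply(counts, 2, stats::median),
                 mean_counts = colMeans(counts), design = design),
            class = "subsampling_result")
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat("<subsampling_result>", nrow(x$counts), "iterations, n_per_pop =",
      x$design$n_per_pop, "\n  median counts:",
      paste(names(x$median_counts), round(x$median_counts, 1), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Population-specific compound sets on the full dataset
#'
#' One-vs-rest Welch tests on all samples (no subsampling) with BH
#' correction across compounds; a compound is specific to the focal
#' population when its adjusted p-value falls below `alpha` (differences in
#' both directions count). The sign of the focal-minus-rest mean difference
#' is recorded.
#'
#' @param m a log2 `intensity_matrix` (typically the older dataset only).
#' @param alpha BH-adjusted significance threshold.
#' @return Named list over populations; each element a data.frame of
#'   `compound_id`, `delta` (focal minus rest mean), `p_adj`.
#' @export
population_specific_set <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "intensity_matrix"))
  st <- m$samples
  out <- lapply(POPULATIONS, function(p) {
    focal <- which(st$population == p)
    rest <- which(st$population != p)
    if (length(focal) < 2 || length(rest) < 2)
      stop("population ", p, " (or its complement) has fewer than 2 samples")
    res <- row_welch(m$values, focal, rest)
    p_adj <- bh_adjust(res$p)
    sig <- which(p_adj < alpha)
    data.frame(compound_id = m$features$compound_id[sig],
               delta = res$delta[sig], p_adj = p_adj[sig],
               stringsAsFactors = FALSE)
  })
  names(out) <- POPULATIONS
  out
}
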