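#' @keywords internal
"_PACKAGE"

POPULATIONS <- c("HC", "WE", "AA")
SEXES <- c("M", "F", "unknown")
ION_MODES <- c("positive", "negative", "none")

#' Construct and validate a sample table
#'
#' A sample table holds per-sample covariates for a cohort: population label,
#' age in years, sex, RNA integrity number (RIN), postmortem interval (PMI,
#' hours), extraction batch and mass-spectrometry run order.
#'
#' @param df data.frame with columns `sample_id`, `population`, `age`, and
#'   optionally `sex`, `rin`, `pmi`, `batch`, `run_order`. Missing optional
#'   columns are filled with `NA` (sex with `"unknown"`).
#' @return A validated `sample_table` (a data.frame subclass).
#' @export
sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("sample_id", "population", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("sample table is missing columns: ", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$population <- as.character(df$population)
  bad_pop <- setdiff(unique(df$population), POPULATIONS)
  if (length(bad_pop) > 0)
    stop("unknown population label(s): ", paste(bad_pop, collapse = ", "))
  df$age <- as.numeric(df$age)
  bad_age <- which(!is.finite(df$age) | df$age < 0)
  if (length(bad_age) > 0)
    stop("non-finite or negative age for sample(s): ",
         paste(df$sample_id[bad_age], collapse = ", "))
  if (is.null(df$sex)) df$sex <- "unknown"
  df$sex[is.na(df$sex)] <- "unknown"
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex) > 0)
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  for (col in c("rin", "pmi")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$pmi < 0, na.rm = TRUE)) stop("negative PMI")
  if (is.null(df$batch)) df$batch <- NA_character_
  df$batch <- as.character(df$batch)
  if (is.null(df$run_order)) df$run_order <- NA_integer_
  df$run_order <- as.integer(df$run_order)
  if (any(df$run_order < 1, na.rm = TRUE)) stop("run_order must be positive")
  ro <- df$run_order[!is.na(df$run_order)]
  if (anyDuplicated(ro)) stop("duplicate run_order values")
  rownames(df) <- df$sample_id
  class(df) <- unique(c("sample_table", class(df)))
  df
}

#' Default age-group scheme
#'
#' Six age groups A1-A6 split at 1, 5, 15, 25 and 45 years (half-open
#' intervals, upper bound exclusive; the last group is unbounded).
#'
#' @param boundaries strictly increasing interior boundaries in years.
#' @param labels group labels, one more than there are boundaries.
#' @return An `age_group_scheme` list with `boundaries` and `labels`.
#' @export
age_group_scheme <- function(boundaries = c(1, 5, 15, 25, 45),
                             labels = paste0("A", seq_len(length(boundaries) + 1))) {
  stopifnot(length(labels) == length(boundaries) + 1)
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, labels = labels),
            class = "age_group_scheme")
}

#' Assign infant/older dataset labels
#'
#' Splits a cohort at 5 years of age into the infant dataset `DS:0-4`
#' (age < 5) and the older dataset `DS:5-71` (age >= 5). The boundary is
#' half-open so the partition is exhaustive and disjoint.
#'
#' @param samples a `sample_table`.
#' @return The table with a `dataset` column added.
#' @export
assign_dataset <- function(samples, split_age = 5) {
  stopifnot(inherits(samples, "sample_table"))
  samples$dataset <- ifelse(samples$age < split_age, "DS:0-4", "DS:5-71")
  samples
}

#' Assign age-group labels
#'
#' Maps each sample's age to one of the scheme's groups using half-open
#' intervals: with the default scheme `[0,1) -> A1`, `[1,5) -> A2`,
#' `[5,15) -> A3`, `[15,25) -> A4`, `[25,45) -> A5`, `[45,Inf) -> A6`.
#'
#' @param samples a `sample_table`.
#' @param scheme an `age_group_scheme`.
#' @return The table with an `age_group` column added.
#' @export
assign_age_group <- function(samples, scheme = age_group_scheme()) {
  stopifnot(inherits(samples, "sample_table"), inherits(scheme, "age_group_scheme"))
  idx <- findInterval(samples$age, scheme$boundaries) + 1L
  samples$age_group <- scheme$labels[idx]
  samples
}

#' Construct an intensity matrix
#'
#' The central container for peak-table data: a compounds-by-samples numeric
#' matrix together with per-compound feature metadata (m/z, retention time,
#' ionization mode for lipids; compound name for metabolites) and the sample
#' table the columns refer to.
#'
#' @param values numeric matrix, compounds in rows, samples in columns.
#' @param features data.frame with at least `compound_id` and `kind`
#'   (`"lipid"` or `"metabolite"`); lipids additionally need positive `mz`,
#'   `rt` and an `ion_mode` of `"positive"` or `"negative"`.
#' @param samples a `sample_table` whose `sample_id`s match `colnames(values)`.
#' @param scale `"raw"` (positive ion intensities) or `"log2"`.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, features, samples, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.data.frame(features),
            inherits(samples, "sample_table"))
  features$compound_id <- as.character(features$compound_id)
  if (anyDuplicated(features$compound_id))
    stop("duplicate compound_id in features")
  if (nrow(values) != nrow(features))
    stop("values has ", nrow(values), " rows but features has ", nrow(features))
  if (ncol(values) != nrow(samples))
    stop("values has ", ncol(values), " columns but samples has ", nrow(samples))
  if (!is.null(colnames(values)) && !identical(colnames(values), samples$sample_id))
    stop("column names of values do not match samples$sample_id")
  if (is.null(features$kind)) stop("features needs a 'kind' column")
  bad_kind <- setdiff(unique(features$kind), c("lipid", "metabolite"))
  if (length(bad_kind) > 0) stop("unknown compound kind: ", bad_kind)
  if (is.null(features$ion_mode)) features$ion_mode <- "none"
  is_lip <- features$kind == "lipid"
  if (any(is_lip)) {
    if (is.null(features$mz) || is.null(features$rt))
      stop("lipid features need mz and rt columns")
    if (any(!is.finite(features$mz[is_lip]) | features$mz[is_lip] <= 0))
      stop("lipid mz must be positive and finite")
    if (any(!is.finite(features$rt[is_lip]) | features$rt[is_lip] <= 0))
      stop("lipid rt must be positive and finite")
    if (any(!features$ion_mode[is_lip] %in% c("positive", "negative")))
      stop("lipid ion_mode must be 'positive' or 'negative'")
  }
  if (any(features$ion_mode[!is_lip] != "none"))
    stop("metabolite features must have ion_mode 'none'")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw intensities must be non-negative")
  dimnames(values) <- list(features$compound_id, samples$sample_id)
  rownames(features) <- features$compound_id
  structure(list(values = values, features = features, samples = samples,
                 scale = scale),
            class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d compounds x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  kinds <- table(x$features$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset an intensity matrix by compound and/or sample
#'
#' @param m an `intensity_matrix`.
#' @param compounds logical/integer/character index over compounds.
#' @param samples logical/integer/character index over samples.
#' @return The subsetted `intensity_matrix`.
#' @export
im_subset <- function(m, compounds = NULL, samples = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!is.null(compounds)) {
    m$values <- m$values[compounds, , drop = FALSE]
    m$features <- m$features[compounds, , drop = FALSE]
  }
  if (!is.null(samples)) {
    m$values <- m$values[, samples, drop = FALSE]
    st <- m$samples[samples, , drop = FALSE]
    class(st) <- class(m$samples)
    m$samples <- st
  }
  if (nrow(m$values) == 0) stop("no compounds left after subsetting")
  if (ncol(m$values) == 0) stop("no samples left after subsetting")
  m
}

FEATURE_COLS <- c("compound_id", "kind", "mz", "rt", "ion_mode", "name")

#' Read / write intensity matrices as TSV
#'
#' The on-disk format is a tab-separated UTF-8 table: feature metadata columns
#' `compound_id, kind, mz, rt, ion_mode, name` followed by one column per
#' sample. `NA` marks missing values; decimals use a period. A round trip
#' through `write_intensity_tsv()` then `read_intensity_tsv()` reproduces the
#' values exactly as written at the chosen precision.
#'
#' @param path file path.
#' @param samples the `sample_table` for the columns (sample ids must match).
#' @param scale value scale to stamp on the object (`"raw"` or `"log2"`).
#' @return `read_intensity_tsv()` returns an `intensity_matrix`;
#'   `write_intensity_tsv()` returns `path` invisibly.
#' @export
read_intensity_tsv <- function(path, samples, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  missing_meta <- setdiff(FEATURE_COLS, names(df))
  if (length(missing_meta) > 0)
    stop("intensity TSV ", path, " is missing metadata columns: ",
         paste(missing_meta, collapse = ", "))
  sample_cols <- names(df)[!names(df) %in% FEATURE_COLS]
  if (anyDuplicated(sample_cols))
    stop("duplicated sample column(s) in ", path, ": ",
         paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", "))
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[, sample_cols, drop = FALSE], is.numeric, logical(1)))
    stop("non-numeric intensity column(s) in ", path, ": ",
         paste(sample_cols[bad], collapse = ", "))
  }
  features <- df[, FEATURE_COLS]
  st <- samples[match(sample_cols, samples$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id))
    stop("sample column(s) absent from sample table: ",
         paste(setdiff(sample_cols, samples$sample_id), collapse = ", "))
  class(st) <- class(samples)
  colnames(vals) <- sample_cols
  intensity_matrix(vals, features, st, scale = scale)
}

#' @rdname read_intensity_tsv
#' @param m an `intensity_matrix` to write.
#' @param digits significant digits used for intensity values.
#' @export
write_intensity_tsv <- function(m, path, digits = 10) {
  stopifnot(inherits(m, "intensity_matrix"))
  feat <- m$features
  for (col in FEATURE_COLS) if (is.null(feat[[col]])) feat[[col]] <- NA
  out <- cbind(feat[, FEATURE_COLS],
               as.data.frame(signif(m$values, digits), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sample table as TSV
#'
#' Columns: `sample_id, population, age, sex, rin, pmi, batch, run_order`,
#' tab-separated with `NA` for missing values.
#'
#' @param path file path.
#' @return `read_sample_tsv()` returns a `sample_table`.
#' @export
read_sample_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  sample_table(df)
}

#' @rdname read_sample_tsv
#' @param samples a `sample_table` to write.
#' @export
write_sample_tsv <- function(samples, path) {
  stopifnot(inherits(samples, "sample_table"))
  cols <- intersect(c("sample_id", "population", "age", "sex", "rin", "pmi",
                      "batch", "run_order", "dataset", "age_group"),
                    names(samples))
  utils::write.table(as.data.frame(samples)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}
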