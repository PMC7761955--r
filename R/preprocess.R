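#' Preprocessing configuration
#'
#' Bundles the feature-screening thresholds applied before statistics:
#' the "80% rule" missingness cutoff, the QC coefficient-of-variation
#' cutoff, and the minimum number of non-missing QC observations a feature
#' needs for its CV to be estimable.
#'
#' @param missing_fraction_threshold Features missing (zero) in at least
#'   this fraction of non-QC samples are removed. Default 0.20.
#' @param qc_cv_threshold Features whose QC coefficient of variation
#'   (sd/mean on raw intensities) strictly exceeds this are removed.
#'   Default 0.30.
#' @param min_qc_observations Minimum non-missing QC intensities required
#'   to compute a CV; features below it are removed and reported
#'   separately. Default 3.
#' @param half_min_scope `"feature"` (default): impute zeros with half the
#'   feature's minimum positive intensity; `"global"`: half the global
#'   minimum positive intensity.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(missing_fraction_threshold = 0.20,
                              qc_cv_threshold = 0.30,
                              min_qc_observations = 3L,
                              half_min_scope = c("feature", "global")) {
  stopifnot_scalar_prob(missing_fraction_threshold, "missing_fraction_threshold")
  stopifnot_scalar_prob(qc_cv_threshold, "qc_cv_threshold")
  structure(
    list(
      missing_fraction_threshold = missing_fraction_threshold,
      qc_cv_threshold = qc_cv_threshold,
      min_qc_observations = as.integer(min_qc_observations),
      half_min_scope = match.arg(half_min_scope)
    ),
    class = "preprocess_config"
  )
}

qc_ids <- function(meta) meta$sample_id[meta$is_qc]
biological_ids <- function(meta) meta$sample_id[!meta$is_qc]

#' Feature screening, imputation, normalization and transformation
#'
#' The preprocessing chain applied to a raw feature table before any
#' statistics, in the order `filter_by_missingness()` (the "80% rule"),
#' `filter_by_qc_cv()`, `impute_half_min()`, `normalize_median()`,
#' `log2_transform()`; `preprocess_pipeline()` runs all five and returns a
#' stage-by-stage report.
#'
#' * `filter_by_missingness()` drops features whose zero fraction over
#'   non-QC samples is `>= threshold` (missing in 20% or more of samples,
#'   by default).
#' * `filter_by_qc_cv()` drops features whose coefficient of variation
#'   (sample sd / mean, raw intensities) over non-missing QC values is
#'   strictly greater than `cv_threshold`; features with fewer than
#'   `min_qc_observations` non-missing QC values are dropped too, counted
#'   separately in the report.
#' * `impute_half_min()` replaces each zero by half the feature's minimum
#'   positive intensity (below-detection-limit censoring); with
#'   `scope = "global"`, by half the global minimum positive intensity.
#' * `normalize_median()` rescales every sample so its median intensity
#'   equals the reference (the median of all sample medians).
#' * `log2_transform()` takes elementwise log2 (requires imputation first).
#'
#' @param x A feature table (see [feature_table()]).
#' @param meta Sample metadata covering every sample column of `x`.
#' @param threshold,cv_threshold,min_qc_observations See
#'   [preprocess_config()].
#' @param scope Half-minimum scope, `"feature"` or `"global"`.
#' @param config A [preprocess_config()].
#' @return The filtered/transformed feature table; `preprocess_pipeline()`
#'   returns a list of class `preprocess_result` with elements `table` and
#'   `report` (a tibble of stages, parameters and removal counts).
#' @examples
#' sim <- simulate_cohort(cohort_spec(
#'   group_sizes = c(normal = 6, malignant = 6),
#'   n_features = 30, n_differential = 3, seed = 1
#' ))
#' res <- preprocess_pipeline(sim$table, sim$meta)
#' res$report
#' @export
filter_by_missingness <- function(x, meta, threshold = 0.20) {
  stopifnot_scalar_prob(threshold, "threshold")
  bio <- intersect(biological_ids(meta), sample_columns(x))
  if (length(bio) == 0L) abort("no non-QC samples to compute missingness over")
  m <- intensity_matrix(x, bio)
  frac_missing <- rowMeans(m == 0)
  keep <- frac_missing < threshold
  out <- x[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' @rdname filter_by_missingness
#' @export
filter_by_qc_cv <- function(x, meta, cv_threshold = 0.30,
                            min_qc_observations = 3L) {
  stopifnot_scalar_prob(cv_threshold, "cv_threshold")
  qc <- intersect(qc_ids(meta), sample_columns(x))
  if (length(qc) == 0L) {
    abort(paste(
      "no QC samples present; skip the QC CV filter explicitly",
      "(omit filter_by_qc_cv / set qc_cv_threshold to NULL in the pipeline)"
    ))
  }
  m <- intensity_matrix(x, qc)
  stats <- apply(m, 1, function(v) {
    v <- v[v > 0]
    if (length(v) < min_qc_observations) return(c(cv = NA_real_, n = length(v)))
    c(cv = sd(v) / mean(v), n = length(v))
  })
  cv <- stats["cv", ]
  insufficient <- is.na(cv)
  removed_cv <- !insufficient & cv > cv_threshold
  keep <- !insufficient & !removed_cv
  out <- x[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(removed_cv)
  attr(out, "n_insufficient_qc") <- sum(insufficient)
  out
}

#' @rdname filter_by_missingness
#' @export
impute_half_min <- function(x, scope = c("feature", "global")) {
  scope <- match.arg(scope)
  if (nrow(x) == 0L) abort("feature table is empty (all features filtered out)")
  smp <- sample_columns(x)
  m <- intensity_matrix(x)
  pos_min <- apply(m, 1, function(v) if (any(v > 0)) min(v[v > 0]) else NA_real_)
  if (anyNA(pos_min)) {
    abort(sprintf("feature '%s' has no positive intensity; remove it upstream",
                  x$feature[which(is.na(pos_min))[1]]))
  }
  fill <- if (scope == "feature") pos_min / 2 else rep(min(pos_min) / 2, nrow(m))
  zero <- m == 0
  m[zero] <- rep(fill, ncol(m))[as.vector(zero)]
  set_intensities(x, m)
}

#' @rdname filter_by_missingness
#' @export
normalize_median <- function(x) {
  m <- intensity_matrix(x)
  med <- apply(m, 2, median)
  if (any(med <= 0)) {
    abort(sprintf("sample '%s' has nonpositive median intensity",
                  colnames(m)[which(med <= 0)[1]]))
  }
  reference <- median(med)
  m <- sweep(m, 2, reference / med, `*`)
  out <- set_intensities(x, m)
  attr(out, "reference_median") <- reference
  out
}

#' @rdname filter_by_missingness
#' @export
log2_transform <- function(x) {
  m <- intensity_matrix(x)
  if (any(m <= 0)) {
    abort("nonpositive intensities present; run impute_half_min() first")
  }
  set_intensities(x, log2(m))
}

#' QC relative standard deviation of a feature
#'
#' RSD (percent) of one feature over the pooled-QC injections, on raw
#' (pre-log) intensities: `100 * sd / mean` over non-missing QC values.
#' The standard instrument-stability diagnostic, e.g. for a spiked internal
#' standard.
#'
#' @param x A feature table.
#' @param meta Sample metadata (QC samples flagged by `is_qc`).
#' @param feature A feature label present in `x`.
#' @return RSD as a percentage (scalar).
#' @export
compute_rsd <- function(x, meta, feature) {
  if (!feature %in% x$feature) abort(sprintf("feature '%s' not found", feature))
  qc <- intersect(qc_ids(meta), sample_columns(x))
  v <- as.numeric(unlist(x[x$feature == feature, qc]))
  v <- v[v > 0]
  if (length(v) < 2L) {
    abort(sprintf("feature '%s' has %d non-missing QC value(s); need at least 2",
                  feature, length(v)))
  }
  100 * sd(v) / mean(v)
}

#' @rdname filter_by_missingness
#' @export
preprocess_pipeline <- function(x, meta, config = preprocess_config()) {
  x <- feature_table(x)
  meta <- sample_metadata(meta)
  n0 <- nrow(x)

  x1 <- filter_by_missingness(x, meta, config$missing_fraction_threshold)
  n_miss <- attr(x1, "n_removed")

  x2 <- filter_by_qc_cv(x1, meta, config$qc_cv_threshold,
                        config$min_qc_observations)
  n_cv <- attr(x2, "n_removed")
  n_insuff <- attr(x2, "n_insufficient_qc")

  x3 <- impute_half_min(x2, scope = config$half_min_scope)
  x4 <- normalize_median(x3)
  reference <- attr(x4, "reference_median")
  x5 <- log2_transform(x4)

  report <- tibble(
    stage = c("input", "missingness_filter", "qc_cv_filter",
              "qc_insufficient", "impute_half_min", "normalize_median",
              "log2_transform"),
    parameter = c(NA, sprintf("threshold=%.3g", config$missing_fraction_threshold),
                  sprintf("cv_threshold=%.3g", config$qc_cv_threshold),
                  sprintf("min_qc_observations=%d", config$min_qc_observations),
                  sprintf("scope=%s", config$half_min_scope),
                  sprintf("reference_median=%.6g", reference), NA),
    n_features = c(n0, nrow(x1), nrow(x2), nrow(x2), nrow(x3), nrow(x4), nrow(x5)),
    n_removed = c(NA, n_miss, n_cv, n_insuff, NA, NA, NA)
  )
  structure(list(table = x5, report = report, config = config),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  print(x$report)
  invisible(x)
}
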