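#' Rank-based differential testing of one feature
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value comparing two groups
#' of intensities. By default (`exact = NULL`) the exact distribution is
#' used when the smaller group has at most 10 observations and the pooled
#' data is tie-free; otherwise the tie-corrected normal approximation with
#' continuity correction (midrank ties).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param exact `TRUE`/`FALSE` to force the exact/approximate variant,
#'   `NULL` for the automatic rule.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)) # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(values_a, values_b, exact = NULL) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("each group needs at least 2 values")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) return(1)  # complete ties: no evidence
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) {
    exact <- min(length(values_a), length(values_b)) <= 10L && !ties
  }
  if (exact && ties) {
    abort("exact Wilcoxon p-value is unavailable with ties")
  }
  if (!ties) {
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE)$p.value
  } else {
    suppressWarnings(
      wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)$p.value
    )
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`,
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Log2 fold change between two groups of log2 intensities
#'
#' `mean(case) - mean(reference)` on already log2-transformed values, so a
#' feature lower in the case group yields a negative value.
#'
#' @param case_log2,reference_log2 Numeric vectors of log2 intensities.
#' @return Scalar log2 fold change.
#' @export
log2_fold_change <- function(case_log2, reference_log2) {
  if (length(case_log2) == 0L || length(reference_log2) == 0L) {
    abort("both groups must be non-empty")
  }
  mean(case_log2) - mean(reference_log2)
}

#' Specification of a two-group comparison
#'
#' Names the reference and case groups, the selection rule, and whether
#' borderline tumors are merged into the malignant group for this
#' comparison (the usual handling when contrasting benign against
#' malignant disease).
#'
#' @param group_a Reference group label (e.g. `"normal"`).
#' @param group_b Case group label; `log2FC = mean(group_b) -
#'   mean(group_a)`.
#' @param mode `"fdr_rule"` (select when `VIP > 1` and `FDR < 0.1`) or
#'   `"p_rule"` (`VIP > 1` and `p < 0.05`); strict inequalities.
#' @param merge_borderline_into_malignant Relabel `borderline` samples as
#'   `malignant` before comparing (default `FALSE`).
#' @return A list of class `comparison_spec`.
#' @export
comparison_spec <- function(group_a, group_b, mode = c("fdr_rule", "p_rule"),
                            merge_borderline_into_malignant = FALSE) {
  if (identical(group_a, group_b)) abort("comparison groups must differ")
  structure(
    list(group_a = group_a, group_b = group_b, mode = match.arg(mode),
         merge_borderline_into_malignant = isTRUE(merge_borderline_into_malignant)),
    class = "comparison_spec"
  )
}

apply_group_merge <- function(meta, comparison) {
  if (comparison$merge_borderline_into_malignant) {
    meta$group[!meta$is_qc & meta$group == "borderline"] <- "malignant"
  }
  meta
}

comparison_samples <- function(meta, comparison, cohort = NULL) {
  meta <- apply_group_merge(meta, comparison)
  keep <- !meta$is_qc & meta$group %in% c(comparison$group_a, comparison$group_b)
  if (!is.null(cohort)) keep <- keep & meta$cohort == cohort
  meta[keep, , drop = FALSE]
}

#' Differential feature table for one comparison
#'
#' Per-feature Wilcoxon rank-sum p-value, Benjamini-Hochberg FDR across
#' all tested features, log2 fold change (`mean(group_b) - mean(group_a)`
#' on the log2 table), the supplied VIP, and the selection flag:
#' `fdr_rule` selects features with `VIP > 1` and `FDR < 0.1`, `p_rule`
#' those with `VIP > 1` and `p < 0.05` (strict inequalities).
#'
#' @param x A processed (log2) feature table.
#' @param meta Sample metadata.
#' @param comparison A [comparison_spec()].
#' @param vip Per-feature VIP scores, in `x`'s feature order (typically
#'   from an OPLS-DA model fitted on the same comparison's discovery
#'   samples).
#' @param cohort Optional cohort restriction (e.g. `"discovery"`).
#' @return A `differential_table` tibble: `feature`, `rt`, `mz`,
#'   `p_value`, `fdr`, `log2fc`, `vip`, `selected`.
#' @export
differential_analysis <- function(x, meta, comparison, vip,
                                  cohort = "discovery") {
  meta <- sample_metadata(meta)
  if (length(vip) != nrow(x)) {
    abort(sprintf("vip has length %d but the table has %d features",
                  length(vip), nrow(x)))
  }
  ms <- comparison_samples(meta, comparison, cohort)
  ids_a <- ms$sample_id[ms$group == comparison$group_a]
  ids_b <- ms$sample_id[ms$group == comparison$group_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    abort("both comparison groups need at least 2 samples")
  }
  m_a <- intensity_matrix(x, ids_a)
  m_b <- intensity_matrix(x, ids_b)

  p_value <- vapply(seq_len(nrow(x)), function(i) {
    wilcoxon_rank_sum(m_a[i, ], m_b[i, ], exact = FALSE)
  }, numeric(1))
  fdr <- bh_fdr(p_value)
  log2fc <- unname(rowMeans(m_b) - rowMeans(m_a))

  selected <- if (comparison$mode == "fdr_rule") {
    vip > 1 & fdr < 0.1
  } else {
    vip > 1 & p_value < 0.05
  }

  out <- tibble(
    feature = x$feature, rt = x$rt, mz = x$mz,
    p_value = p_value, fdr = fdr, log2fc = log2fc,
    vip = as.numeric(vip), selected = selected
  )
  class(out) <- c("differential_table", class(out))
  attr(out, "comparison") <- comparison
  out
}

#' Write a differential table as delimited text
#'
#' Column layout mirrors the standard reporting schema for differential
#' putative metabolites: retention time, m/z, p-value, FDR, log2FC, VIP,
#' optional annotation columns, plus the selection flag.
#'
#' @param x A `differential_table`.
#' @param path Output path (`.tsv`/`.txt` tab, otherwise comma).
#' @export
write_differential_table <- function(x, path) {
  readr::write_delim(as_tibble(x), path, delim = delim_for(path))
  invisible(path)
}
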