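#' Mass accuracy in parts per million
#'
#' Signed relative deviation of an observed m/z from a theoretical one:
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed_mz,theoretical_mz Positive m/z values (vectorized).
#' @return Delta in ppm (signed).
#' @examples
#' mass_delta_ppm(200.0040, 200.0000) # +20
#' @export
mass_delta_ppm <- function(observed_mz, theoretical_mz) {
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0)) {
    abort("m/z values must be positive")
  }
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Match features to a reference compound list by precursor mass
#'
#' Precursor-only annotation: every reference compound within
#' `tolerance_ppm` (inclusive) of a feature's m/z is listed as a
#' candidate, sorted by absolute ppm deviation. The reference list must
#' already carry positive-mode adduct m/z values; taxonomy columns
#' (`super_class`, `class`, `direct_parent`), if present, are passed
#' through. No MS2 fragment evidence is used, so candidates are putative.
#'
#' @param features A data frame with columns `feature`, `mz` (a feature
#'   table works directly).
#' @param references A data frame with columns `name`, `mz` and optional
#'   taxonomy columns.
#' @param tolerance_ppm Inclusive match tolerance in ppm (default 20, the
#'   conventional precursor tolerance for QTOF data).
#' @return A tibble with one row per (feature, candidate) pair: `feature`,
#'   `observed_mz`, `name`, `theoretical_mz`, `delta_ppm`, plus taxonomy
#'   columns; features without candidates are absent.
#' @export
match_features <- function(features, references, tolerance_ppm = 20) {
  if (nrow(references) == 0L) abort("reference compound list is empty")
  if (!all(c("name", "mz") %in% names(references))) {
    abort("references must have columns 'name' and 'mz'")
  }
  if (tolerance_ppm <= 0) abort("tolerance_ppm must be positive")
  taxonomy <- intersect(c("super_class", "class", "direct_parent"),
                        names(references))
  rows <- map(seq_len(nrow(features)), function(i) {
    delta <- mass_delta_ppm(features$mz[i], references$mz)
    hit <- which(abs(delta) <= tolerance_ppm)
    if (length(hit) == 0L) return(NULL)
    hit <- hit[order(abs(delta[hit]))]
    bind_cols(
      tibble(feature = features$feature[i], observed_mz = features$mz[i],
             name = references$name[hit], theoretical_mz = references$mz[hit],
             delta_ppm = delta[hit]),
      references[hit, taxonomy, drop = FALSE]
    )
  })
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) {
    out <- tibble(feature = character(0), observed_mz = numeric(0),
                  name = character(0), theoretical_mz = numeric(0),
                  delta_ppm = numeric(0))
  }
  out
}

#' Join best annotation candidates onto a differential table
#'
#' Adds the closest-matching reference compound (if any) per feature:
#' `name`, `delta_ppm` and taxonomy columns. Matching is precursor-only
#' (see [match_features()]).
#'
#' @param diff_table A `differential_table`.
#' @param references Reference compound list.
#' @param tolerance_ppm Match tolerance in ppm.
#' @return The differential table with annotation columns appended.
#' @export
annotate_differential <- function(diff_table, references, tolerance_ppm = 20) {
  hits <- match_features(diff_table, references, tolerance_ppm)
  best <- hits |>
    group_by(.data$feature) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-"observed_mz")
  left_join(diff_table, best, by = "feature")
}
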