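#' Feature tables and sample metadata
#'
#' A *feature table* is a tibble holding an untargeted LC-MS feature matrix:
#' one row per feature with columns `feature` (unique label, conventionally
#' `"RT_mz"`), `rt` (retention time, minutes), `mz` (mass-to-charge) followed
#' by one numeric column per sample. Intensities are nonnegative; zero encodes
#' a missing (undetected) value. *Sample metadata* is a tibble with one row
#' per sample: `sample_id`, `group` (`normal`, `benign`, `borderline`,
#' `malignant`, or `qc`), `cohort` (`discovery`/`validation`), `batch`,
#' `is_qc`, optional clinical marker columns (e.g. `ca125`) and optional
#' `stage` (FIGO `I`--`IV`).
#'
#' `feature_table()` validates and canonicalises a data frame into this
#' shape; `sample_columns()` lists the sample columns; `intensity_matrix()`
#' extracts the features-by-samples numeric matrix.
#'
#' @param x A data frame with `feature`, `rt`, `mz` and sample columns, or
#'   (for `feature_table()`) a data frame whose first column holds `"RT_mz"`
#'   labels to be parsed.
#' @param samples Optional character vector restricting which sample columns
#'   to extract.
#' @return `feature_table()` returns the validated tibble;
#'   `sample_columns()` a character vector; `intensity_matrix()` a numeric
#'   matrix with feature labels as rownames and sample ids as colnames.
#' @examples
#' tbl <- feature_table(data.frame(
#'   feature = c("1.20_100.0500", "2.40_200.1000"),
#'   s1 = c(10, 0), s2 = c(12, 5)
#' ))
#' intensity_matrix(tbl)
#' @export
feature_table <- function(x) {
  nm <- names(x)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  x <- as_tibble(x, .name_repair = "minimal")
  if (!"feature" %in% names(x)) {
    names(x)[1] <- "feature"
  }
  x$feature <- as.character(x$feature)
  if (anyDuplicated(x$feature)) {
    dup <- unique(x$feature[duplicated(x$feature)])
    abort(paste0("duplicate feature labels: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(c("rt", "mz") %in% names(x))) {
    parsed <- parse_feature_label(x$feature)
    x <- bind_cols(x[, "feature", drop = FALSE], parsed,
                   x[, setdiff(names(x), c("feature", "rt", "mz")), drop = FALSE])
  }
  smp <- setdiff(names(x), c("feature", "rt", "mz"))
  if (length(smp) == 0L) abort("feature table has no sample columns")
  if (anyDuplicated(smp)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  }
  for (s in smp) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(sprintf("sample column '%s' is not numeric", s))
    if (anyNA(v)) {
      abort(sprintf(
        "sample column '%s' contains NA; missing values must be encoded as zero", s
      ))
    }
    if (any(v < 0)) {
      abort(sprintf("sample column '%s' contains negative intensities (row %d)",
                    s, which(v < 0)[1]))
    }
  }
  x[c("feature", "rt", "mz", smp)]
}

# Parse "RT_mz" labels such as "5.7625_477.3462" into rt and mz columns.
parse_feature_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)
  bad <- which(map_int(parts, length) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("feature label '%s' (row %d) is not of the form 'RT_mz'",
                  label[bad[1]], bad[1]))
  }
  rt <- suppressWarnings(as.numeric(map_chr_(parts, 1L)))
  mz <- suppressWarnings(as.numeric(map_chr_(parts, 2L)))
  bad <- which(is.na(rt) | is.na(mz))
  if (length(bad) > 0) {
    abort(sprintf("feature label '%s' (row %d) has non-numeric RT or m/z",
                  label[bad[1]], bad[1]))
  }
  tibble(rt = rt, mz = mz)
}

map_chr_ <- function(lst, i) vapply(lst, `[[`, character(1), i)

#' @rdname feature_table
#' @export
sample_columns <- function(x) {
  setdiff(names(x), c("feature", "rt", "mz"))
}

#' @rdname feature_table
#' @export
intensity_matrix <- function(x, samples = NULL) {
  smp <- samples %||% sample_columns(x)
  missing <- setdiff(smp, names(x))
  if (length(missing) > 0) {
    abort(paste0("samples absent from feature table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- as.matrix(x[, smp, drop = FALSE])
  rownames(m) <- x$feature
  m
}

#' Read and write feature tables and metadata
#'
#' Delimited-text I/O for the two study tables. Feature tables are stored
#' with features as rows (default), a header of sample ids, and the feature
#' label `"RT_mz"` in the first column; `layout = "samples_rows"` accepts the
#' transposed orientation. Metadata files carry the columns `sample_id`,
#' `group`, `cohort`, `batch`, `is_qc`, and optionally clinical markers
#' (e.g. `ca125`) and `stage`.
#'
#' @param path File path (comma- or tab-delimited, inferred from extension:
#'   `.tsv`/`.txt` is tab, anything else comma).
#' @param layout `"features_rows"` (default) or `"samples_rows"`.
#' @param x A feature table or metadata tibble to write.
#' @return `read_feature_table()` a validated feature table;
#'   `read_sample_metadata()` a metadata tibble; the writers return `path`
#'   invisibly.
#' @export
read_feature_table <- function(path, layout = c("features_rows", "samples_rows")) {
  layout <- match.arg(layout)
  raw <- read_delim_auto(path)
  if (layout == "samples_rows") {
    ids <- names(raw)[-1]
    vals <- t(as.matrix(raw[, -1, drop = FALSE]))
    out <- as_tibble(as.data.frame(vals), .name_repair = "minimal")
    names(out) <- as.character(raw[[1]])
    raw <- bind_cols(tibble(feature = ids), out)
  }
  feature_table(raw)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(x, path) {
  x <- feature_table(x)
  out <- x[, c("feature", sample_columns(x))]
  readr::write_delim(out, path, delim = delim_for(path))
  invisible(path)
}

#' @rdname read_feature_table
#' @export
read_sample_metadata <- function(path) {
  meta <- read_delim_auto(path)
  sample_metadata(meta)
}

#' @rdname read_feature_table
#' @export
write_sample_metadata <- function(x, path) {
  readr::write_delim(x, path, delim = delim_for(path))
  invisible(path)
}

#' @rdname feature_table
#' @export
sample_metadata <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "group", "cohort")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("metadata lacks required columns: ", paste(miss, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    abort("duplicate sample_id in metadata")
  }
  if (!"is_qc" %in% names(x)) x$is_qc <- x$group == "qc"
  x$is_qc <- as.logical(x$is_qc)
  if (!"batch" %in% names(x)) x$batch <- 1L
  bad <- !x$is_qc & (is.na(x$group) | is.na(x$cohort))
  if (any(bad)) {
    abort(sprintf("non-QC sample '%s' lacks group or cohort",
                  x$sample_id[which(bad)[1]]))
  }
  x
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    name_repair = "minimal", progress = FALSE)
}

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

# Replace the intensity columns of a feature table with a matrix of the
# same shape (features x samples), preserving feature/rt/mz columns.
set_intensities <- function(x, m) {
  stopifnot(nrow(m) == nrow(x))
  smp <- colnames(m)
  x[smp] <- as.data.frame(m)
  x
}
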