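#' Column scaling for multivariate models
#'
#' Fits centering/scaling parameters on a training matrix so that exactly
#' the same transform can be applied to held-out data. `unit_variance`
#' divides each centered column by its sample standard deviation (the usual
#' PCA pretreatment); `pareto` divides by the *square root* of the standard
#' deviation, the conventional pretreatment for OPLS-DA and SVM models on
#' log-scale metabolomics data — it shrinks the dominance of high-variance
#' features without fully equalising them; `none` leaves columns as-is
#' (optionally centered).
#'
#' @param x A samples-by-features numeric matrix or data frame.
#' @param kind One of `"unit_variance"`, `"pareto"`, `"none"`.
#' @param center Center columns to zero mean first (default `TRUE`).
#' @return `fit_scaling()` returns a `scaling_spec` object holding
#'   `kind`, `center`, the fitted per-feature `means` and `divisors`;
#'   `apply_scaling()` returns the transformed matrix.
#' @examples
#' sc <- fit_scaling(matrix(c(1, 3, 2, 8), 2, 2), kind = "pareto")
#' apply_scaling(sc, matrix(c(1, 3, 2, 8), 2, 2))
#' @export
fit_scaling <- function(x, kind = c("unit_variance", "pareto", "none"),
                        center = TRUE) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("need at least 2 samples to fit scaling")
  means <- if (center) colMeans(x) else rep(0, ncol(x))
  if (kind == "none") {
    divisors <- rep(1, ncol(x))
  } else {
    n <- nrow(x)
    mu <- colMeans(x)
    sds <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
    if (any(sds == 0)) {
      bad <- colnames(x)[sds == 0] %||% which(sds == 0)
      abort(paste0("constant feature(s), divisor would be zero: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    divisors <- if (kind == "unit_variance") sds else sqrt(sds)
  }
  names(means) <- names(divisors) <- colnames(x)
  structure(list(kind = kind, center = center, means = means,
                 divisors = divisors),
            class = "scaling_spec")
}

#' @rdname fit_scaling
#' @param spec A fitted `scaling_spec`.
#' @export
apply_scaling <- function(spec, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(spec$means)) {
    abort("matrix has a different number of features than the fitted scaling")
  }
  sweep(sweep(x, 2, spec$means, `-`), 2, spec$divisors, `/`)
}

#' Principal component analysis of a scaled feature matrix
#'
#' Thin wrapper around [stats::prcomp()] applying a fitted scaling first;
#' used to inspect overall metabolome structure and QC-sample clustering.
#'
#' @param x Samples-by-features matrix or data frame.
#' @param n_components Number of components to keep (must not exceed
#'   `min(nrow - 1, ncol)`).
#' @param kind Scaling kind, as in [fit_scaling()]; default unit variance.
#' @return A list of class `pca_fit`: `scores` (samples x components),
#'   `loadings` (features x components, orthonormal), `explained_variance`
#'   (fractions, nonincreasing), and the fitted `scaling`.
#' @export
fit_pca <- function(x, n_components = 2L, kind = "unit_variance") {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    abort(sprintf("n_components = %d exceeds min(samples - 1, features) = %d",
                  n_components, kmax))
  }
  sc <- fit_scaling(x, kind = kind)
  xs <- apply_scaling(sc, x)
  p <- prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  idx <- seq_len(n_components)
  structure(
    list(scores = p$x[, idx, drop = FALSE],
         loadings = p$rotation[, idx, drop = FALSE],
         explained_variance = ev[idx],
         scaling = sc),
    class = "pca_fit"
  )
}
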