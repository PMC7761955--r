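#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns per-feature (or per-threshold,
#' per-permutation) rows; `glance()` a one-row model summary.
#'
#' @param x A fitted `opls_model`, `permutation_result`, `roc_curve`,
#'   `panel_search` or `panel_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.opls_model <- function(x, ...) {
  tibble(
    feature = names(x$vip) %||% paste0("f", seq_along(x$vip)),
    weight = unname(x$predictive_weights),
    loading = unname(x$predictive_loadings),
    vip = unname(x$vip)
  )
}

#' @rdname tidiers
#' @export
glance.opls_model <- function(x, ...) {
  tibble(r2y = x$r2y, q2 = x$q2, n_orthogonal = x$n_orthogonal,
         cv_folds = x$cv_folds, positive = x$positive, seed = x$seed)
}

#' @rdname tidiers
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_len(x$n_permutations),
         r2y = x$permuted_r2y, q2 = x$permuted_q2)
}

#' @rdname tidiers
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed_r2y = x$observed_r2y, observed_q2 = x$observed_q2,
         p_r2y = x$p_r2y, p_q2 = x$p_q2, overfit = x$overfit,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' @rdname tidiers
#' @export
tidy.roc_curve <- function(x, ...) {
  tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
         specificity = x$specificity)
}

#' @rdname tidiers
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, n_thresholds = length(x$thresholds))
}

#' @rdname tidiers
#' @export
tidy.panel_search <- function(x, ...) x$results

#' @rdname tidiers
#' @export
glance.panel_search <- function(x, ...) {
  tibble(panel = paste(x$panel, collapse = "+"), size = length(x$panel),
         cv_auc = x$cv_auc, method = x$method,
         n_subsets_evaluated = x$n_subsets_evaluated, seed = x$seed)
}

#' @rdname tidiers
#' @export
glance.panel_model <- function(x, ...) {
  tibble(panel = paste(x$panel, collapse = "+"), size = length(x$panel),
         gamma = x$gamma, cost = x$cost, seed = x$seed,
         includes_clinical_marker = x$includes_clinical_marker,
         probability_cutoff = x$probability_cutoff)
}

#' Plots for fitted objects
#'
#' ggplot2 `autoplot()` methods: OPLS-DA score plot (predictive vs first
#' orthogonal component, colored by class), permutation-test histogram of
#' permuted Q2 with the observed value marked, and the ROC curve.
#'
#' @param object A fitted `opls_model`, `permutation_result` or
#'   `roc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplots
NULL

#' @rdname autoplots
#' @export
autoplot.opls_model <- function(object, ...) {
  ortho <- if (object$n_orthogonal > 0) {
    object$orthogonal_scores[, 1]
  } else {
    rep(0, length(object$predictive_scores))
  }
  neg <- setdiff(object$levels, object$positive)
  df <- tibble(
    t_pred = object$predictive_scores, t_ortho = ortho,
    class = ifelse(object$y == 1, object$positive, neg)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_pred, .data$t_ortho,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "predictive score t[1]", y = "orthogonal score to[1]",
      title = sprintf("OPLS-DA scores (R2Y = %.2f, Q2 = %.2f)",
                      object$r2y, object$q2)
    )
}

#' @rdname autoplots
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$q2)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$observed_q2, colour = "red") +
    ggplot2::labs(
      x = "permuted Q2", y = "count",
      title = sprintf("Permutation test: pQ2 = %.4g (observed Q2 = %.2f)",
                      object$p_q2, object$observed_q2)
    )
}

#' @rdname autoplots
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tidy(object) |> arrange(dplyr::desc(.data$threshold))
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
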