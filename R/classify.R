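#' Train a radial-kernel SVM panel classifier
#'
#' Fits a radial-kernel SVM on a samples-by-panel-features matrix after
#' pareto scaling (fitted on the training data and frozen into the model).
#' Probability outputs come from cross-validated Platt (sigmoid)
#' calibration: decision values are computed for every training sample by
#' seeded stratified cross-validation, then a logistic curve maps decision
#' value to class probability. Refitting with the same seed reproduces the
#' probabilities exactly.
#'
#' @param x Samples-by-features numeric matrix or data frame (panel
#'   columns only, already preprocessed/log2 intensities).
#' @param y Binary class labels; `positive` is the class whose probability
#'   is reported (default last factor level).
#' @param gamma,cost Radial-kernel SVM hyperparameters (both > 0).
#' @param seed Seed fixing the calibration fold assignment.
#' @param scaling Scaling kind applied before the SVM (default
#'   `"pareto"`).
#' @param calibration_folds Folds for the Platt calibration (default 5).
#' @param positive Positive class label.
#' @return An object of class `panel_model`: the fitted classifier, frozen
#'   `scaling`, calibration coefficients, `panel` (feature names),
#'   `gamma`, `cost`, `seed`, `cv_probabilities` (cross-validated
#'   probabilities of the training samples, the optimism-free scores used
#'   for discovery ROC and cutoff selection), and a `probability_cutoff`
#'   (NA until set with [set_cutoff()]).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 2), 60, 2)
#' y <- rep(c("benign", "malignant"), each = 30)
#' x[y == "malignant", ] <- x[y == "malignant", ] + 2
#' m <- train_svm(x, y, gamma = 0.1, cost = 10, seed = 1)
#' head(predict(m, x))
#' @export
train_svm <- function(x, y, gamma = 0.1, cost = 100, seed = 1L,
                      scaling = "pareto", calibration_folds = 5L,
                      positive = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (any(!is.finite(x))) abort("panel matrix contains non-finite values")
  if (gamma <= 0 || cost <= 0) abort("gamma and cost must be positive")
  yb <- code_binary(y, positive)
  yf <- factor(ifelse(yb$y01 == 1, yb$positive,
                      setdiff(yb$levels, yb$positive)),
               levels = c(setdiff(yb$levels, yb$positive), yb$positive))

  sc <- fit_scaling(x, kind = scaling)
  xs <- apply_scaling(sc, x)
  fit <- e1071::svm(xs, yf, kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  orient <- svm_orientation(fit, xs, yb$y01)

  k <- min(calibration_folds, min(table(yb$y01)))
  if (k < 2L) abort("each class needs at least 2 members for calibration")
  fold_id <- stratified_folds(yb$y01, k, derive_seed(seed, 17L))
  dv_cv <- numeric(length(yb$y01))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit_f <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        gamma = gamma, cost = cost, scale = FALSE)
    o_f <- svm_orientation(fit_f, xs[tr, , drop = FALSE], yb$y01[tr])
    dv_cv[!tr] <- o_f * svm_decision(fit_f, xs[!tr, , drop = FALSE])
  }
  calib <- suppressWarnings(
    glm(yb$y01 ~ dv_cv, family = binomial())
  )
  coefs <- unname(coef(calib))
  structure(
    list(panel = colnames(x), fit = fit, scaling = sc, orient = orient,
         calibration = coefs, gamma = gamma, cost = cost,
         seed = as.integer(seed), levels = yb$levels, positive = yb$positive,
         includes_clinical_marker = FALSE, clinical_marker = NULL,
         cv_probabilities = plogis(coefs[1] + coefs[2] * dv_cv),
         probability_cutoff = NA_real_),
    class = "panel_model"
  )
}

svm_decision <- function(fit, xs) {
  pr <- predict(fit, xs, decision.values = TRUE)
  drop(attr(pr, "decision.values"))
}

# libsvm's decision-value sign depends on class order of appearance;
# return +1/-1 so that oriented values are higher for the positive class.
svm_orientation <- function(fit, xs_train, y01_train) {
  dv <- svm_decision(fit, xs_train)
  if (mean(dv[y01_train == 1]) >= mean(dv[y01_train == 0])) 1 else -1
}

#' @export
predict.panel_model <- function(object, newdata, type = c("probability", "decision", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  miss <- setdiff(object$panel, colnames(x))
  if (length(miss) > 0) {
    abort(paste0("panel features absent from newdata: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  x <- x[, object$panel, drop = FALSE]
  xs <- apply_scaling(object$scaling, x)
  dv <- object$orient * svm_decision(object$fit, xs)
  if (type == "decision") return(dv)
  prob <- plogis(object$calibration[1] + object$calibration[2] * dv)
  if (type == "probability") return(prob)
  neg <- setdiff(object$levels, object$positive)
  cutoff <- object$probability_cutoff
  if (is.na(cutoff)) abort("model has no probability cutoff; run set_cutoff()")
  ifelse(prob >= cutoff, object$positive, neg)
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf(
    "<panel_model> radial SVM on %d feature(s)%s: gamma = %g, cost = %g, seed = %d\n",
    length(x$panel), if (x$includes_clinical_marker) " + clinical marker" else "",
    x$gamma, x$cost, x$seed
  ))
  cat(sprintf("  cutoff = %s, positive class '%s'\n",
              if (is.na(x$probability_cutoff)) "unset"
              else format(x$probability_cutoff), x$positive))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sensitivity and specificity at every distinct score threshold (a sample
#' is called positive when its score is `>=` the threshold, so the curve
#' runs from sensitivity 0 / specificity 1 down to sensitivity 1 /
#' specificity 0), with AUC by the trapezoidal rule — identical to the
#' normalized Mann-Whitney U statistic, ties counting one half.
#'
#' @param scores Numeric scores (probabilities, decision values, or a raw
#'   clinical marker).
#' @param labels Binary class labels aligned with `scores`.
#' @param positive Positive class label.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity` (parallel vectors) and `auc`.
#' @examples
#' roc_curve(c(.9, .7, .8, .6), c(1, 1, 0, 0))$auc # 0.75
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  yb <- code_binary(labels, positive)
  pos <- scores[yb$y01 == 1]
  neg <- scores[yb$y01 == 0]
  thresholds <- c(sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(
    list(thresholds = thresholds, sensitivity = sens, specificity = spec,
         auc = auc, positive = yb$positive),
    class = "roc_curve"
  )
}

#' Youden-optimal probability cutoff
#'
#' The observed score threshold maximizing the Youden index
#' (sensitivity + specificity - 1). Ties are broken toward the threshold
#' with higher specificity, then toward the larger threshold; the cutoff
#' is meant to be fixed on the discovery cohort and transferred unchanged
#' to validation data.
#'
#' @param roc A [roc_curve()].
#' @return The cutoff (scalar).
#' @export
optimal_cutoff <- function(roc) {
  finite <- is.finite(roc$thresholds)
  if (sum(finite) < 2L) {
    abort("degenerate ROC: all scores identical, no cutoff is defined")
  }
  youden <- roc$sensitivity[finite] + roc$specificity[finite] - 1
  thr <- roc$thresholds[finite]
  spec <- roc$specificity[finite]
  best <- which(youden == max(youden))
  best <- best[spec[best] == max(spec[best])]
  max(thr[best])
}

#' @rdname train_svm
#' @param model A `panel_model`.
#' @param cutoff Probability cutoff in `[0, 1]` to freeze into the model.
#' @export
set_cutoff <- function(model, cutoff) {
  stopifnot_scalar_prob(cutoff, "cutoff", open0 = FALSE)
  model$probability_cutoff <- cutoff
  model
}

#' Evaluate a frozen panel model on a cohort
#'
#' Applies the model's frozen scaler, classifier and probability cutoff to
#' evaluation samples — nothing is re-estimated from the evaluation data —
#' and reports AUC (cutoff-free), sensitivity, specificity and confusion
#' counts at the cutoff.
#'
#' @param model A `panel_model` with its cutoff set.
#' @param x_eval Samples-by-features matrix containing the panel columns.
#' @param y_eval Binary labels for the evaluation samples.
#' @param subset Optional logical vector restricting the evaluation
#'   samples (e.g. early-stage cases plus all controls).
#' @param cohort Label recorded in the report (e.g. `"validation"`).
#' @param scores Optional precomputed probability scores to evaluate
#'   instead of `predict(model, x_eval)` — used to report discovery
#'   operating characteristics from the model's cross-validated
#'   probabilities (`model$cv_probabilities`), which are free of
#'   resubstitution optimism.
#' @return A one-row `evaluation_report` tibble: `cohort`, `n`, `auc`,
#'   `cutoff`, `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_panel <- function(model, x_eval, y_eval, subset = NULL,
                           cohort = "validation", scores = NULL) {
  if (is.na(model$probability_cutoff)) {
    abort("model cutoff not set; fix it on the discovery cohort first")
  }
  if (!is.null(subset)) {
    if (!any(subset)) abort("subset filter matches no samples")
    x_eval <- as.matrix(x_eval)[subset, , drop = FALSE]
    y_eval <- y_eval[subset]
    if (!is.null(scores)) scores <- scores[subset]
  }
  prob <- scores %||% predict(model, x_eval, type = "probability")
  yb <- code_binary(y_eval, model$positive)
  roc <- roc_curve(prob, y_eval, positive = model$positive)
  pred_pos <- prob >= model$probability_cutoff
  tp <- sum(pred_pos & yb$y01 == 1)
  fp <- sum(pred_pos & yb$y01 == 0)
  tn <- sum(!pred_pos & yb$y01 == 0)
  fn <- sum(!pred_pos & yb$y01 == 1)
  out <- tibble(
    cohort = cohort, n = length(prob), auc = roc$auc,
    cutoff = model$probability_cutoff,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
  class(out) <- c("evaluation_report", class(out))
  out
}

# Mean cross-validated AUC of a candidate panel under seeded stratified
# folds; scaling and SVM are refitted inside each training fold.
cv_panel_auc <- function(x, y01, panel, fold_id, gamma, cost) {
  k <- max(fold_id)
  aucs <- numeric(k)
  xp <- x[, panel, drop = FALSE]
  yf <- factor(y01, levels = c(0, 1))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    sc <- fit_scaling(xp[tr, , drop = FALSE], kind = "pareto")
    xs_tr <- apply_scaling(sc, xp[tr, , drop = FALSE])
    xs_te <- apply_scaling(sc, xp[!tr, , drop = FALSE])
    fit <- e1071::svm(xs_tr, yf[tr], kernel = "radial", gamma = gamma,
                      cost = cost, scale = FALSE)
    o <- svm_orientation(fit, xs_tr, y01[tr])
    dv <- o * svm_decision(fit, xs_te)
    aucs[f] <- roc_curve(dv, y01[!tr], positive = "1")$auc
  }
  mean(aucs)
}

#' Exhaustive biomarker-panel search
#'
#' Evaluates candidate feature subsets of size 1 to `max_panel_size` by
#' mean cross-validated AUC of a radial-kernel SVM (stratified folds,
#' seeded, scaling refit per fold) and returns the best subset. Subsets
#' are enumerated exhaustively while their total count stays within
#' `budget`; beyond it the search falls back to seeded greedy forward
#' selection — one feature added per step, keeping the best panel seen —
#' and the report records the fallback.
#'
#' Ties in CV AUC are resolved toward the subset seen first in
#' enumeration order (sizes ascending, features in candidate order), which
#' prefers smaller panels.
#'
#' @param candidates Character vector of candidate feature names (columns
#'   of `x`).
#' @param x Samples-by-features matrix containing at least the candidate
#'   columns.
#' @param y Binary labels.
#' @param max_panel_size Largest panel considered (default 10).
#' @param folds Cross-validation folds (default 7).
#' @param gamma,cost SVM hyperparameters.
#' @param seed Seed fixing the fold assignment.
#' @param budget Maximum number of subset evaluations before the greedy
#'   fallback (default 1e6).
#' @param positive Positive class label.
#' @return A list of class `panel_search`: `panel` (best subset),
#'   `cv_auc`, `method` (`"exhaustive"` or `"greedy_forward"`),
#'   `n_subsets_evaluated`, and `results` (a tibble of evaluated subsets
#'   with their scores).
#' @export
exhaustive_panel_search <- function(candidates, x, y, max_panel_size = 10L,
                                    folds = 7L, gamma = 0.1, cost = 100,
                                    seed = 1L, budget = 1e6, positive = NULL) {
  x <- as.matrix(x)
  if (length(candidates) == 0L) abort("no candidate features supplied")
  miss <- setdiff(candidates, colnames(x))
  if (length(miss) > 0) {
    abort(paste0("candidates absent from x: ", paste(head(miss, 5), collapse = ", ")))
  }
  yb <- code_binary(y, positive)
  fold_id <- stratified_folds(yb$y01, folds, derive_seed(seed, 101L))
  max_panel_size <- min(max_panel_size, length(candidates))

  n_subsets <- sum(choose(length(candidates), seq_len(max_panel_size)))
  exhaustive <- n_subsets <= budget

  results <- list()
  best <- list(panel = character(0), cv_auc = -Inf)
  consider <- function(panel) {
    score <- cv_panel_auc(x, yb$y01, panel, fold_id, gamma, cost)
    results[[length(results) + 1L]] <<- tibble(
      panel = paste(panel, collapse = "+"), size = length(panel),
      cv_auc = score
    )
    if (score > best$cv_auc) best <<- list(panel = panel, cv_auc = score)
    score
  }

  if (exhaustive) {
    for (k in seq_len(max_panel_size)) {
      sets <- combn(candidates, k, simplify = FALSE)
      for (s in sets) consider(s)
    }
    method <- "exhaustive"
  } else {
    current <- character(0)
    repeat {
      if (length(current) >= max_panel_size) break
      remaining <- setdiff(candidates, current)
      step_scores <- vapply(remaining, function(f) consider(c(current, f)),
                            numeric(1))
      current <- c(current, remaining[which.max(step_scores)])
    }
    method <- "greedy_forward"
  }

  structure(
    list(panel = best$panel, cv_auc = best$cv_auc, method = method,
         n_subsets_evaluated = length(results),
         results = list_rbind(results),
         folds = as.integer(folds), gamma = gamma, cost = cost,
         seed = as.integer(seed)),
    class = "panel_search"
  )
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf(
    "<panel_search> %s over %d subset(s): best CV AUC %.3f with {%s}\n",
    x$method, x$n_subsets_evaluated, x$cv_auc, paste(x$panel, collapse = ", ")
  ))
  invisible(x)
}

#' Hybrid panel plus clinical-marker model
#'
#' Appends a log2-transformed clinical marker (e.g. CA125) as an extra
#' column to the panel matrix and trains the same radial-kernel SVM as
#' [train_svm()]. Samples with a missing marker value are excluded and
#' counted in the returned model (`n_excluded_missing_marker`).
#'
#' @param x Samples-by-features matrix with the panel columns.
#' @param marker_values Numeric marker values per sample (nonnegative;
#'   `NA` = missing).
#' @param y Binary labels.
#' @param marker_name Column name recorded for the marker.
#' @inheritParams train_svm
#' @return A `panel_model` with `includes_clinical_marker = TRUE`.
#' @export
hybrid_model <- function(x, marker_values, y, marker_name = "ca125",
                         gamma = 0.1, cost = 100, seed = 1L,
                         scaling = "pareto", positive = NULL) {
  x <- as.matrix(x)
  if (all(is.na(marker_values))) abort("clinical marker missing for all samples")
  keep <- !is.na(marker_values)
  xm <- cbind(x[keep, , drop = FALSE],
              matrix(log2(marker_values[keep] + 1),
                     dimnames = list(NULL, marker_name)))
  model <- train_svm(xm, y[keep], gamma = gamma, cost = cost, seed = seed,
                     scaling = scaling, positive = positive)
  model$includes_clinical_marker <- TRUE
  model$clinical_marker <- marker_name
  model$n_excluded_missing_marker <- sum(!keep)
  model
}

#' @rdname hybrid_model
#' @param newdata Samples-by-features matrix with the panel columns.
#' @param model A hybrid `panel_model`.
#' @export
hybrid_matrix <- function(model, newdata, marker_values) {
  stopifnot(inherits(model, "panel_model"), model$includes_clinical_marker)
  cbind(as.matrix(newdata),
        matrix(log2(marker_values + 1),
               dimnames = list(NULL, model$clinical_marker)))
}

#' ROC of a clinical marker used directly as the score
#'
#' ROC and cutoff evaluation for a raw clinical marker (e.g. CA125 in
#' U/mL): either the Youden-optimal cutoff or a user-fixed clinical one
#' (conventionally 35 U/mL for CA125). Samples with missing marker values
#' are dropped and counted.
#'
#' @param meta Sample metadata containing the marker column.
#' @param y Binary labels aligned with `meta` rows.
#' @param marker Metadata column name (default `"ca125"`).
#' @param fixed_cutoff Optional clinical cutoff; `NULL` uses the Youden
#'   cutoff.
#' @param positive Positive class label.
#' @return A list of class `marker_evaluation`: `roc`, `auc`, `cutoff`,
#'   `cutoff_type`, `sensitivity`, `specificity`, `n`, `n_missing`.
#' @export
clinical_marker_roc <- function(meta, y, marker = "ca125",
                                fixed_cutoff = NULL, positive = NULL) {
  if (!marker %in% names(meta)) abort(sprintf("marker '%s' not in metadata", marker))
  values <- meta[[marker]]
  keep <- !is.na(values)
  if (!any(keep)) abort(sprintf("marker '%s' missing for all samples", marker))
  values <- values[keep]
  y <- y[keep]
  yb <- code_binary(y, positive)
  roc <- roc_curve(values, y, positive = yb$positive)
  cutoff <- fixed_cutoff %||% optimal_cutoff(roc)
  pos <- values[yb$y01 == 1]
  neg <- values[yb$y01 == 0]
  structure(
    list(roc = roc, auc = roc$auc, cutoff = cutoff,
         cutoff_type = if (is.null(fixed_cutoff)) "youden" else "fixed",
         sensitivity = mean(pos >= cutoff), specificity = mean(neg < cutoff),
         n = length(values), n_missing = sum(!keep)),
    class = "marker_evaluation"
  )
}

#' @export
print.marker_evaluation <- function(x, ...) {
  cat(sprintf(
    "<marker_evaluation> AUC %.3f; cutoff %.4g (%s): sens %.1f%%, spec %.1f%% (n = %d)\n",
    x$auc, x$cutoff, x$cutoff_type, 100 * x$sensitivity, 100 * x$specificity, x$n
  ))
  invisible(x)
}
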