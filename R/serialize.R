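#' Export a fitted model as a JSON document
#'
#' Writes the reproducibility-relevant parameters of a fitted model to
#' JSON: for an OPLS-DA model the scaling parameters, per-component
#' weights and loadings, R2Y, Q2, VIP and seed; for an SVM panel model
#' the panel labels, hyperparameters, scaling, Platt calibration
#' coefficients, probability cutoff and seed. A SHA-agnostic training
#' fingerprint (feature names + sample count) is included so an exported
#' model can be matched to its training run. The export is one-way
#' provenance, not a reloadable classifier.
#'
#' @param model A fitted `opls_model` or `panel_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- if (inherits(model, "opls_model")) {
    list(
      type = "opls_model",
      n_predictive = model$n_predictive,
      n_orthogonal = model$n_orthogonal,
      scaling = scaling_doc(model$scaling),
      predictive_weights = unname(model$predictive_weights),
      predictive_loadings = unname(model$predictive_loadings),
      orthogonal_weights = as.list(as.data.frame(model$orthogonal_weights)),
      orthogonal_loadings = as.list(as.data.frame(model$orthogonal_loadings)),
      q_coef = model$q_coef,
      y_mean = model$y_mean,
      r2y = model$r2y,
      q2 = model$q2,
      vip = as.list(model$vip),
      positive = model$positive,
      cv_folds = model$cv_folds,
      seed = model$seed,
      training_fingerprint = fingerprint(names(model$vip),
                                         length(model$predictive_scores))
    )
  } else if (inherits(model, "panel_model")) {
    list(
      type = "panel_model",
      panel = model$panel,
      kernel = "radial",
      gamma = model$gamma,
      cost = model$cost,
      seed = model$seed,
      scaling = scaling_doc(model$scaling),
      calibration = model$calibration,
      probability_cutoff = model$probability_cutoff,
      positive = model$positive,
      includes_clinical_marker = model$includes_clinical_marker,
      clinical_marker = model$clinical_marker,
      training_fingerprint = fingerprint(model$panel,
                                         length(model$cv_probabilities))
    )
  } else {
    abort("`model` must be an opls_model or a panel_model")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

scaling_doc <- function(sc) {
  list(kind = sc$kind, center = sc$center,
       means = as.list(sc$means), divisors = as.list(sc$divisors))
}

fingerprint <- function(features, n_samples) {
  key <- paste(c(features, n_samples), collapse = "|")
  sprintf("%d-%08x", n_samples, sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% .Machine$integer.max)
}
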