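#' Run the full discovery-to-validation workflow
#'
#' Orchestrates the complete analysis on a feature table + metadata pair
#' for one two-group comparison: preprocessing (filters, imputation,
#' median normalization, log2), OPLS-DA on the discovery cohort with the
#' permutation overfitting test, univariate differential selection
#' (Wilcoxon/BH + VIP rule), optional precursor-ppm annotation, SVM panel
#' search among the selected features, discovery ROC with Youden cutoff,
#' and evaluation of the frozen model on the validation cohort (plus an
#' optional early-stage subset). When the permutation test flags the
#' OPLS-DA model as overfit (`pQ2 >= 0.05`) the pipeline stops before
#' panel search unless `force = TRUE`.
#'
#' The discovery/validation split is read from the metadata `cohort`
#' column; the pipeline never splits samples itself.
#'
#' @param table Raw feature table (see [feature_table()]).
#' @param meta Sample metadata for every sample column.
#' @param comparison A [comparison_spec()].
#' @param config A [preprocess_config()].
#' @param references Optional reference compound list for annotation.
#' @param n_orthogonal,scaling,cv_folds OPLS-DA settings (see
#'   [fit_oplsda()]).
#' @param n_permutations Label permutations for the overfitting test
#'   (default 1000).
#' @param max_panel_size,gamma,cost,budget Panel-search / SVM settings
#'   (see [exhaustive_panel_search()]).
#' @param max_candidates Cap on panel-search candidates; when more
#'   features are selected, the top by VIP are kept (default 20).
#' @param early_stage_groups FIGO stages defining the early-stage subset
#'   evaluation (`NULL` to skip; default `c("I", "II")`).
#' @param force Run panel search even if the OPLS-DA model is overfit.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `pipeline_run`: `preprocess`, `opls`,
#'   `permutation`, `differential`, `search`, `model`, `evaluations` (a
#'   tibble of evaluation rows), and `manifest` (stages, seeds,
#'   parameters).
#' @export
run_pipeline <- function(table, meta, comparison,
                         config = preprocess_config(),
                         references = NULL,
                         n_orthogonal = 1L, scaling = "pareto", cv_folds = 7L,
                         n_permutations = 1000L,
                         max_panel_size = 10L, gamma = 0.1, cost = 100,
                         budget = 1e6, max_candidates = 20L,
                         early_stage_groups = c("I", "II"),
                         force = FALSE, seed = 1L) {
  meta <- sample_metadata(meta)
  manifest <- list(seed = as.integer(seed), stages = character(0),
                   parameters = list(
                     comparison = unclass(comparison),
                     n_orthogonal = n_orthogonal, scaling = scaling,
                     cv_folds = cv_folds, n_permutations = n_permutations,
                     max_panel_size = max_panel_size, gamma = gamma,
                     cost = cost, budget = budget,
                     max_candidates = max_candidates
                   ))
  log_stage <- function(name) {
    manifest$stages <<- c(manifest$stages, name)
    inform(sprintf("[metabopanel] stage: %s", name))
  }

  log_stage("preprocess")
  prep <- preprocess_pipeline(table, meta, config)
  proc <- prep$table

  # discovery-side matrices for the comparison
  disc <- comparison_samples(meta, comparison, "discovery")
  x_disc <- t(intensity_matrix(proc, disc$sample_id))
  y_disc <- disc$group
  positive <- comparison$group_b

  log_stage("multivariate")
  opls <- fit_oplsda(x_disc, y_disc, n_orthogonal = n_orthogonal,
                     scaling = scaling, cv_folds = cv_folds,
                     seed = derive_seed(seed, 1L), positive = positive)

  log_stage("permutation_test")
  perm <- permutation_test(x_disc, y_disc, n_orthogonal = n_orthogonal,
                           scaling = scaling, folds = cv_folds,
                           n_permutations = n_permutations,
                           seed = derive_seed(seed, 2L), positive = positive)

  log_stage("differential")
  diff_tab <- differential_analysis(proc, meta, comparison, opls$vip,
                                    cohort = "discovery")
  if (!is.null(references)) {
    log_stage("annotate")
    diff_tab <- annotate_differential(diff_tab, references)
  }

  out <- list(preprocess = prep, opls = opls, permutation = perm,
              differential = diff_tab, search = NULL, model = NULL,
              evaluations = NULL, comparison = comparison,
              manifest = manifest)
  class(out) <- "pipeline_run"

  if (perm$overfit && !force) {
    warn(sprintf(
      "OPLS-DA model is overfit (pQ2 = %.3g >= 0.05); panel search skipped (use force = TRUE to override)",
      perm$p_q2
    ))
    out$manifest <- manifest
    return(out)
  }

  candidates <- diff_tab$feature[diff_tab$selected]
  if (length(candidates) == 0L) {
    warn("no features selected; panel search skipped")
    out$manifest <- manifest
    return(out)
  }
  if (length(candidates) > max_candidates) {
    keep <- order(diff_tab$vip[diff_tab$selected], decreasing = TRUE)
    candidates <- candidates[keep][seq_len(max_candidates)]
  }

  log_stage("panel_search")
  search <- exhaustive_panel_search(
    candidates, x_disc, y_disc, max_panel_size = max_panel_size,
    folds = cv_folds, gamma = gamma, cost = cost,
    seed = derive_seed(seed, 3L), budget = budget, positive = positive
  )

  log_stage("discovery_roc")
  model <- train_svm(x_disc[, search$panel, drop = FALSE], y_disc,
                     gamma = gamma, cost = cost,
                     seed = derive_seed(seed, 4L), positive = positive)
  # discovery operating characteristics come from the cross-validated
  # probabilities, so the cutoff is chosen on optimism-free scores
  prob_disc <- model$cv_probabilities
  roc_disc <- roc_curve(prob_disc, y_disc, positive = positive)
  model <- set_cutoff(model, optimal_cutoff(roc_disc))

  evals <- list(
    evaluate_panel(model, x_disc[, search$panel, drop = FALSE], y_disc,
                   cohort = "discovery", scores = prob_disc)
  )

  log_stage("validation")
  val <- comparison_samples(meta, comparison, "validation")
  if (nrow(val) > 0 &&
      length(unique(val$group)) == 2L) {
    x_val <- t(intensity_matrix(proc, val$sample_id))
    evals <- c(evals, list(
      evaluate_panel(model, x_val[, search$panel, drop = FALSE], val$group,
                     cohort = "validation")
    ))
    if (!is.null(early_stage_groups) && "stage" %in% names(val)) {
      sub <- val$group == comparison$group_a |
        (!is.na(val$stage) & val$stage %in% early_stage_groups)
      if (any(sub & val$group == positive)) {
        log_stage("early_stage_subset")
        evals <- c(evals, list(
          evaluate_panel(model, x_val[, search$panel, drop = FALSE],
                         val$group, subset = sub,
                         cohort = "validation_early_stage")
        ))
      }
    }
  }

  out$search <- search
  out$model <- model
  out$evaluations <- list_rbind(evals)
  out$manifest <- manifest
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat(sprintf("  OPLS-DA R2Y %.3f, Q2 %.3f, pQ2 %.4g (%s)\n",
              x$opls$r2y, x$opls$q2, x$permutation$p_q2,
              if (x$permutation$overfit) "overfit" else "not overfit"))
  cat(sprintf("  %d features selected\n", sum(x$differential$selected)))
  if (!is.null(x$search)) {
    cat(sprintf("  panel {%s}, CV AUC %.3f (%s)\n",
                paste(x$search$panel, collapse = ", "), x$search$cv_auc,
                x$search$method))
    print(x$evaluations)
  }
  invisible(x)
}
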