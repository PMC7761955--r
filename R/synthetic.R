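#' Specification of a synthetic LC-MS cohort
#'
#' Describes the generative model for a synthetic untargeted-metabolomics
#' cohort with known ground truth: log-normal feature intensities, a
#' minority of truly differential features with planted log2 effects,
#' intensity-dependent (detection-limit) missingness encoded as zeros,
#' multiplicative batch effects, pooled QC injections with low dispersion,
#' an optional spiked internal-standard feature, and a CA125-like clinical
#' marker drawn per group from a moment-matched log-normal (right-skewed,
#' positive). Group sizes and marker means/sds default to a typical
#' four-group ovarian-tumor discovery cohort.
#'
#' @param group_sizes Named counts per clinical group. Default
#'   `c(normal = 40, benign = 36, borderline = 13, malignant = 74)`.
#' @param n_features Number of LC-MS features (default 1300).
#' @param n_differential Number of truly differential features (default
#'   100).
#' @param effect_log2fc Planted absolute log2 effect, scalar or length
#'   `n_differential` (default 2).
#' @param effect_pattern `"tumor_vs_normal"`: benign and malignant share
#'   the planted shift (random sign per feature) while borderline receives
#'   an independently signed shift of the same size, so borderline does
#'   not sit on a benign-to-malignant axis; `"malignant_only"`: only the
#'   malignant group is shifted.
#' @param base_log2_mean,base_log2_sd Distribution of per-feature baseline
#'   log2 intensities (default 18, 2.5).
#' @param feature_sd_meanlog,feature_sd_sdlog Log-normal parameters of the
#'   per-feature biological noise sd in log2 units (default `log(0.8)`,
#'   0.3).
#' @param missing_baseline Baseline missingness rate at the centre of the
#'   intensity distribution (default 0.05).
#' @param missing_slope Logistic slope of missingness per log2 unit below
#'   the centre (default 0.8); 0 gives completely-at-random missingness.
#' @param qc_count QC injections; `NULL` (default) uses one per 20 real
#'   samples.
#' @param qc_noise_sd Multiplicative QC noise sd on the natural-log scale
#'   (default 0.1, i.e. ~10% RSD).
#' @param batch_count,batch_shift_sd Number of batches and the sd of the
#'   per-feature log2 batch offsets (defaults 2 and 0.1).
#' @param internal_standard Add a spiked internal-standard feature
#'   (constant concentration, ~5% RSD, never missing). Default `TRUE`.
#' @param clinical_marker_params Named list of `c(mean, sd)` per group for
#'   the CA125-like marker in U/mL; defaults are strongly right-skewed
#'   group distributions typical of an ovarian-tumor cohort.
#' @param cohort Cohort label written into the metadata (default
#'   `"discovery"`).
#' @param seed Integer seed; every random draw flows from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(normal = 40, benign = 36,
                                        borderline = 13, malignant = 74),
                        n_features = 1300L,
                        n_differential = 100L,
                        effect_log2fc = 2,
                        effect_pattern = c("tumor_vs_normal", "malignant_only"),
                        base_log2_mean = 18, base_log2_sd = 2.5,
                        feature_sd_meanlog = log(0.8), feature_sd_sdlog = 0.3,
                        missing_baseline = 0.05, missing_slope = 0.8,
                        qc_count = NULL, qc_noise_sd = 0.1,
                        batch_count = 2L, batch_shift_sd = 0.1,
                        internal_standard = TRUE,
                        clinical_marker_params = list(
                          normal = c(mean = 8.35, sd = 5.81),
                          benign = c(mean = 83.45, sd = 234.82),
                          borderline = c(mean = 183.88, sd = 326.63),
                          malignant = c(mean = 1254.34, sd = 1597.27)
                        ),
                        cohort = "discovery",
                        seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    abort("group_sizes must be a named vector")
  }
  if (any(group_sizes < 0)) abort("group sizes must be >= 0")
  if (n_differential > n_features) {
    abort("n_differential cannot exceed n_features")
  }
  if (qc_noise_sd < 0 || batch_shift_sd < 0) abort("sds must be >= 0")
  stopifnot_scalar_prob(missing_baseline, "missing_baseline", open0 = FALSE)
  structure(
    list(group_sizes = group_sizes, n_features = as.integer(n_features),
         n_differential = as.integer(n_differential),
         effect_log2fc = effect_log2fc,
         effect_pattern = match.arg(effect_pattern),
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
         feature_sd_meanlog = feature_sd_meanlog,
         feature_sd_sdlog = feature_sd_sdlog,
         missing_baseline = missing_baseline, missing_slope = missing_slope,
         qc_count = qc_count, qc_noise_sd = qc_noise_sd,
         batch_count = as.integer(batch_count),
         batch_shift_sd = batch_shift_sd,
         internal_standard = isTRUE(internal_standard),
         clinical_marker_params = clinical_marker_params,
         cohort = cohort, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# moment-matched log-normal parameters for a given mean and sd
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a feature table, sample metadata and the generating ground truth
#' from a [cohort_spec()]. Intensities are `2^(baseline + batch offset +
#' group offset + noise)`; values falling below the detection model are
#' zeroed (missing-not-at-random: the probability of a zero decreases
#' logistically with the underlying log2 intensity). QC injections
#' (`generate_qc_samples()`) are pooled means of a random 20% of the real
#' samples with multiplicative noise, one per 20 real samples.
#' `simulate_null_cohort()` is the same generator with no planted effects,
#' for calibration studies.
#'
#' @param spec A [cohort_spec()].
#' @param qc Append QC samples (default `TRUE` when `qc_count` is not 0).
#' @param template Optional previous `synthetic_cohort`: its feature-level
#'   parameters (identities, baselines, noise sds, planted offsets) are
#'   reused so the new cohort — e.g. a validation cohort — is drawn i.i.d.
#'   from the same generative model, with fresh samples under this
#'   `spec`'s group sizes, cohort label and seed.
#' @return A list of class `synthetic_cohort`: `table` (feature table,
#'   QC columns included), `meta` (metadata incl. QC rows, `ca125`,
#'   `stage`), and `truth` — a list with `differential_features`,
#'   `differential_indices`, `group_offsets` (tibble of per-group log2
#'   offsets for every feature), `batch`, `marker_params`, `seed`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(
#'   group_sizes = c(normal = 10, malignant = 10),
#'   n_features = 50, n_differential = 5, seed = 42
#' ))
#' dim(sim$table)
#' sim$truth$differential_features
#' @export
simulate_cohort <- function(spec, qc = TRUE, template = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$group_sizes)
  n_real <- sum(spec$group_sizes)

  with_seed(spec$seed, {
    if (is.null(template)) {
      fp <- draw_feature_params(spec, groups)
    } else {
      fp <- feature_params_from(template, groups)
    }
    p <- length(fp$label)

    # samples
    group <- rep(groups, times = spec$group_sizes)
    sample_id <- sprintf("%s_%s_%03d", substr(spec$cohort, 1, 4), group,
                         unlist(lapply(spec$group_sizes, seq_len)))
    batch <- rep_len(seq_len(spec$batch_count), n_real)
    batch <- sample(batch)  # interleave groups over batches
    batch_offsets <- matrix(
      c(rep(0, p), rnorm(p * (spec$batch_count - 1L), 0, spec$batch_shift_sd)),
      p, spec$batch_count
    )

    latent <- fp$base +
      batch_offsets[, batch, drop = FALSE] +
      fp$offsets[, group, drop = FALSE] +
      matrix(rnorm(p * n_real, 0, fp$noise_sd), p, n_real)
    intens <- 2^latent

    # detection-limit missingness (never applied to the internal standard)
    p_miss <- plogis(stats::qlogis(max(spec$missing_baseline, 1e-12)) -
                       spec$missing_slope * (latent - spec$base_log2_mean))
    if (spec$missing_baseline == 0) p_miss[] <- 0
    p_miss[fp$no_missing, ] <- 0
    zero <- matrix(rbinom(p * n_real, 1, p_miss), p, n_real) == 1
    intens[zero] <- 0
    colnames(intens) <- sample_id

    # clinical marker and FIGO stage
    ca125 <- vapply(group, function(g) {
      prm <- spec$clinical_marker_params[[g]]
      if (is.null(prm)) return(NA_real_)
      lp <- lognormal_params(prm[["mean"]], prm[["sd"]])
      stats::rlnorm(1, lp$meanlog, lp$sdlog)
    }, numeric(1))
    stage <- rep(NA_character_, n_real)
    stage_probs <- list(
      borderline = c(I = 8, II = 1, III = 2, IV = 0, `NA` = 2),
      malignant = c(I = 8, II = 9, III = 50, IV = 7, `NA` = 0)
    )
    for (g in intersect(names(stage_probs), groups)) {
      idx <- which(group == g)
      drawn <- sample(names(stage_probs[[g]]), length(idx), replace = TRUE,
                      prob = stage_probs[[g]])
      stage[idx] <- ifelse(drawn == "NA", NA_character_, drawn)
    }

    tbl <- feature_table(bind_cols(
      tibble(feature = fp$label, rt = fp$rt, mz = fp$mz),
      as_tibble(as.data.frame(intens))
    ))
    meta <- tibble(
      sample_id = sample_id, group = group, cohort = spec$cohort,
      batch = batch, is_qc = FALSE, ca125 = ca125, stage = stage
    )
    truth <- list(
      differential_features = fp$label[fp$diff_idx],
      differential_indices = fp$diff_idx,
      group_offsets = as_tibble(fp$offsets) |>
        mutate(feature = fp$label, .before = 1),
      feature_params = tibble(feature = fp$label, base_log2 = fp$base,
                              noise_sd = fp$noise_sd,
                              no_missing = fp$no_missing),
      batch = setNames(batch, sample_id),
      marker_params = spec$clinical_marker_params,
      seed = spec$seed
    )
    out <- structure(list(table = tbl, meta = meta, truth = truth,
                          spec = spec),
                     class = "synthetic_cohort")
  })
  n_qc <- spec$qc_count %||% ceiling(n_real / 20)
  if (qc && n_qc > 0) out <- generate_qc_samples(spec, out, n_qc)
  out
}

# Draw the feature-level parameters: identities, baselines, noise sds,
# planted per-group offsets, and the optional internal-standard feature.
draw_feature_params <- function(spec, groups) {
  p <- spec$n_features
  repeat {
    rt <- round(runif(p, 0.5, 12), 4)
    mz <- round(runif(p, 100, 1000), 4)
    label <- sprintf("%.4f_%.4f", rt, mz)
    if (!anyDuplicated(label)) break
  }
  base <- rnorm(p, spec$base_log2_mean, spec$base_log2_sd)
  noise_sd <- exp(rnorm(p, spec$feature_sd_meanlog, spec$feature_sd_sdlog))

  # effects are planted among reliably detected features (low expected
  # missingness) — biomarker candidates must be quantifiable, and heavily
  # censored features cannot carry a panel
  expected_miss <- plogis(stats::qlogis(max(spec$missing_baseline, 1e-12)) -
                            spec$missing_slope * (base - spec$base_log2_mean))
  if (spec$missing_baseline == 0) expected_miss[] <- 0
  eligible <- which(expected_miss < 0.1)
  if (length(eligible) < spec$n_differential) {
    eligible <- order(expected_miss)[seq_len(min(p, spec$n_differential))]
  }
  offsets <- matrix(0, p, length(groups), dimnames = list(label, groups))
  diff_idx <- sort(eligible[sample.int(length(eligible), spec$n_differential)])
  if (spec$n_differential > 0) {
    eff <- rep_len(spec$effect_log2fc, spec$n_differential)
    sgn <- sample(c(-1, 1), spec$n_differential, replace = TRUE)
    shifted <- switch(spec$effect_pattern,
                      tumor_vs_normal = intersect(c("benign", "malignant"), groups),
                      malignant_only = intersect("malignant", groups))
    for (g in shifted) offsets[diff_idx, g] <- sgn * eff
    if ("borderline" %in% groups && spec$effect_pattern == "tumor_vs_normal") {
      sgn_bl <- sample(c(-1, 1), spec$n_differential, replace = TRUE)
      offsets[diff_idx, "borderline"] <- sgn_bl * eff
    }
  }
  no_missing <- rep(FALSE, p)

  # spiked internal standard: constant concentration, ~5% RSD, never missing
  if (spec$internal_standard) {
    label <- c(label, "6.6644_303.0501")
    rt <- c(rt, 6.6644); mz <- c(mz, 303.0501)
    base <- c(base, 20); noise_sd <- c(noise_sd, 0.07)
    offsets <- rbind(offsets, 0)
    rownames(offsets) <- label
    no_missing <- c(no_missing, TRUE)
  }
  list(label = label, rt = rt, mz = mz, base = base, noise_sd = noise_sd,
       offsets = offsets, diff_idx = diff_idx, no_missing = no_missing)
}

# Reuse a previous cohort's feature-level parameters so a validation
# cohort is drawn i.i.d. from the same generative model.
feature_params_from <- function(template, groups) {
  stopifnot(inherits(template, "synthetic_cohort"))
  tr <- template$truth
  if (is.null(tr$feature_params)) {
    abort("template cohort lacks feature parameters; regenerate it")
  }
  miss <- setdiff(groups, setdiff(names(tr$group_offsets), "feature"))
  if (length(miss) > 0) {
    abort(paste0("template has no offsets for group(s): ",
                 paste(miss, collapse = ", ")))
  }
  offsets <- as.matrix(tr$group_offsets[, groups, drop = FALSE])
  rownames(offsets) <- tr$group_offsets$feature
  list(label = tr$feature_params$feature,
       rt = template$table$rt, mz = template$table$mz,
       base = tr$feature_params$base_log2,
       noise_sd = tr$feature_params$noise_sd,
       offsets = offsets,
       diff_idx = tr$differential_indices,
       no_missing = tr$feature_params$no_missing)
}

#' @rdname simulate_cohort
#' @param cohort A `synthetic_cohort` to extend with QC injections.
#' @param n_qc Number of QC injections; default one per 20 real samples.
#' @export
generate_qc_samples <- function(spec, cohort, n_qc = NULL) {
  real_ids <- cohort$meta$sample_id[!cohort$meta$is_qc]
  n_real <- length(real_ids)
  n_pool <- max(2L, round(0.2 * n_real))
  if (n_real < 2L) abort("cohort too small to pool QC samples")
  n_qc <- n_qc %||% ceiling(n_real / 20)
  with_seed(derive_seed(spec$seed, 7919L), {
    pool_ids <- sample(real_ids, n_pool)
    m <- intensity_matrix(cohort$table, pool_ids)
    pooled <- rowMeans(m)
    qc <- vapply(seq_len(n_qc), function(i) {
      pooled * exp(rnorm(length(pooled), 0, spec$qc_noise_sd))
    }, numeric(length(pooled)))
    colnames(qc) <- sprintf("%s_qc_%03d", substr(spec$cohort, 1, 4), seq_len(n_qc))
  })
  tbl <- cohort$table
  tbl[colnames(qc)] <- as.data.frame(qc)
  meta_qc <- tibble(
    sample_id = colnames(qc), group = "qc", cohort = spec$cohort,
    batch = rep_len(seq_len(spec$batch_count), n_qc), is_qc = TRUE,
    ca125 = NA_real_, stage = NA_character_
  )
  cohort$table <- tbl
  cohort$meta <- bind_rows(cohort$meta, meta_qc)
  cohort$truth$qc_pool <- pool_ids
  cohort
}

#' @rdname simulate_cohort
#' @param ... Arguments passed to [cohort_spec()] (except
#'   `n_differential`, forced to 0).
#' @export
simulate_null_cohort <- function(...) {
  args <- list(...)
  args$n_differential <- 0L
  simulate_cohort(do.call(cohort_spec, args))
}

#' True log2 fold change of every feature for a group contrast
#'
#' Reads the planted per-group offsets from a synthetic cohort's ground
#' truth: `offset(group_b) - offset(group_a)` (0 for non-differential
#' features). Lets any downstream selection be scored against the truth
#' without re-deriving the generative model.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param group_a Reference group.
#' @param group_b Case group.
#' @return Named numeric vector over all features.
#' @export
true_log2fc <- function(truth, group_a, group_b) {
  go <- truth$group_offsets
  setNames(go[[group_b]] - go[[group_a]], go$feature)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d features x %d samples (%d QC); %d differential; seed %d\n",
    nrow(x$table), nrow(x$meta), sum(x$meta$is_qc),
    length(x$truth$differential_indices), x$truth$seed
  ))
  invisible(x)
}
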