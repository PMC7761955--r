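#' Orthogonal PLS discriminant analysis (OPLS-DA)
#'
#' Fits a two-class OPLS-DA model: variation in `x` orthogonal to the
#' class response is removed by `n_orthogonal` orthogonal-signal-correction
#' components, then a single predictive PLS component is fitted to the
#' dummy-coded response. The model reports `R2Y` (explained response
#' variance of the full fit), `Q2` (1 - PRESS/TSS from stratified
#' `cv_folds`-fold cross-validation, with scaling re-estimated inside each
#' training fold so no information leaks from held-out samples), and the
#' per-feature VIP scores.
#'
#' The response is coded 0/1 (the `positive` class is 1) and centered; the
#' predictive component is oriented so that the positive class has positive
#' mean score. With `n_orthogonal = 0` the model reduces exactly to
#' single-component PLS1-DA.
#'
#' @param x Samples-by-features matrix or data frame (already preprocessed,
#'   typically log2 intensities).
#' @param y Binary class labels (factor, character, or 0/1 numeric).
#' @param n_orthogonal Number of orthogonal components (default 1), or
#'   `"auto"` to keep adding components while Q2 improves by more than 0.01
#'   (up to 5).
#' @param scaling Scaling kind for [fit_scaling()]; default `"pareto"`.
#' @param cv_folds Stratified cross-validation folds for Q2 (default 7).
#' @param seed Seed fixing the fold assignment.
#' @param positive Label of the class to code 1; default the last level of
#'   `factor(y)`.
#' @return An object of class `opls_model` with elements
#'   `predictive_scores`, `predictive_loadings`, `predictive_weights`,
#'   `orthogonal_scores`/`loadings`/`weights` (matrices, one column per
#'   component), `r2y`, `q2`, `vip`, `scaling`, `q_coef`, `y_mean`,
#'   `levels`, `positive`, `cv_folds`, `seed`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 10), 40, 10)
#' y <- rep(c("a", "b"), each = 20)
#' x[, 1] <- x[, 1] + 2 * (y == "b")
#' m <- fit_oplsda(x, y, n_orthogonal = 1, seed = 1)
#' glance(m)
#' @export
fit_oplsda <- function(x, y, n_orthogonal = 1L, scaling = "pareto",
                       cv_folds = 7L, seed = 1L, positive = NULL) {
  x <- as.matrix(x)
  yb <- code_binary(y, positive)
  if (any(table(yb$y01) < cv_folds)) {
    abort(sprintf("each class needs at least cv_folds = %d members", cv_folds))
  }

  if (identical(n_orthogonal, "auto")) {
    n_orthogonal <- choose_n_orthogonal(x, yb$y01, scaling, cv_folds, seed)
  }
  n_orthogonal <- as.integer(n_orthogonal)
  if (n_orthogonal < 0L) abort("n_orthogonal must be >= 0")

  sc <- fit_scaling(x, kind = scaling)
  xs <- apply_scaling(sc, x)
  y_mean <- mean(yb$y01)
  yc <- yb$y01 - y_mean

  core <- opls_core(xs, yc, n_orthogonal)
  # orient so the positive class has positive mean predictive score
  if (mean(core$t[yb$y01 == 1]) < mean(core$t[yb$y01 == 0])) {
    core$w <- -core$w; core$t <- -core$t; core$p <- -core$p; core$q <- -core$q
  }
  fitted_y <- core$t * core$q
  r2y <- 1 - sum((yc - fitted_y)^2) / sum(yc^2)

  q2 <- cv_q2(x, yb$y01, n_orthogonal, scaling, cv_folds, seed)
  vip <- vip_from_weights(core$w)
  names(vip) <- colnames(x)

  structure(
    list(
      n_predictive = 1L,
      n_orthogonal = n_orthogonal,
      predictive_scores = core$t,
      predictive_loadings = core$p,
      predictive_weights = core$w,
      orthogonal_scores = core$T_o,
      orthogonal_loadings = core$P_o,
      orthogonal_weights = core$W_o,
      q_coef = core$q,
      y_mean = y_mean,
      r2y = r2y,
      q2 = q2,
      vip = vip,
      scaling = sc,
      levels = yb$levels,
      positive = yb$positive,
      y = yb$y01,
      cv_folds = as.integer(cv_folds),
      seed = as.integer(seed)
    ),
    class = "opls_model"
  )
}

# Map arbitrary binary labels to 0/1 with a declared positive class.
code_binary <- function(y, positive = NULL) {
  f <- factor(y)
  if (nlevels(f) != 2L) {
    abort(sprintf("y must have exactly 2 classes, found %d", nlevels(f)))
  }
  positive <- positive %||% levels(f)[2]
  if (!positive %in% levels(f)) {
    abort(sprintf("positive class '%s' not among labels", positive))
  }
  list(y01 = as.numeric(f == positive), levels = levels(f), positive = positive)
}

# Core OPLS fit on an already-scaled matrix and centered response.
# NIPALS-style with explicit deflation; single predictive component.
opls_core <- function(xs, yc, n_orthogonal) {
  p_feat <- ncol(xs)
  W_o <- matrix(0, p_feat, 0)
  P_o <- matrix(0, p_feat, 0)
  T_o <- matrix(0, nrow(xs), 0)
  xd <- xs
  for (k in seq_len(n_orthogonal)) {
    w <- crossprod(xd, yc)
    w <- w / sqrt(sum(w^2))
    t <- xd %*% w
    p <- crossprod(xd, t) / sum(t^2)
    wo <- p - c(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- xd %*% wo
    po <- crossprod(xd, to) / sum(to^2)
    xd <- xd - to %*% t(po)
    W_o <- cbind(W_o, wo)
    P_o <- cbind(P_o, po)
    T_o <- cbind(T_o, to)
  }
  w <- crossprod(xd, yc)
  w <- w / sqrt(sum(w^2))
  t <- xd %*% w
  p <- crossprod(xd, t) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(w = drop(w), p = drop(p), q = q, t = drop(t),
       W_o = W_o, P_o = P_o, T_o = T_o)
}

# Predict scores / response for new already-scaled data.
opls_core_predict <- function(core, xs_new) {
  xd <- xs_new
  n_o <- ncol(core$W_o)
  for (k in seq_len(n_o)) {
    to <- xd %*% core$W_o[, k]
    xd <- xd - to %*% t(core$P_o[, k])
  }
  t_pred <- drop(xd %*% core$w)
  list(t = t_pred, y = t_pred * core$q)
}

vip_from_weights <- function(w) {
  # single predictive component: VIP_j = sqrt(p) * |w_j| / ||w||
  sqrt(length(w) * w^2 / sum(w^2))
}

#' @export
predict.opls_model <- function(object, newdata, ...) {
  xs <- apply_scaling(object$scaling, as.matrix(newdata))
  core <- list(w = object$predictive_weights, q = object$q_coef,
               W_o = object$orthogonal_weights, P_o = object$orthogonal_loadings)
  pr <- opls_core_predict(core, xs)
  y_hat <- pr$y + object$y_mean
  neg <- setdiff(object$levels, object$positive)
  tibble(
    score = pr$t,
    y_hat = y_hat,
    class = ifelse(y_hat >= 0.5, object$positive, neg)
  )
}

#' Variable importance in projection
#'
#' VIP of each feature in a fitted OPLS-DA model, computed over the
#' predictive component: `VIP_j = sqrt(p * w_j^2 / sum(w^2))` with `p` the
#' feature count, so that the mean squared VIP is 1 and features with
#' VIP > 1 contribute more than average to the class separation.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @return Named numeric vector of nonnegative VIP scores.
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "opls_model")) abort("`model` must be an opls_model")
  model$vip
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' `Q2 = 1 - PRESS/TSS`, where PRESS accumulates squared errors of
#' held-out dummy-response predictions over seeded stratified folds and TSS
#' is the total sum of squares of the centered dummy response. Scaling and
#' the model are refitted inside every training fold.
#'
#' @inheritParams fit_oplsda
#' @param folds Number of stratified folds.
#' @return Q2 (scalar, at most 1; near or below 0 for uninformative models).
#' @export
cross_validated_q2 <- function(x, y, n_orthogonal = 1L, scaling = "pareto",
                               folds = 7L, seed = 1L, positive = NULL) {
  x <- as.matrix(x)
  yb <- code_binary(y, positive)
  cv_q2(x, yb$y01, as.integer(n_orthogonal), scaling, folds, seed)
}

cv_q2 <- function(x, y01, n_orthogonal, scaling, folds, seed) {
  fold_id <- stratified_folds(y01, folds, seed)
  press <- 0
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    sc <- fit_scaling(x[tr, , drop = FALSE], kind = scaling)
    xs_tr <- apply_scaling(sc, x[tr, , drop = FALSE])
    xs_te <- apply_scaling(sc, x[!tr, , drop = FALSE])
    ym <- mean(y01[tr])
    core <- opls_core(xs_tr, y01[tr] - ym, n_orthogonal)
    pred <- opls_core_predict(core, xs_te)$y + ym
    press <- press + sum((y01[!tr] - pred)^2)
  }
  tss <- sum((y01 - mean(y01))^2)
  1 - press / tss
}

choose_n_orthogonal <- function(x, y01, scaling, folds, seed, max_components = 5L) {
  best_k <- 0L
  best_q2 <- cv_q2(x, y01, 0L, scaling, folds, seed)
  for (k in seq_len(max_components)) {
    q2k <- cv_q2(x, y01, k, scaling, folds, seed)
    if (q2k > best_q2 + 0.01) {
      best_k <- k
      best_q2 <- q2k
    } else {
      break
    }
  }
  best_k
}

#' Permutation test for OPLS-DA overfitting
#'
#' Refits the OPLS-DA model on `n_permutations` random permutations of the
#' class labels and compares the permuted `R2Y` and `Q2` with the observed
#' values. The add-one estimator
#' `pQ2 = (#\{permuted Q2 >= observed Q2\} + 1) / (n_permutations + 1)`
#' (and likewise `pR2Y`) never reports zero; a model is declared overfit
#' when `pQ2 >= 0.05` — its apparent predictivity is not better than what
#' label-shuffled refits achieve.
#'
#' @inheritParams fit_oplsda
#' @param folds Cross-validation folds for each refit's Q2.
#' @param n_permutations Number of label permutations (default 1000).
#' @return An object of class `permutation_result`: `observed_r2y`,
#'   `observed_q2`, `permuted_r2y`, `permuted_q2` (length
#'   `n_permutations`), `p_r2y`, `p_q2`, `overfit`, `n_permutations`,
#'   `seed`.
#' @export
permutation_test <- function(x, y, n_orthogonal = 1L, scaling = "pareto",
                             folds = 7L, n_permutations = 1000L, seed = 1L,
                             positive = NULL) {
  x <- as.matrix(x)
  yb <- code_binary(y, positive)
  y01 <- yb$y01
  n_orthogonal <- as.integer(n_orthogonal)

  obs_q2 <- cv_q2(x, y01, n_orthogonal, scaling, folds, seed)
  obs_r2y <- full_fit_r2y(x, y01, n_orthogonal, scaling)

  perm_r2y <- numeric(n_permutations)
  perm_q2 <- numeric(n_permutations)
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      yp <- sample(y01)
      fold_seed <- derive_seed(seed, i)
      perm_q2[i] <- cv_q2(x, yp, n_orthogonal, scaling, folds, fold_seed)
      perm_r2y[i] <- full_fit_r2y(x, yp, n_orthogonal, scaling)
    }
  })

  p_q2 <- (sum(perm_q2 >= obs_q2) + 1) / (n_permutations + 1)
  p_r2y <- (sum(perm_r2y >= obs_r2y) + 1) / (n_permutations + 1)
  structure(
    list(observed_r2y = obs_r2y, observed_q2 = obs_q2,
         permuted_r2y = perm_r2y, permuted_q2 = perm_q2,
         p_r2y = p_r2y, p_q2 = p_q2, overfit = p_q2 >= 0.05,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed)),
    class = "permutation_result"
  )
}

full_fit_r2y <- function(x, y01, n_orthogonal, scaling) {
  sc <- fit_scaling(x, kind = scaling)
  xs <- apply_scaling(sc, x)
  yc <- y01 - mean(y01)
  core <- opls_core(xs, yc, n_orthogonal)
  1 - sum((yc - core$t * core$q)^2) / sum(yc^2)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s), %d features\n",
    x$n_orthogonal, length(x$vip)
  ))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f (%d-fold CV), positive class '%s'\n",
              x$r2y, x$q2, x$cv_folds, x$positive))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d permutations: pR2Y = %.4g, pQ2 = %.4g (%s)\n",
    x$n_permutations, x$p_r2y, x$p_q2,
    if (x$overfit) "overfit" else "not overfit"
  ))
  invisible(x)
}
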