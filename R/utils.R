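#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols group_by
#'   summarise ungroup across left_join pull rename n all_of any_of desc
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 imap list_rbind
#' @importFrom stats median sd prcomp wilcox.test p.adjust predict plogis
#'   quantile rnorm runif rbinom glm binomial coef setNames
#' @importFrom utils combn head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013904223L + as.integer(offset) * 7919L) %% 2147483562L
}

# Stratified k-fold assignment: returns an integer vector of fold ids, one
# per observation, with each class spread as evenly as possible over folds.
stratified_folds <- function(y, k, seed = NULL) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    abort(sprintf(
      "cannot build %d stratified folds: smallest class has %d member(s)",
      k, min(table(y))
    ))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

stopifnot_scalar_prob <- function(x, name, open0 = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  lo_ok <- if (open0) x > 0 else x >= 0
  if (!lo_ok || x > 1) {
    abort(sprintf("`%s` must lie in %s0, 1]", name, if (open0) "(" else "["))
  }
  invisible(x)
}
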