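# Independent oracles and small fixture builders used across the suite.
# Each oracle is implemented from the definition, never by calling the
# package function it checks.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(po[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# AUC as the normalized Mann-Whitney U statistic (midranks: ties count 1/2).
oracle_auc <- function(scores, y01) {
  r <- rank(scores)
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Youden-optimal threshold by direct scan of every observed threshold,
# with the same tie-breaks the package promises (higher specificity, then
# larger threshold).
oracle_youden <- function(scores, y01) {
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[y01 == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y01 == 0] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  max(thr[best])
}

# Single-component PLS1 by the NIPALS definition, for the
# zero-orthogonal-component limit of OPLS-DA.
oracle_pls1 <- function(xs, yc) {
  w <- crossprod(xs, yc)
  w <- w / sqrt(sum(w^2))
  t <- xs %*% w
  q <- sum(yc * t) / sum(t^2)
  list(w = drop(w), scores = drop(t), q = q)
}

# A tiny feature table with explicit values; samples s1..sk.
tiny_table <- function(values, rt = NULL, mz = NULL) {
  p <- nrow(values)
  k <- ncol(values)
  tbl <- data.frame(
    feature = sprintf("%d.1000_%d.2000", seq_len(p), 100 + seq_len(p)),
    check.names = FALSE
  )
  for (j in seq_len(k)) tbl[[paste0("s", j)]] <- values[, j]
  feature_table(tbl)
}

tiny_meta <- function(sample_ids, group, cohort = "discovery",
                      is_qc = NULL, ca125 = NA_real_) {
  sample_metadata(tibble::tibble(
    sample_id = sample_ids,
    group = group,
    cohort = cohort,
    batch = 1L,
    is_qc = is_qc %||% (group == "qc"),
    ca125 = ca125
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-group cohort with a known separable structure for classifier tests.
blob_data <- function(n_per = 20, p = 2, shift = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  y <- rep(c("a", "b"), each = n_per)
  x[y == "b", ] <- x[y == "b", ] + shift
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
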