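# Fixture: 10 biological samples + 4 QC injections, with features built to
# exercise each screening rule.
prep_fixture <- function() {
  # columns: s1..s10 biological, q1..q4 QC
  rows <- rbind(
    c(rep(100, 10), 100, 100, 100, 100),          # clean
    c(0, 0, rep(50, 8), 60, 60, 60, 60),          # 2/10 missing (20%)
    c(0, rep(80, 9), 90, 90, 90, 90),             # 1/10 missing (10%)
    c(rep(40, 10), 50, 100, 150, 0),              # QC CV 50% (3 QC values)
    c(rep(70, 10), 100, 100, 100, 0),             # QC CV 0 with 3 values
    c(rep(30, 10), 30, 30, 0, 0)                  # only 2 QC values
  )
  tbl <- tiny_table(rows)
  names(tbl)[4:17] <- c(paste0("s", 1:10), paste0("q", 1:4))
  meta <- tiny_meta(
    c(paste0("s", 1:10), paste0("q", 1:4)),
    group = c(rep("normal", 5), rep("malignant", 5), rep("qc", 4))
  )
  list(tbl = tbl, meta = meta)
}

test_that("missingness filter removes features missing in >= threshold of non-QC samples", {
  fx <- prep_fixture()
  out <- filter_by_missingness(fx$tbl, fx$meta, threshold = 0.20)
  expect_false(fx$tbl$feature[2] %in% out$feature)  # 20% missing: removed
  expect_true(fx$tbl$feature[3] %in% out$feature)   # 10% missing: retained
  expect_equal(attr(out, "n_removed"), 1L)

  clean <- tiny_table(matrix(c(1, 2, 3, 4), 2))
  meta2 <- tiny_meta(c("s1", "s2"), c("normal", "malignant"))
  expect_equal(nrow(filter_by_missingness(clean, meta2, 0.2)), 2)
})

test_that("QC CV filter uses strict inequality and a minimum-observation rule", {
  fx <- prep_fixture()
  out <- filter_by_qc_cv(fx$tbl, fx$meta, cv_threshold = 0.30)
  expect_true(fx$tbl$feature[1] %in% out$feature)   # CV 0
  expect_false(fx$tbl$feature[4] %in% out$feature)  # CV 50%
  expect_false(fx$tbl$feature[6] %in% out$feature)  # 2 QC values only
  expect_equal(attr(out, "n_insufficient_qc"), 1L)

  # CV exactly at the threshold is retained ("greater than" is strict):
  v <- c(70, 100, 130)  # mean 100, sample sd exactly 30 -> CV = 30.0%
  tbl <- tiny_table(matrix(c(rep(10, 2), v), nrow = 1))
  names(tbl)[4:8] <- c("s1", "s2", "q1", "q2", "q3")
  meta <- tiny_meta(c("s1", "s2", paste0("q", 1:3)),
                    c("normal", "malignant", rep("qc", 3)))
  expect_equal(nrow(filter_by_qc_cv(tbl, meta, 0.30)), 1)
  expect_error(filter_by_qc_cv(tbl, tiny_meta(c("s1", "s2"), c("normal", "malignant"))),
               "no QC samples")
})

test_that("half-minimum imputation fills zeros with half the feature minimum positive", {
  tbl <- tiny_table(matrix(c(0, 4, 8), nrow = 1))
  names(tbl)[4:6] <- paste0("s", 1:3)
  out <- impute_half_min(tbl)
  expect_equal(unname(unlist(out[1, 4:6])), c(2, 4, 8))

  no_zeros <- tiny_table(matrix(c(1, 2, 3, 4), 2))
  expect_equal(impute_half_min(no_zeros), no_zeros)

  all_zero <- tiny_table(matrix(c(0, 0, 0), nrow = 1))
  expect_error(impute_half_min(all_zero), "no positive intensity")
})

test_that("median normalization equalizes sample medians at the median of medians", {
  # two samples with medians 10 and 20 -> reference 15
  tbl <- tiny_table(matrix(c(5, 10, 15, 10, 20, 30), nrow = 3))
  out <- normalize_median(tbl)
  m <- intensity_matrix(out)
  expect_equal(unname(apply(m, 2, median)), c(15, 15))
  expect_equal(unname(m[, 1]), c(5, 10, 15) * 1.5)
  expect_equal(unname(m[, 2]), c(10, 20, 30) * 0.75)

  # three samples with medians 1, 10, 100 -> all medians become 10
  tbl3 <- tiny_table(matrix(c(0.5, 1, 2, 5, 10, 20, 50, 100, 200), nrow = 3))
  m3 <- intensity_matrix(normalize_median(tbl3))
  expect_equal(unname(apply(m3, 2, median)), c(10, 10, 10))

  same <- tiny_table(matrix(c(1, 2, 3, 1, 2, 3), nrow = 3))
  expect_equal(intensity_matrix(normalize_median(same)),
               intensity_matrix(same))
})

test_that("log2 transform requires strictly positive intensities", {
  tbl <- tiny_table(matrix(c(8, 1, 2, 4), 2))
  out <- log2_transform(tbl)
  expect_equal(unname(intensity_matrix(out)), matrix(c(3, 0, 1, 2), 2))
  withzero <- tiny_table(matrix(c(0, 1), nrow = 1))
  expect_error(log2_transform(withzero), "nonpositive")
})

test_that("QC RSD is sd/mean in percent, scale-invariant, and guards degenerate input", {
  fx <- prep_fixture()
  expect_equal(compute_rsd(fx$tbl, fx$meta, fx$tbl$feature[1]), 0)
  expect_equal(compute_rsd(fx$tbl, fx$meta, fx$tbl$feature[4]), 50)

  # scale invariance: multiplying QC intensities by c > 0 leaves RSD fixed
  scaled <- fx$tbl
  qc_cols <- paste0("q", 1:4)
  scaled[qc_cols] <- scaled[qc_cols] * 7.3
  expect_equal(compute_rsd(scaled, fx$meta, fx$tbl$feature[4]),
               compute_rsd(fx$tbl, fx$meta, fx$tbl$feature[4]))

  expect_error(compute_rsd(fx$tbl, fx$meta, "nope_1"), "not found")
  one_qc <- tiny_table(matrix(c(5, 5, 9, 0, 0), nrow = 1))
  names(one_qc)[4:8] <- c("s1", "s2", paste0("q", 1:3))
  meta <- tiny_meta(c("s1", "s2", paste0("q", 1:3)),
                    c("normal", "malignant", rep("qc", 3)))
  expect_error(compute_rsd(one_qc, meta, one_qc$feature[1]), "at least 2")
})

test_that("the pipeline applies stages in order and reports per-stage counts", {
  # constructed to lose exactly 1 feature to missingness, 1 to QC CV and
  # 1 to the insufficient-QC rule
  fx <- prep_fixture()
  res <- preprocess_pipeline(fx$tbl, fx$meta)
  rep_ <- res$report
  expect_equal(rep_$n_removed[rep_$stage == "missingness_filter"], 1L)
  expect_equal(rep_$n_removed[rep_$stage == "qc_cv_filter"], 1L)
  expect_equal(rep_$n_removed[rep_$stage == "qc_insufficient"], 1L)
  expect_equal(nrow(res$table), 3)

  # determinism: identical rerun gives an identical table
  res2 <- preprocess_pipeline(fx$tbl, fx$meta)
  expect_identical(res$table, res2$table)

  # medians on the pre-log scale agree with the reference to 1e-9 relative
  prelog <- intensity_matrix(res$table)
  med <- apply(2^prelog, 2, median)
  expect_lt(max(abs(med / median(med) - 1)), 1e-9)
})

test_that("imputation never changes which features pass the two filters", {
  sim <- simulate_cohort(cohort_spec(
    group_sizes = c(normal = 12, malignant = 12), n_features = 120,
    n_differential = 10, qc_count = 4, seed = 9
  ))
  f1 <- filter_by_missingness(sim$table, sim$meta, 0.2)
  f2 <- filter_by_qc_cv(f1, sim$meta, 0.3)
  imp <- impute_half_min(f2)
  # re-applying the missingness filter after imputation removes nothing
  f1b <- filter_by_missingness(imp, sim$meta, 0.2)
  expect_equal(f1b$feature, f2$feature)

  # imputed values equal exactly half the minimum positive, never more
  m_before <- intensity_matrix(f2)
  m_after <- intensity_matrix(imp)
  zeros <- m_before == 0
  if (any(zeros)) {
    halfmin <- apply(m_before, 1, function(v) min(v[v > 0]) / 2)
    filled <- m_after * zeros
    expect_true(all(abs(filled[zeros] -
                          rep(halfmin, ncol(m_before))[as.vector(zeros)]) < 1e-12))
  }
})
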