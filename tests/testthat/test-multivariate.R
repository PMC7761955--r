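test_that("pareto and unit-variance scaling match hand-computed values", {
  x <- matrix(c(1, 3), 2, 1)
  sc_p <- fit_scaling(x, "pareto")
  expect_equal(unname(apply_scaling(sc_p, x)[, 1]),
               c(-0.84090, 0.84090), tolerance = 1e-4)
  sc_u <- fit_scaling(x, "unit_variance")
  expect_equal(unname(apply_scaling(sc_u, x)[, 1]),
               c(-0.70711, 0.70711), tolerance = 1e-4)
  sc_n <- fit_scaling(x, "none", center = FALSE)
  expect_equal(apply_scaling(sc_n, x), x)
  expect_error(fit_scaling(cbind(x, c(5, 5)), "pareto"), "constant")
})

test_that("scaling is fitted on training data and applied unchanged to new data", {
  set.seed(2)
  tr <- matrix(rnorm(20), 10, 2)
  te <- matrix(rnorm(6), 3, 2)
  sc <- fit_scaling(tr, "unit_variance")
  expect_equal(apply_scaling(sc, te),
               sweep(sweep(te, 2, colMeans(tr)), 2, apply(tr, 2, sd), `/`))
})

test_that("PCA returns orthonormal loadings and complete reconstruction", {
  # collinear two-feature data: first component carries all variance
  x <- cbind(1:6, 2 * (1:6))
  p <- fit_pca(x, n_components = 1, kind = "none")
  expect_equal(p$explained_variance[1], 1)

  set.seed(3)
  x2 <- matrix(rnorm(100), 20, 5)
  p2 <- fit_pca(x2, n_components = 5, kind = "unit_variance")
  expect_equal(crossprod(p2$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p2$explained_variance) <= 1e-12))
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(recon, apply_scaling(p2$scaling, x2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(x2, n_components = 10), "exceeds")
})

test_that("OPLS-DA with zero orthogonal components is exactly PLS1", {
  set.seed(4)
  x <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(c(0, 1), each = 10)
  m <- fit_oplsda(x, y, n_orthogonal = 0, scaling = "pareto", seed = 1)
  sc <- fit_scaling(x, "pareto")
  pls <- oracle_pls1(apply_scaling(sc, x), y - mean(y))
  # same up to sign
  s <- sign(sum(m$predictive_scores * pls$scores))
  expect_equal(m$predictive_scores, s * pls$scores, tolerance = 1e-8)
  expect_equal(unname(m$predictive_weights), s * pls$w, tolerance = 1e-8)
})

test_that("a noiseless class-coding feature yields near-perfect R2Y and Q2", {
  set.seed(5)
  x <- cbind(rep(c(0, 1), each = 20), matrix(rnorm(40 * 5, 0, 0.3), 40, 5))
  colnames(x) <- paste0("f", 1:6)
  y <- rep(c("ctl", "case"), each = 20)
  m <- fit_oplsda(x, y, n_orthogonal = 1, seed = 2, positive = "case")
  expect_gte(m$r2y, 0.99)
  expect_gte(m$q2, 0.9)
  expect_equal(names(which.max(m$vip)), "f1")
  expect_error(fit_oplsda(x, rep("case", 40)), "2 classes")
})

test_that("predictive and orthogonal scores are orthogonal and the positive class scores high", {
  set.seed(6)
  x <- matrix(rnorm(30 * 12), 30, 12)
  y <- rep(c("a", "b"), 15)
  x[y == "b", 1:3] <- x[y == "b", 1:3] + 1.5
  m <- fit_oplsda(x, y, n_orthogonal = 2, seed = 3)
  for (k in seq_len(ncol(m$orthogonal_scores))) {
    expect_lt(abs(sum(m$predictive_scores * m$orthogonal_scores[, k])), 1e-8)
  }
  expect_gt(mean(m$predictive_scores[y == "b"]),
            mean(m$predictive_scores[y == "a"]))
})

test_that("VIP has unit mean square and ranks symmetric features equally", {
  # two features with identical weights get identical VIP of 1
  x <- cbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6) + 1e-9)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_oplsda(x, y, n_orthogonal = 0, scaling = "unit_variance",
                  cv_folds = 3, seed = 1)
  expect_equal(unname(m$vip), c(1, 1), tolerance = 1e-6)
  expect_equal(sum(m$vip^2), 2, tolerance = 1e-10)
})

test_that("Q2 detects a noiseless linear rule and stays low under the null", {
  set.seed(7)
  x <- cbind(rep(c(-1, 1), each = 14), matrix(rnorm(28 * 4, 0, 0.3), 28, 4))
  y <- rep(c(0, 1), each = 14)
  expect_gte(cross_validated_q2(x, y, n_orthogonal = 0, folds = 7, seed = 1), 0.9)

  # null: 200 features, n = 40, Q2 <= 0.2 in at least 95 of 100 repetitions
  low <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    xn <- matrix(rnorm(40 * 200), 40, 200)
    yn <- rep(c(0, 1), each = 20)
    cross_validated_q2(xn, yn, n_orthogonal = 1, folds = 7, seed = i) <= 0.2
  }, logical(1))
  expect_gte(sum(low), 95)

  expect_error(cross_validated_q2(matrix(rnorm(12), 6), rep(0:1, each = 3),
                                  folds = 7), "folds")
})

test_that("Q2 is invariant to label swap and feature order", {
  set.seed(8)
  x <- matrix(rnorm(24 * 8), 24, 8)
  y <- rep(c(0, 1), each = 12)
  q <- cross_validated_q2(x, y, n_orthogonal = 1, folds = 4, seed = 5)
  expect_equal(cross_validated_q2(x, 1 - y, n_orthogonal = 1, folds = 4,
                                  seed = 5, positive = "0"), q)
  perm <- sample(8)
  expect_equal(cross_validated_q2(x[, perm], y, n_orthogonal = 1, folds = 4,
                                  seed = 5), q)
})

test_that("the permutation test is seeded, bounded below, and exact on separable data", {
  set.seed(9)
  x <- cbind(rep(c(0, 1), each = 20), matrix(rnorm(40 * 3), 40, 3))
  y <- rep(c(0, 1), each = 20)
  pt <- permutation_test(x, y, n_orthogonal = 0, folds = 5,
                         n_permutations = 199, seed = 11)
  # no permutation can reach the noiseless observed Q2
  expect_equal(pt$p_q2, 1 / 200)
  expect_false(pt$overfit)
  expect_gte(pt$p_q2, 1 / (pt$n_permutations + 1))

  pt2 <- permutation_test(x, y, n_orthogonal = 0, folds = 5,
                          n_permutations = 199, seed = 11)
  expect_identical(pt$permuted_q2, pt2$permuted_q2)
  expect_identical(pt$p_q2, pt2$p_q2)
})

test_that("tidy and glance return the documented shapes", {
  d <- blob_data(10, 3)
  m <- fit_oplsda(d$x, d$y, n_orthogonal = 1, cv_folds = 5, seed = 1)
  td <- tidy(m)
  expect_named(td, c("feature", "weight", "loading", "vip"))
  expect_equal(nrow(td), 3)
  g <- glance(m)
  expect_equal(g$n_orthogonal, 1L)
  expect_s3_class(autoplot(m), "ggplot")
})
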