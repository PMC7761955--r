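test_that("the SVM separates well-separated blobs and refits reproducibly", {
  d <- blob_data(20, 2, shift = 3, seed = 1)
  m <- train_svm(d$x, d$y, gamma = 0.1, cost = 100, seed = 7)
  m <- set_cutoff(m, 0.5)
  expect_equal(mean(predict(m, d$x, type = "class") == d$y), 1.0)

  m2 <- train_svm(d$x, d$y, gamma = 0.1, cost = 100, seed = 7)
  expect_identical(predict(m, d$x, type = "probability"),
                   predict(m2, d$x, type = "probability"))

  expect_error(train_svm(d$x, rep("a", nrow(d$x)), seed = 1), "2 classes")
  bad <- d$x; bad[1, 1] <- NA
  expect_error(train_svm(bad, d$y), "non-finite")
})

test_that("ROC sensitivity/specificity and AUC match direct counting", {
  r <- roc_curve(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0), positive = "1")
  expect_equal(r$auc, 0.75)  # 3 of 4 concordant pairs

  perfect <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = "1")
  expect_equal(perfect$auc, 1.0)
  expect_true(all(diff(perfect$sensitivity) <= 1e-12))  # nonincreasing in threshold

  # rank-statistic oracle on random score vectors, including heavy ties
  set.seed(12)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_curve(scores, y, positive = "1")$auc,
                 oracle_auc(scores, y))
  }
  expect_error(roc_curve(1:4, rep(1, 4)), "2 classes")
})

test_that("the Youden cutoff matches an exhaustive threshold scan", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.75, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  r <- roc_curve(scores, y, positive = "1")
  cut <- optimal_cutoff(r)
  expect_equal(cut, 0.6)  # sens 1.0, spec 0.75, Youden 0.75
  expect_equal(cut, oracle_youden(scores, y))

  # perfect separation: the larger observed threshold in the gap wins
  r2 <- roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0), positive = "1")
  expect_equal(optimal_cutoff(r2), 5)

  expect_error(optimal_cutoff(roc_curve(rep(2, 6), rep(c(0, 1), 3),
                                        positive = "1")),
               "degenerate")
})

test_that("evaluation applies the frozen model and cutoff without re-estimation", {
  d <- blob_data(25, 3, shift = 2, seed = 3)
  m <- train_svm(d$x, d$y, gamma = 0.1, cost = 10, seed = 5)
  prob <- predict(m, d$x, type = "probability")
  roc <- roc_curve(prob, d$y, positive = "b")
  m <- set_cutoff(m, optimal_cutoff(roc))
  ev <- evaluate_panel(m, d$x, d$y, cohort = "discovery")

  # self-consistency with the cutoff-selection scan
  idx <- which(roc$thresholds == m$probability_cutoff)
  expect_equal(ev$sensitivity, roc$sensitivity[idx])
  expect_equal(ev$specificity, roc$specificity[idx])
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, nrow(d$x))

  # the frozen model is unchanged by evaluating other data
  d2 <- blob_data(25, 3, shift = 2, seed = 4)
  before <- m$scaling
  invisible(evaluate_panel(m, d2$x, d2$y))
  expect_identical(m$scaling, before)
  expect_error(evaluate_panel(m, d$x, d$y, subset = rep(FALSE, nrow(d$x))),
               "no samples")
})

test_that("panel search equals brute-force enumeration within budget", {
  # an XOR-style pair: only {f1, f2} jointly separates the classes
  set.seed(13)
  n <- 40
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.5)
  y <- ifelse(xor(a == 1, b == 1), "case", "ctl")
  x <- cbind(f1 = a + rnorm(n, 0, 0.1), f2 = b + rnorm(n, 0, 0.1),
             f3 = rnorm(n), f4 = rnorm(n))
  res <- exhaustive_panel_search(colnames(x), x, y, max_panel_size = 2,
                                 folds = 4, gamma = 1, cost = 10, seed = 9,
                                 positive = "case")
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_subsets_evaluated, 10)  # C(4,1) + C(4,2)
  expect_setequal(res$panel, c("f1", "f2"))
  # agrees with explicit enumeration over the same folds and scorer
  fold_id <- metabopanel:::stratified_folds(
    as.numeric(factor(y) == "case"), 4, metabopanel:::derive_seed(9, 101L))
  subsets <- c(lapply(1:4, function(i) colnames(x)[i]),
               combn(colnames(x), 2, simplify = FALSE))
  scores <- vapply(subsets, function(s) {
    metabopanel:::cv_panel_auc(x, as.numeric(factor(y) == "case"), s,
                               fold_id, gamma = 1, cost = 10)
  }, numeric(1))
  expect_equal(sort(res$panel), sort(subsets[[which.max(scores)]]))
  expect_equal(res$cv_auc, max(scores))

  single <- exhaustive_panel_search("f1", x, y, max_panel_size = 3,
                                    folds = 4, seed = 1, positive = "case")
  expect_equal(single$panel, "f1")
  expect_error(exhaustive_panel_search(character(0), x, y), "no candidate")
})

test_that("the greedy fallback triggers beyond the budget and is recorded", {
  d <- blob_data(15, 6, shift = 1, seed = 5)
  res <- exhaustive_panel_search(colnames(d$x), d$x, d$y, max_panel_size = 3,
                                 folds = 3, seed = 2, budget = 10,
                                 positive = "b")
  expect_equal(res$method, "greedy_forward")
  expect_lte(length(res$panel), 3)
  # deterministic rerun
  res2 <- exhaustive_panel_search(colnames(d$x), d$x, d$y, max_panel_size = 3,
                                  folds = 3, seed = 2, budget = 10,
                                  positive = "b")
  expect_identical(res$panel, res2$panel)
  expect_identical(res$cv_auc, res2$cv_auc)
})

test_that("a hybrid model uses the clinical marker and surfaces degenerate input", {
  set.seed(14)
  n <- 30
  y <- rep(c("benign", "malignant"), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  marker <- ifelse(y == "malignant", 500, 10) * exp(rnorm(n, 0, 0.1))
  hm <- hybrid_model(x, marker, y, gamma = 0.1, cost = 10, seed = 3,
                     positive = "malignant")
  xm <- hybrid_matrix(hm, x, marker)
  prob <- predict(hm, xm, type = "probability")
  expect_equal(roc_curve(prob, y, positive = "malignant")$auc, 1.0)

  expect_error(hybrid_model(x, rep(NA_real_, n), y), "missing for all")
  expect_error(hybrid_model(x, rep(3, n), y, positive = "malignant"),
               "constant")

  # missing markers are excluded with a count
  marker2 <- marker; marker2[1:3] <- NA
  hm2 <- hybrid_model(x, marker2, y, positive = "malignant")
  expect_equal(hm2$n_excluded_missing_marker, 3)
})

test_that("a raw clinical marker ROC supports Youden and fixed cutoffs", {
  y <- rep(c(0, 1), each = 10)
  meta <- tibble::tibble(sample_id = as.character(1:20),
                         ca125 = c(seq(5, 32, length.out = 10),
                                   seq(20, 400, length.out = 10)))
  mk <- clinical_marker_roc(meta, y, "ca125", fixed_cutoff = 35, positive = "1")
  # hand tally at cutoff 35: positives >= 35, negatives < 35
  expect_equal(mk$sensitivity, mean(meta$ca125[11:20] >= 35))
  expect_equal(mk$specificity, mean(meta$ca125[1:10] < 35))

  ident <- clinical_marker_roc(tibble::tibble(ca125 = y + 0.0), y, "ca125",
                               positive = "1")
  expect_equal(ident$auc, 1.0)

  # marker independent of class: AUC near 0.5
  set.seed(15)
  y2 <- rbinom(500, 1, 0.5)
  meta2 <- tibble::tibble(ca125 = rlnorm(500, 3, 1))
  null_mk <- clinical_marker_roc(meta2, y2, "ca125", positive = "1")
  expect_lt(abs(null_mk$auc - 0.5), 0.08)

  expect_error(clinical_marker_roc(tibble::tibble(ca125 = NA_real_), 1, "ca125"),
               "missing for all")
})
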