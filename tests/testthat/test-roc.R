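test_that("perfect and degenerate score sets give textbook ROC results", {
  r <- compute_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$best_sensitivity$value, 1.0)
  expect_equal(r$best_specificity$value, 1.0)
  # pure ties: chance performance
  expect_equal(compute_roc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(compute_roc(1:4, rep(1, 4)), "degenerate labels")
  expect_error(compute_roc(c(1, NA, 3), c(0, 1, 1)), "finite")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  # hand case: 7 wins of 9 positive-negative pairs
  r <- compute_roc(c(3, 1, 2, 5, 4, 0), c(1, 0, 1, 1, 0, 0))
  expect_equal(r$auc, 7 / 9)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(c(0, 1, 3), 1))  # induce ties sometimes
    expect_equal(compute_roc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("reversing scores mirrors the AUC", {
  set.seed(23)
  for (i in 1:10) {
    scores <- rnorm(30)
    labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
    expect_equal(compute_roc(scores, labels)$auc +
                 compute_roc(-scores, labels)$auc, 1)
  }
})

test_that("DeLong interval brackets the estimate and narrows with n", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(n)
    scores <- c(rnorm(n / 2, 1), rnorm(n / 2, 0))
    labels <- rep(c(1, 0), each = n / 2)
    r <- compute_roc(scores, labels)
    expect_gte(r$auc, r$auc_ci95["lo"])
    expect_lte(r$auc, r$auc_ci95["hi"])
    unname(r$auc_ci95["hi"] - r$auc_ci95["lo"])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the Youden cutoff is an observed score or the Inf sentinel", {
  set.seed(31)
  for (i in 1:10) {
    scores <- round(rnorm(40), 1)
    labels <- c(0, 1, sample(0:1, 38, replace = TRUE))
    r <- compute_roc(scores, labels)
    expect_true(r$best_cutoff %in% c(scores, Inf))
    j <- r$sens_spec_points[, 1] + r$sens_spec_points[, 2] - 1
    expect_equal(r$best_sensitivity$value + r$best_specificity$value - 1,
                 max(j))
    # CI bounds are proper proportions around the point estimates
    expect_gte(r$best_sensitivity$value, r$best_sensitivity$ci95[1])
    expect_lte(r$best_sensitivity$value, r$best_sensitivity$ci95[2])
  }
})

test_that("ROC points are monotone along the threshold sweep", {
  set.seed(37)
  scores <- rnorm(60); labels <- c(0, 1, sample(0:1, 58, replace = TRUE))
  r <- compute_roc(scores, labels)
  expect_true(all(diff(r$sens_spec_points[, "sensitivity"]) >= 0))
  expect_true(all(diff(r$sens_spec_points[, "specificity"]) <= 0))
  expect_true(all(diff(r$thresholds) < 0))
})
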