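test_that("confusion metrics follow their definitions and NA on 0/0", {
  m <- confusion_metrics(TP = 50, FP = 0, FN = 5, TN = 45)
  expect_equal(m$accuracy, 0.95)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 10 / 11)
  expect_equal(m$specificity, 1)
  expect_equal(m$f1, 20 / 21)
  expect_equal(m$npv, 0.9)
  expect_equal(m$fdr, 0)
  expect_equal(m$fpr, 0)
  expect_equal(m$fnr, 1 / 11)

  perfect <- confusion_metrics(10, 0, 0, 10)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  degenerate <- confusion_metrics(0, 3, 0, 7)
  expect_true(is.na(degenerate$sensitivity))   # TP + FN = 0
  expect_true(is.na(degenerate$fnr))
})

test_that("complementary metric identities hold on random contingencies", {
  set.seed(8)
  for (i in 1:25) {
    cts <- rmultinom(1, 200, runif(4, 0.05, 1))
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    if (!is.na(m$precision)) expect_equal(m$fdr + m$precision, 1)
    if (!is.na(m$specificity)) expect_equal(m$fpr + m$specificity, 1)
  }
})

test_that("rank AUC agrees with pairwise counting and pROC", {
  y <- c(0, 0, 1, 1, 1, 0)
  p <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.8)
  # O(n^2) pairwise oracle with half-credit ties
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  oracle <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                        ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  expect_equal(roc_auc(y, p), oracle)
  expect_equal(roc_auc(c(0, 1), c(0.1, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "classes")
  set.seed(9)
  y2 <- rbinom(60, 1, 0.5); p2 <- runif(60)
  expect_equal(roc_auc(y2, p2),
               as.numeric(pROC::auc(pROC::roc(y2, p2, quiet = TRUE,
                                              direction = "<"))))
})

test_that("Brier score evaluates its closed form", {
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.25)
  expect_equal(brier_score(c(1, 0, 1, 1), c(0.9, 0.1, 0.8, 0.6)), 0.055)
})

test_that("expected calibration error averages per-bin gaps", {
  y <- c(1, 1, 1, 0, 0)
  p <- rep(0.8, 5)                 # one bin: mean p 0.8, rate 0.6
  expect_equal(ece(y, p), 0.2)
  expect_equal(ece(y, p, weighted = TRUE), 0.2)
  # perfectly calibrated within bins
  y2 <- c(rep(1, 2), rep(0, 8), rep(1, 9), rep(0, 1))
  p2 <- c(rep(0.2, 10), rep(0.9, 10))
  expect_equal(ece(y2, p2), 0)
  set.seed(10)
  e <- ece(rbinom(100, 1, 0.5), runif(100))
  expect_gte(e, 0); expect_lte(e, 1)
  cc <- calibration_curve(y2, p2)
  expect_equal(cc$obs_rate, c(0.2, 0.9))
})

test_that("calibration slope recovers the logit scaling", {
  set.seed(14)
  x <- rnorm(4000)
  eta <- 1.5 * x
  y <- rbinom(4000, 1, plogis(eta))
  expect_equal(calibration_slope(y, plogis(eta)), 1, tolerance = 0.1)
  expect_equal(calibration_slope(y, plogis(2 * eta)), 0.5, tolerance = 0.1)
  expect_equal(calibration_slope(y, plogis(eta / 2)), 2, tolerance = 0.2)
})

test_that("paired t-test matches hand values and degenerate contracts", {
  a <- c(2, 3, 4); b <- c(1, 1, 1)      # differences 1, 2, 3
  res <- paired_t_test(a, b)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  swapped <- paired_t_test(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_equal(paired_t_test(a, a), list(t = 0, p = 1))
  expect_warning(z <- paired_t_test(c(1, 2), c(0, 1)), "zero-variance")
  expect_equal(z$p, 0)
})

test_that("the calibrated oracle has the lowest Brier score (propriety)", {
  set.seed(15)
  p_true <- runif(3000)
  y <- rbinom(3000, 1, p_true)
  b0 <- brier_score(y, p_true)
  expect_lt(b0, brier_score(y, p_true^2))
  expect_lt(b0, brier_score(y, sqrt(p_true)))
  expect_lt(b0, brier_score(y, pmin(pmax(p_true * 1.5 - 0.25, 0), 1)))
})

test_that("nested CV stratifies folds, excludes synthetic rows, and aggregates recomputably", {
  ds <- generate_dataset(synthetic_spec(n_samples = 150, seed = 23))
  plan <- cv_plan(outer_folds = 5, inner_folds = 3, repeats = 1, seed = 23)
  rep_ <- nested_cv(ds, plan, fast_pipeline_config(seed = 23))
  # every row predicted exactly once per repeat
  expect_equal(nrow(rep_$predictions), 150)
  # stratification: fold class proportions within +/-1 positive sample
  n_pos <- sum(ds$labels)
  for (k in 1:5) {
    fold_y <- rep_$predictions$y_true[rep_$predictions$fold == k]
    expected <- n_pos * length(fold_y) / 150
    expect_lte(abs(sum(fold_y) - expected), 1 + 1e-9)
  }
  # aggregation is recomputable from the per-fold table
  s <- rep_$summary
  expect_equal(s$mean[s$metric == "auc"], mean(rep_$per_fold$auc))
  expect_equal(s$sd[s$metric == "accuracy"], sd(rep_$per_fold$accuracy))
  expect_equal(nrow(rep_$per_repeat), 1)
  # report writer emits the CSV/JSON artifact set
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  expect_true(all(file.exists(file.path(dir,
    c("summary.csv", "per_fold.csv", "calibration.csv", "report.json")))))
})
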