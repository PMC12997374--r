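#' Cross-validation plan
#'
#' @param outer_folds stratified outer folds (generalisation estimate only).
#' @param inner_folds stratified inner folds (feature selection and tuning).
#' @param repeats independent repetitions of the whole nested scheme.
#' @param seed integer RNG seed.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(outer_folds = 5, inner_folds = 3, repeats = 10,
                    seed = 1) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, repeats >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Confusion-matrix metrics
#'
#' The nine standard screening metrics from the confusion counts.  Ratios
#' with a zero denominator are reported as `NA`, never as 0.
#'
#' @param TP,FP,FN,TN confusion counts.
#' @return Named list: accuracy, precision (PPV), sensitivity, specificity,
#'   f1, npv, fdr, fpr, fnr.
#' @export
confusion_metrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0, TP + FP + FN + TN > 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(TP, TP + FP)
  recall <- div(TP, TP + FN)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = div(TP + TN, TP + TN + FP + FN),
       precision = precision,
       sensitivity = recall,
       specificity = div(TN, TN + FP),
       f1 = f1,
       npv = div(TN, TN + FN),
       fdr = div(FP, TP + FP),
       fpr = div(FP, FP + TN),
       fnr = div(FN, TP + FN))
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with midrank tie correction.
#'
#' @param y_true 0/1 labels.
#' @param p_hat predicted positive-class scores.
#' @return The AUC.
#' @export
roc_auc <- function(y_true, p_hat) {
  stopifnot(length(y_true) == length(p_hat))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(p_hat)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better.
#'
#' @inheritParams roc_auc
#' @return The Brier score.
#' @export
brier_score <- function(y_true, p_hat) {
  stopifnot(length(y_true) == length(p_hat), length(y_true) > 0)
  mean((y_true - p_hat)^2)
}

#' Expected calibration error
#'
#' Predictions are grouped into `K` equal-width probability bins; within
#' each nonempty bin the absolute gap between the mean predicted
#' probability and the empirical positive rate is taken, and the gaps are
#' averaged over nonempty bins (or weighted by bin occupancy when
#' `weighted = TRUE`).
#'
#' @inheritParams roc_auc
#' @param K number of bins (default 10).
#' @param weighted weight bins by occupancy instead of averaging equally.
#' @return The ECE, in [0,1].
#' @export
ece <- function(y_true, p_hat, K = 10, weighted = FALSE) {
  stopifnot(K >= 1, length(y_true) == length(p_hat))
  bin <- pmin(pmax(ceiling(p_hat * K), 1L), K)
  gaps <- w <- numeric(0)
  for (k in unique(bin)) {
    idx <- bin == k
    gaps <- c(gaps, abs(mean(p_hat[idx]) - mean(y_true[idx])))
    w <- c(w, sum(idx))
  }
  if (weighted) sum(gaps * w) / sum(w) else mean(gaps)
}

#' Calibration-curve bin table
#'
#' @inheritParams ece
#' @return data.frame with bin index, count, mean predicted probability and
#'   observed positive rate for each nonempty bin.
#' @export
calibration_curve <- function(y_true, p_hat, K = 10) {
  bin <- pmin(pmax(ceiling(p_hat * K), 1L), K)
  do.call(rbind, lapply(sort(unique(bin)), function(k) {
    idx <- bin == k
    data.frame(bin = k, n = sum(idx), mean_pred = mean(p_hat[idx]),
               obs_rate = mean(y_true[idx]))
  }))
}

#' Calibration slope
#'
#' Slope of the logistic recalibration of the outcome on the logit of the
#' predicted probability (clipped at 1e-6).  1 indicates neither over- nor
#' under-confidence; below 1, overconfident; above 1, underconfident.
#'
#' @inheritParams roc_auc
#' @param clip probability clipping bound before the logit transform.
#' @return The slope, or `NA` with a warning when the refit fails.
#' @export
calibration_slope <- function(y_true, p_hat, clip = 1e-6) {
  lp <- stats::qlogis(pmin(pmax(p_hat, clip), 1 - clip))
  fit <- tryCatch(
    suppressWarnings(stats::glm(y_true ~ lp, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("calibration refit did not converge; slope reported as NA")
    return(NA_real_)
  }
  unname(stats::coef(fit)[2])
}

#' Paired t-test on matched performance vectors
#'
#' Two-sided paired t-test on the differences.  Degenerate cases follow the
#' screening convention: identical vectors give `p = 1`; zero-variance
#' differences with nonzero mean give `p = 0` with a warning.
#'
#' @param acc_a,acc_b equal-length numeric vectors (length >= 2).
#' @return list with `t` and `p`.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2)
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    warning("zero-variance nonzero-mean differences; p reported as 0")
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' All fold-level metrics for one prediction set
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold for the confusion metrics.
#' @param ece_bins number of ECE bins.
#' @return Named list of the nine confusion metrics plus auc, brier, ece
#'   and calibration slope.
#' @export
prediction_metrics <- function(y_true, p_hat, threshold = 0.5,
                               ece_bins = 10) {
  pred <- as.integer(p_hat > threshold)
  cm <- confusion_metrics(TP = sum(pred == 1 & y_true == 1),
                          FP = sum(pred == 1 & y_true == 0),
                          FN = sum(pred == 0 & y_true == 1),
                          TN = sum(pred == 0 & y_true == 0))
  c(cm, list(auc = roc_auc(y_true, p_hat),
             brier = brier_score(y_true, p_hat),
             ece = ece(y_true, p_hat, ece_bins),
             cal_slope = suppressWarnings(
               calibration_slope(y_true, p_hat))))
}

#' Nested stratified cross-validated evaluation of the full pipeline
#'
#' For every repeat and outer fold: fit the preprocessing state on the
#' outer-training rows only, validate categories, remove numeric outliers,
#' oversample the training minority with SMOTE, and standardise/encode;
#' select features by spiral-search gravitational search against an
#' inner-fold surrogate error; optionally tune the network hyperparameters
#' by elephant herding against inner-fold MSE; train the final deep belief
#' network on the outer-training rows and predict the untouched outer-test
#' rows.  Outer folds measure generalisation only; synthetic rows never
#' enter a test split (asserted).
#'
#' @param ds a [tabular_dataset()] (already row-filtered; the
#'   high-missingness filter is a one-off applied to the raw file).
#' @param plan a [cv_plan()].
#' @param cfg pipeline configuration list; see [pipeline_config()].
#' @return An object of class `evaluation_report`: `per_fold` metric
#'   data.frame, `predictions`, `summary` (metric, mean, sd over all
#'   fold-by-repeat results), `per_repeat` calibration rows, and the
#'   selected masks per fold.
#' @export
nested_cv <- function(ds, plan = cv_plan(), cfg = pipeline_config()) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(plan, "cv_plan"))
  if (min(table(ds$labels)) < plan$outer_folds)
    stop("each class needs at least outer_folds members")
  per_fold <- list(); preds <- list(); masks <- list()
  for (r in seq_len(plan$repeats)) {
    rseed <- plan$seed + 1000L * (r - 1L)
    set.seed(rseed)
    folds <- caret::createFolds(factor(ds$labels), k = plan$outer_folds)
    for (k in seq_along(folds)) {
      test_idx <- folds[[k]]
      fit <- fit_fold_model(ds_rows(ds, -test_idx), plan, cfg,
                            seed = rseed + k)
      test_ds <- validate_categories(ds_rows(ds, test_idx), fit$state)
      stopifnot(!any(test_ds$synthetic))      # leakage sentinel
      enc_test <- transform_dataset(test_ds, fit$state)
      p <- predict_proba(fit$model,
                         enc_test$X[, fit$keep, drop = FALSE])[, 2]
      m <- prediction_metrics(test_ds$labels, p, cfg$threshold,
                              cfg$ece_bins)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(repeat_ = r, fold = k, as.data.frame(m))
      preds[[length(preds) + 1L]] <-
        data.frame(repeat_ = r, fold = k, y_true = test_ds$labels,
                   p_hat = p)
      masks[[length(masks) + 1L]] <- fit$mask
    }
  }
  per_fold <- do.call(rbind, per_fold)
  preds <- do.call(rbind, preds)
  metric_cols <- setdiff(names(per_fold), c("repeat_", "fold"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols,
                  function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols,
                function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  per_repeat <- do.call(rbind, lapply(split(preds, preds$repeat_),
    function(pr) data.frame(
      repeat_ = pr$repeat_[1],
      brier = brier_score(pr$y_true, pr$p_hat),
      ece = ece(pr$y_true, pr$p_hat, cfg$ece_bins),
      cal_slope = suppressWarnings(
        calibration_slope(pr$y_true, pr$p_hat)))))
  rownames(per_repeat) <- NULL
  structure(list(per_fold = per_fold, predictions = preds,
                 summary = summary, per_repeat = per_repeat, masks = masks,
                 plan = plan),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d outer folds x %d repeats\n",
              x$plan$outer_folds, x$plan$repeats))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Write an evaluation report to CSV/JSON
#'
#' @param report an [nested_cv()] report.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_fold, file.path(dir, "per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_repeat, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(calibration_curve(report$predictions$y_true,
                                     report$predictions$p_hat),
                   file.path(dir, "calibration_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, per_repeat = report$per_repeat),
    file.path(dir, "report.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}
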