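test_that("imputation statistics follow the mode/median definitions", {
  ds <- tiny_dataset()
  st <- fit_preprocessor(ds)
  expect_equal(st$modes$htn, "yes")          # majority category
  expect_equal(st$medians$age, 30)           # odd observed count
  expect_equal(st$medians$hb, 3)             # 5 observed values
  # even-count branch
  ds2 <- ds_rows(ds, 1:4)
  expect_equal(fit_preprocessor(ds2)$medians$age, 25)
  # tie broken by lexicographically smallest category
  ds$values$rbc <- c("normal", "abnormal", "normal", "abnormal", NA, NA)
  expect_equal(fit_preprocessor(ds)$modes$rbc, "abnormal")
})

test_that("an all-missing column is reported by name", {
  ds <- tiny_dataset()
  ds$values$hb <- NA_real_
  expect_error(fit_preprocessor(ds), "hb")
})

test_that("row filter uses >= threshold*m over the 24 non-label attributes", {
  ds <- wide_dataset(n = 3, m = 24, missing_per_row = c(12, 11, 0))
  res <- filter_high_missing_rows(ds, 0.5)
  expect_equal(res$removed, 1)               # 12 >= 12 removed, 11 < 12 kept
  expect_equal(nrow(res$dataset$values), 2)
})

test_that("category validation repairs case/whitespace and blanks the rest", {
  ds <- tiny_dataset()
  st <- fit_preprocessor(ds)
  ds$values$htn[1] <- "unknown"
  ds$values$htn[2] <- "yes"
  ds$values$rbc[1] <- "Normal "
  out <- validate_categories(ds, st)
  expect_true(is.na(out$values$htn[1]))
  expect_equal(out$values$htn[2], "yes")
  expect_equal(out$values$rbc[1], "normal")
})

test_that("Z-score outlier removal drops rows under training statistics", {
  train <- wide_dataset(n = 3, m = 2)
  train$values$f01 <- c(-1, 0, 1)            # mean 0, sd 1
  train$values$f02 <- c(5, 5, 5)             # constant: sigma = 0
  st <- fit_preprocessor(train)
  test <- wide_dataset(n = 3, m = 2)
  test$values$f01 <- c(0, 3.5, -2.9)         # |z| = 0, 3.5, 2.9
  test$values$f02 <- c(100, 5, 5)            # constant column never triggers
  out <- remove_numeric_outliers(test, st, z_cut = 3)
  expect_equal(nrow(out$values), 2)
  expect_equal(out$values$f01, c(0, -2.9))
  # clean data unchanged
  expect_equal(nrow(remove_numeric_outliers(train, st, 3)$values), 3)
})

test_that("SMOTE interpolates minority rows on the parent segment", {
  n <- 12
  values <- data.frame(x = c(0, 2, rep(10, 10)),
                       y = c(0, 2, rep(-10, 10)))
  col_meta <- data.frame(name = c("x", "y"), kind = "numeric",
                         stringsAsFactors = FALSE)
  col_meta$levels <- list(NULL, NULL)
  ds <- tabular_dataset(values, col_meta,
                        labels = c(1, 1, rep(0, 10)))
  out <- smote_oversample(ds, smote_config(k_neighbors = 1, seed = 4))
  expect_equal(nrow(out$values), 20)         # balanced to 10/10
  expect_equal(sum(out$labels == 1), 10)
  syn <- which(out$synthetic)
  expect_length(syn, 8)
  # parents are (0,0) and (2,2): synthetic points lie on the diagonal
  expect_equal(out$values$x[syn], out$values$y[syn])
  expect_true(all(out$values$x[syn] >= 0 & out$values$x[syn] <= 2))
})

test_that("SMOTE refuses a minority smaller than k+1 and flags synthetic rows", {
  ds <- tiny_dataset()                        # 3 positives / 3 negatives
  expect_error(smote_oversample(ds, smote_config(k_neighbors = 5)), "k")
  ds2 <- generate_dataset(synthetic_spec(n_samples = 80, class_ratio = 0.7,
                                         seed = 2))
  out <- smote_oversample(ds2, smote_config(seed = 2))
  expect_true(all(out$labels[out$synthetic] ==
                    as.integer(sum(ds2$labels == 1) <= sum(ds2$labels == 0))))
  expect_false(any(out$synthetic[seq_len(nrow(ds2$values))]))
})

test_that("transform standardises with training statistics only", {
  ds <- generate_dataset(synthetic_spec(n_samples = 200, seed = 31))
  train <- ds_rows(ds, 1:150)
  test <- ds_rows(ds, 151:200)
  st <- fit_preprocessor(train)
  enc <- transform_dataset(train, st)
  num_cols <- which(enc$feature_map %in%
                      which(ds$col_meta$kind == "numeric"))
  mus <- colMeans(enc$X[, num_cols])
  # means near 0 (imputed cells pull slightly off exact zero)
  expect_true(all(abs(mus) < 0.15))
  # a held-out constant column maps through the training mean, not its own
  test$values$num01 <- rep(1000, 50)
  enc_te <- transform_dataset(test, st)
  expect_true(all(enc_te$X[, "num01"] > 3))
  # missing numeric cell -> stored training median
  test2 <- ds_rows(ds, 151:200)
  test2$values$num02[1] <- NA
  e2 <- transform_dataset(test2, st)
  expected <- (st$medians$num02 - st$means$num02) / st$sds$num02
  expect_equal(e2$X[1, "num02"], expected, ignore_attr = TRUE)
})

test_that("held-out corruption never touches fitted parameters or training encodings", {
  ds <- generate_dataset(synthetic_spec(n_samples = 120, seed = 41))
  train <- ds_rows(ds, 1:90)
  heldout <- ds_rows(ds, 91:120)
  st <- fit_preprocessor(train)
  enc <- transform_dataset(train, st)
  # corrupt every held-out cell with extreme values
  for (j in seq_len(ncol(heldout$values)))
    heldout$values[[j]][] <- if (ds$col_meta$kind[j] == "numeric") 1e6
                             else "corrupted"
  st2 <- fit_preprocessor(train)
  expect_identical(st[names(st) != "col_meta"], st2[names(st2) != "col_meta"])
  expect_identical(enc$X, transform_dataset(train, st2)$X)
})

test_that("preprocessing state serialises for audit", {
  st <- fit_preprocessor(tiny_dataset())
  path <- withr::local_tempfile(fileext = ".yaml")
  preproc_state_export(st, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$modes$htn, "yes")
  expect_equal(back$medians$age, 30)
})
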