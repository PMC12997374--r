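#' Fit leakage-safe preprocessing parameters on a training fold
#'
#' Computes, from the observed training values only: the per-nominal-column
#' imputation mode (ties broken by the lexicographically smallest category),
#' the per-numeric-column imputation median, the per-numeric-column mean and
#' standard deviation used for Z-scoring and standardisation, and the
#' allowed category sets used for domain validation.  Held-out folds are
#' always transformed with these stored training statistics, never refit.
#'
#' @param train a [tabular_dataset()] of training rows.
#' @return An object of class `preproc_state`.
#' @export
fit_preprocessor <- function(train) {
  stopifnot(inherits(train, "tabular_dataset"))
  if (nrow(train$values) == 0) stop("training fold is empty")
  meta <- train$col_meta
  modes <- medians <- means <- sds <- stats::setNames(
    vector("list", nrow(meta)), meta$name)
  for (j in seq_len(nrow(meta))) {
    v <- train$values[[j]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0)
      stop("column '", meta$name[j], "' has no observed training values")
    if (meta$kind[j] == "nominal") {
      tab <- table(obs)
      top <- names(tab)[tab == max(tab)]
      modes[[j]] <- sort(top)[1]
    } else {
      obs <- as.numeric(obs)
      medians[[j]] <- stats::median(obs)
      means[[j]] <- mean(obs)
      sds[[j]] <- if (length(obs) > 1) stats::sd(obs) else 0
    }
  }
  structure(list(modes = modes, medians = medians, means = means, sds = sds,
                 valid_sets = stats::setNames(meta$levels, meta$name),
                 col_meta = meta, fitted = TRUE),
            class = "preproc_state")
}

#' Remove rows above a missingness threshold
#'
#' Drops every row whose count of missing feature cells is at least
#' `threshold * m`, where `m` is the number of non-label attributes (the
#' class label never counts as missing).  The comparison is `>=`, following
#' the filter's formula rather than the looser "more than 50%" phrasing.
#'
#' @param ds a [tabular_dataset()].
#' @param threshold missingness fraction in (0,1], default 0.5.
#' @return list with elements `dataset` (the survivors) and `removed`
#'   (number of rows dropped).
#' @export
filter_high_missing_rows <- function(ds, threshold = 0.5) {
  stopifnot(inherits(ds, "tabular_dataset"),
            threshold > 0, threshold <= 1)
  m <- ncol(ds$values)
  bad <- rowSums(is.na(ds$values)) >= threshold * m
  list(dataset = ds_rows(ds, !bad), removed = sum(bad))
}

.normalize_cat <- function(x) tolower(trimws(x))

#' Domain-validate nominal cells
#'
#' Cells of nominal columns are trimmed and lowercased, then checked against
#' the column's allowed category set (e.g. hypertension in \{yes, no\}, red
#' blood cells in \{normal, abnormal\}); values outside the set — `"?"`,
#' `"unknown"`, misspellings — become missing.  Only case and surrounding
#' whitespace are repaired; anything else is treated as implausible.
#'
#' @param ds a [tabular_dataset()].
#' @param state a fitted [fit_preprocessor()] state carrying the allowed sets.
#' @return The validated `tabular_dataset`.
#' @export
validate_categories <- function(ds, state) {
  stopifnot(inherits(state, "preproc_state"), isTRUE(state$fitted))
  for (j in seq_len(ncol(ds$values))) {
    if (ds$col_meta$kind[j] != "nominal") next
    allowed <- state$valid_sets[[ds$col_meta$name[j]]]
    v <- .normalize_cat(ds$values[[j]])
    v[!is.na(v) & !(v %in% .normalize_cat(allowed))] <- NA
    # map back onto the canonical spelling of the allowed set
    idx <- match(v, .normalize_cat(allowed))
    ds$values[[j]] <- ifelse(is.na(idx), NA_character_, allowed[idx])
  }
  ds
}

#' Remove rows containing numeric outliers
#'
#' A row is dropped when any of its observed numeric cells has
#' `|x - mu| / sigma > z_cut` under the training-fold mean and standard
#' deviation stored in `state`.  Constant columns (`sigma = 0`) contribute
#' z = 0 and never trigger removal.
#'
#' @param ds a [tabular_dataset()].
#' @param state a fitted [fit_preprocessor()] state.
#' @param z_cut positive Z-score cutoff (default 3).
#' @return The filtered `tabular_dataset`.
#' @export
remove_numeric_outliers <- function(ds, state, z_cut = 3) {
  stopifnot(inherits(state, "preproc_state"), z_cut > 0)
  keep <- rep(TRUE, nrow(ds$values))
  for (j in seq_len(ncol(ds$values))) {
    if (ds$col_meta$kind[j] != "numeric") next
    nm <- ds$col_meta$name[j]
    s <- state$sds[[nm]]
    if (is.null(s) || s == 0) next
    z <- abs(as.numeric(ds$values[[j]]) - state$means[[nm]]) / s
    keep <- keep & (is.na(z) | z <= z_cut)
  }
  ds_rows(ds, keep)
}

#' SMOTE configuration
#'
#' @param k_neighbors number of minority nearest neighbours (default 5).
#' @param target_ratio minority:majority ratio after resampling, in (0,1]
#'   (default 1: oversample to balance).
#' @param seed integer RNG seed.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1, seed = 1) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "smote_config")
}

#' SMOTE oversampling of the minority class (training folds only)
#'
#' New minority rows are interpolations `x_new = x_i + lambda * (x_j - x_i)`
#' with `lambda ~ U(0,1)` and `x_j` one of the `k` nearest minority
#' neighbours of `x_i` under Euclidean distance on the median-imputed,
#' standardised numeric encoding (nominal columns one-hot).  Numeric cells
#' of the synthetic row are interpolated on the raw scale (interpolation
#' commutes with the affine standardisation); nominal cells take the
#' nearer parent's category (`x_i` for `lambda <= 0.5`).  Synthetic rows
#' are flagged so they can never leak into evaluation splits.
#'
#' @param train a [tabular_dataset()] training fold.
#' @param cfg a [smote_config()].
#' @param state optional fitted [fit_preprocessor()] state; fitted on
#'   `train` itself when omitted (leakage-safe, since SMOTE only ever sees
#'   training rows).
#' @return `train` with synthetic minority rows appended.
#' @export
smote_oversample <- function(train, cfg = smote_config(), state = NULL) {
  stopifnot(inherits(train, "tabular_dataset"), inherits(cfg, "smote_config"))
  if (is.null(state)) state <- fit_preprocessor(train)
  n1 <- sum(train$labels == 1L); n0 <- sum(train$labels == 0L)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min < cfg$k_neighbors + 1)
    stop("minority class too small for k = ", cfg$k_neighbors,
         " neighbours; reduce k_neighbors")
  n_new <- max(0L, as.integer(round(cfg$target_ratio * n_maj)) - n_min)
  if (n_new == 0L) return(train)

  enc <- transform_dataset(train, state)
  idx_min <- which(train$labels == minority)
  Xm <- enc$X[idx_min, , drop = FALSE]
  D2 <- as.matrix(stats::dist(Xm))
  diag(D2) <- Inf
  nn <- matrix(0L, n_min, cfg$k_neighbors)
  for (i in seq_len(n_min))
    nn[i, ] <- order(D2[i, ])[seq_len(cfg$k_neighbors)]

  set.seed(cfg$seed)
  base <- idx_min[((seq_len(n_new) - 1L) %% n_min) + 1L]
  base_pos <- match(base, idx_min)
  nb_pick <- nn[cbind(base_pos,
                      sample.int(cfg$k_neighbors, n_new, replace = TRUE))]
  neighbor <- idx_min[nb_pick]
  lambda <- stats::runif(n_new)

  imp <- .impute_raw(train, state)      # median/mode-imputed raw values
  new_vals <- imp[rep(1L, n_new), , drop = FALSE]
  for (r in seq_len(n_new)) {
    i <- base[r]; j <- neighbor[r]; lam <- lambda[r]
    for (c in seq_len(ncol(imp))) {
      if (train$col_meta$kind[c] == "numeric") {
        xi <- as.numeric(imp[i, c]); xj <- as.numeric(imp[j, c])
        new_vals[r, c] <- xi + lam * (xj - xi)
      } else {
        new_vals[r, c] <- if (lam <= 0.5) imp[i, c] else imp[j, c]
      }
    }
  }
  new_df <- as.data.frame(new_vals, stringsAsFactors = FALSE)
  for (c in seq_len(ncol(new_df)))
    if (train$col_meta$kind[c] == "numeric")
      new_df[[c]] <- as.numeric(new_df[[c]])
  rownames(new_df) <- NULL

  out_vals <- rbind(
    stats::setNames(as.data.frame(lapply(train$values, identity),
                                  stringsAsFactors = FALSE),
                    names(train$values)),
    stats::setNames(new_df, names(train$values)))
  tabular_dataset(out_vals, train$col_meta,
                  c(train$labels, rep(minority, n_new)),
                  train$informative_idx,
                  c(train$synthetic, rep(TRUE, n_new)))
}

# raw-value imputation (character matrix; numeric cols as numbers in strings)
.impute_raw <- function(ds, state) {
  out <- matrix(NA_character_, nrow(ds$values), ncol(ds$values))
  for (j in seq_len(ncol(ds$values))) {
    nm <- ds$col_meta$name[j]
    v <- ds$values[[j]]
    if (ds$col_meta$kind[j] == "numeric") {
      v <- as.numeric(v); v[is.na(v)] <- state$medians[[nm]]
      out[, j] <- as.character(v)
    } else {
      v <- as.character(v); v[is.na(v)] <- state$modes[[nm]]
      out[, j] <- v
    }
  }
  out
}

#' Transform a dataset with stored training statistics
#'
#' Imputes missing nominal cells with the stored training modes and missing
#' numeric cells with the stored training medians, standardises numeric
#' columns with the stored training mean/sd, and one-hot encodes nominal
#' columns over their allowed category sets.  Deterministic; a category
#' unseen in the allowed set (possible only if validation was skipped) is
#' treated as missing.
#'
#' @param ds a [tabular_dataset()].
#' @param state a fitted [fit_preprocessor()] state.
#' @return An object of class `encoded_dataset`: list with numeric matrix
#'   `X`, `labels`, `feature_map` (original feature index of each encoded
#'   column), `feature_names`, and `synthetic` flags.
#' @export
transform_dataset <- function(ds, state) {
  stopifnot(inherits(state, "preproc_state"), isTRUE(state$fitted))
  cols <- list(); fmap <- integer(0)
  for (j in seq_len(ncol(ds$values))) {
    nm <- ds$col_meta$name[j]
    if (ds$col_meta$kind[j] == "numeric") {
      v <- as.numeric(ds$values[[j]])
      v[is.na(v)] <- state$medians[[nm]]
      s <- state$sds[[nm]]
      v <- if (s > 0) (v - state$means[[nm]]) / s else v - state$means[[nm]]
      cols[[nm]] <- v
      fmap <- c(fmap, j)
    } else {
      allowed <- state$valid_sets[[nm]]
      v <- as.character(ds$values[[j]])
      v[!is.na(v) & !(v %in% allowed)] <- NA
      v[is.na(v)] <- state$modes[[nm]]
      for (lv in allowed) {
        cols[[paste(nm, lv, sep = ".")]] <- as.numeric(v == lv)
        fmap <- c(fmap, j)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, labels = ds$labels, feature_map = fmap,
                 feature_names = ds$col_meta$name,
                 synthetic = ds$synthetic),
            class = "encoded_dataset")
}

#' Serialise preprocessing parameters for audit
#'
#' @param state a fitted [fit_preprocessor()] state.
#' @param path optional file path; `.yaml`/`.yml` writes YAML, anything
#'   else JSON.  When `NULL`, the plain list is returned.
#' @return The serialisable list, invisibly when written to file.
#' @export
preproc_state_export <- function(state, path = NULL) {
  stopifnot(inherits(state, "preproc_state"))
  lst <- list(modes = state$modes[!vapply(state$modes, is.null, TRUE)],
              medians = state$medians[!vapply(state$medians, is.null, TRUE)],
              means = state$means[!vapply(state$means, is.null, TRUE)],
              sds = state$sds[!vapply(state$sds, is.null, TRUE)],
              valid_sets = state$valid_sets[
                !vapply(state$valid_sets, is.null, TRUE)])
  if (is.null(path)) return(lst)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(lst)
}
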