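#' Specification for a synthetic CKD-like dataset
#'
#' Defines the generating conditions for a synthetic clinical table whose
#' structure mirrors the UCI chronic-kidney-disease panel: a mix of numeric
#' laboratory measurements and small-category nominal findings, a binary
#' disease label driven by a known informative feature subset, configurable
#' class imbalance and completely-at-random missingness.  Defaults follow
#' the reference panel: 400 records, 11 numeric + 13 nominal features,
#' 62.5% positives (the 250/150 split), and 7 informative features.
#'
#' @param n_samples number of records.
#' @param n_numeric number of numeric feature columns.
#' @param n_nominal number of nominal feature columns (2-5 categories each).
#' @param informative_idx indices of the features that drive the label;
#'   `NULL` picks a default spread of 7 indices across both kinds.
#' @param class_ratio expected fraction of positive labels, in (0,1).
#' @param missing_rate expected fraction of missing feature cells, in
#'   [0, 0.5); kept below 0.5 so the high-missingness row filter cannot
#'   annihilate the data by construction.
#' @param effect_size log-odds scale of each informative feature's
#'   (standardised) contribution to the label.
#' @param noise_sd standard deviation of Gaussian noise added to the
#'   generating logit.
#' @param seed integer RNG seed; regeneration with the same spec is
#'   bit-identical.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 400, n_numeric = 11, n_nominal = 13,
                           informative_idx = NULL, class_ratio = 0.625,
                           missing_rate = 0.05, effect_size = 4,
                           noise_sd = 0.25, seed = 1) {
  m <- n_numeric + n_nominal
  if (n_samples < 1 || m < 1)
    stop("n_samples and feature counts must be positive")
  if (!(class_ratio > 0 && class_ratio < 1))
    stop("class_ratio must lie strictly inside (0,1)")
  if (!(missing_rate >= 0 && missing_rate < 0.5))
    stop("missing_rate must lie in [0, 0.5)")
  if (effect_size < 0 || noise_sd < 0)
    stop("effect_size and noise_sd must be nonnegative")
  if (is.null(informative_idx)) {
    k <- min(7L, m)
    # interleave numeric and nominal informative features
    informative_idx <- unique(round(seq(1, m, length.out = k)))
  }
  informative_idx <- sort(as.integer(informative_idx))
  if (any(informative_idx < 1) || any(informative_idx > m))
    stop("informative_idx must index the feature columns")
  structure(list(n_samples = as.integer(n_samples),
                 n_numeric = as.integer(n_numeric),
                 n_nominal = as.integer(n_nominal),
                 informative_idx = informative_idx,
                 class_ratio = class_ratio, missing_rate = missing_rate,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# nominal level vocabularies, cycled over nominal columns (2-5 levels,
# echoing yes/no findings and semi-quantitative 0-5 urine scales)
.nominal_vocab <- list(
  c("yes", "no"),
  c("normal", "abnormal"),
  c("present", "notpresent"),
  c("0", "1", "2", "3"),
  c("0", "1", "2", "3", "4"))

#' Generate a synthetic CKD-like dataset
#'
#' Draws a latent standard-normal score per feature; numeric columns are
#' affine transforms of their latent score, nominal columns discretise it
#' into 2-5 ordered categories.  The label is Bernoulli with
#' logit = intercept + effect_size * (signed sum of standardised informative
#' scores) + N(0, noise_sd), where the score of a nominal informative
#' feature is its centred category code, so the label depends only on the
#' recorded feature values of the informative subset.  The intercept is
#' solved so the expected positive fraction equals `class_ratio`.  Missing
#' cells are then inserted completely at random at `missing_rate`.
#'
#' @param spec a [synthetic_spec()].
#' @return A [tabular_dataset()] carrying `informative_idx` and, for tests,
#'   the generating logits as field `generating_logits` and the informative
#'   signs as `informative_signs`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_numeric + spec$n_nominal
  kinds <- c(rep("numeric", spec$n_numeric), rep("nominal", spec$n_nominal))
  z <- matrix(stats::rnorm(n * m), n, m)

  values <- vector("list", m)
  levels <- vector("list", m)
  score <- matrix(0, n, m)          # standardised score entering the logit
  nom_seen <- 0L
  for (j in seq_len(m)) {
    if (kinds[j] == "numeric") {
      loc <- stats::runif(1, 1, 150); scl <- stats::runif(1, 0.5, 20)
      values[[j]] <- round(loc + scl * z[, j], 3)
      score[, j] <- z[, j]
    } else {
      nom_seen <- nom_seen + 1L
      lv <- .nominal_vocab[[(nom_seen - 1L) %% length(.nominal_vocab) + 1L]]
      K <- length(lv)
      code <- findInterval(stats::pnorm(z[, j]),
                           seq_len(K - 1) / K) + 1L  # equal-mass bins
      values[[j]] <- lv[code]
      levels[[j]] <- lv
      sc <- code - mean(seq_len(K))
      score[, j] <- sc / stats::sd(sc)
    }
  }
  names(values) <- sprintf("%s%02d", ifelse(kinds == "numeric", "num", "nom"),
                           seq_len(m))
  df <- as.data.frame(values, stringsAsFactors = FALSE)

  signs <- rep_len(c(1, -1), length(spec$informative_idx))
  eta <- as.numeric(score[, spec$informative_idx, drop = FALSE] %*% signs) *
    spec$effect_size +
    stats::rnorm(n, 0, spec$noise_sd)
  # intercept matching the target prevalence in expectation
  icpt <- stats::uniroot(function(c0) mean(stats::plogis(c0 + eta)) -
                           spec$class_ratio,
                         interval = c(-50, 50))$root
  logits <- icpt + eta
  labels <- stats::rbinom(n, 1, stats::plogis(logits))

  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    for (j in seq_len(m)) df[[j]][mask[, j]] <- NA
  }

  col_meta <- data.frame(name = names(df), kind = kinds,
                         stringsAsFactors = FALSE)
  col_meta$levels <- levels
  ds <- tabular_dataset(df, col_meta, labels,
                        informative_idx = spec$informative_idx)
  ds$generating_logits <- logits
  ds$informative_signs <- signs
  ds
}

#' Force a block of rows above a missingness threshold
#'
#' Fixture helper for the high-missingness row filter: makes exactly `k`
#' rows carry `ceiling(frac_missing * m)` missing feature cells each (the
#' `k` rows with the fewest existing missing cells are chosen, so the
#' remaining rows are untouched).
#'
#' @param ds a [tabular_dataset()].
#' @param k number of rows to alter.
#' @param frac_missing target missing fraction per altered row, in (0,1].
#' @return A modified copy of `ds`.
#' @export
inject_high_missing_rows <- function(ds, k, frac_missing) {
  stopifnot(inherits(ds, "tabular_dataset"))
  n <- nrow(ds$values); m <- ncol(ds$values)
  if (k > n) stop("k exceeds the number of rows")
  if (k == 0) return(ds)
  if (!(frac_missing > 0 && frac_missing <= 1))
    stop("frac_missing must lie in (0,1]")
  target <- ceiling(frac_missing * m)
  na_count <- rowSums(is.na(ds$values))
  rows <- order(na_count, seq_len(n))[seq_len(k)]
  if (any(na_count[rows] > target))
    stop("some rows already exceed the target missing count")
  for (i in rows) {
    present <- which(!is.na(ds$values[i, ]))
    drop <- present[seq_len(target - na_count[i])]
    for (j in drop) ds$values[i, j] <- NA
  }
  ds
}
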