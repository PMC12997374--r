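#' Exact Shapley attribution of one sample
#'
#' Enumerates all 2^d feature coalitions (feasible because the selected
#' subsets are small, d <= 20).  The value of a coalition S is the mean
#' model output over the background rows with the features in S replaced
#' by the sample's values (interventional replacement, which assumes
#' feature independence).  The attribution of feature j is the
#' Shapley-weighted average of its marginal contributions:
#' `phi_j = sum over S not containing j of
#'  |S|! (d-|S|-1)! / d! * (v(S + j) - v(S))`.
#' Efficiency holds sharply: `sum(phi) = f(x) - mean background output`.
#'
#' @param model_fn function taking a numeric matrix of rows and returning
#'   the positive-class probability per row.
#' @param x numeric sample vector (one entry per model input column).
#' @param background matrix of reference rows (same columns as `x`).
#' @param groups optional vector assigning each input column to a player
#'   (e.g. all one-hot columns of one clinical feature form one player);
#'   by default every column is its own player.  Attributions are
#'   per player.
#' @return list with `phi` (per-player attributions), `fx` (model output
#'   at `x`) and `baseline` (mean background output).
#' @export
exact_shapley <- function(model_fn, x, background, groups = NULL) {
  background <- as.matrix(background)
  stopifnot(ncol(background) == length(x), nrow(background) >= 1)
  if (is.null(groups)) {
    groups <- seq_along(x)
    if (!is.null(colnames(background))) groups <- colnames(background)
  }
  stopifnot(length(groups) == length(x))
  players <- unique(groups)
  d <- length(players)
  if (d > 20) stop("d = ", d, " players: exact enumeration of 2^d ",
                   "coalitions is limited to d <= 20; use a sampling ",
                   "approximation instead")
  cols_of <- lapply(players, function(g) which(groups == g))
  nb <- nrow(background)
  n_sets <- bitwShiftL(1L, d)
  # v(S) for every coalition bitmask.  Coalitions are visited in Gray-code
  # order so consecutive sets differ by one player (a single column-block
  # overwrite), and evaluated through the model in bounded blocks.
  v <- numeric(n_sets)
  block <- max(1L, as.integer(2e5 / nb))
  rows <- background
  sets <- integer(block); filled <- 0L
  grid <- matrix(0, block * nb, length(x))
  flush <- function() {
    if (filled == 0L) return()
    g <- grid[seq_len(filled * nb), , drop = FALSE]
    colnames(g) <- colnames(background)
    out <- model_fn(g)
    v[sets[seq_len(filled)] + 1L] <<-
      vapply(seq_len(filled),
             function(k) mean(out[(k - 1L) * nb + seq_len(nb)]), numeric(1))
    filled <<- 0L
  }
  gray_prev <- 0L
  for (k in seq_len(n_sets) - 1L) {
    gray <- bitwXor(k, bitwShiftR(k, 1))
    changed <- bitwXor(gray, gray_prev)
    if (changed != 0L) {
      j <- 1L + as.integer(round(log2(changed)))
      cols <- cols_of[[j]]
      rows[, cols] <- if (bitwAnd(gray, changed) != 0L)
        rep(x[cols], each = nb) else background[, cols]
    }
    gray_prev <- gray
    filled <- filled + 1L
    sets[filled] <- gray
    grid[(filled - 1L) * nb + seq_len(nb), ] <- rows
    if (filled == block) flush()
  }
  flush()
  sizes <- vapply(seq_len(n_sets) - 1L,
                  function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(d - 1))) != 0),
                  numeric(1))
  wt <- factorial(0:(d - 1)) * factorial(d - (0:(d - 1)) - 1) / factorial(d)
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bitj <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(n_sets) - 1L, bitj) == 0L)
    phi[j] <- sum(wt[sizes[without] + 1] * (v[without + bitj] - v[without]))
  }
  names(phi) <- as.character(players)
  list(phi = phi, fx = v[n_sets], baseline = v[1])
}

#' Global importance ranking from per-sample attributions
#'
#' @param phi matrix of per-sample Shapley values (samples x features);
#'   positive values push the prediction toward the disease class.
#' @return An object of class `attribution_report`: `global` data.frame
#'   (feature, mean absolute attribution, rank; sorted descending) and the
#'   signed `per_sample` table for beeswarm-style plotting.
#' @export
global_importance <- function(phi) {
  phi <- as.matrix(phi)
  stopifnot(nrow(phi) >= 1)
  imp <- colMeans(abs(phi))
  ord <- order(imp, decreasing = TRUE)
  global <- data.frame(feature = colnames(phi)[ord],
                       mean_abs_phi = unname(imp[ord]),
                       rank = seq_along(ord))
  structure(list(global = global, per_sample = phi),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report>\n")
  print(x$global, row.names = FALSE)
  invisible(x)
}

#' Shapley attributions for a set of samples
#'
#' @param model_fn row-matrix to probability function (see
#'   [exact_shapley()]).
#' @param X matrix of samples to explain.
#' @param background matrix of reference rows (typically the preprocessed
#'   training fold).
#' @param groups optional column-to-player assignment (see
#'   [exact_shapley()]).
#' @return An [global_importance()] `attribution_report`; the per-sample
#'   efficiency residuals `fx - baseline - sum(phi)` are attached as
#'   `efficiency_gap`.
#' @export
shapley_explain <- function(model_fn, X, background, groups = NULL) {
  X <- as.matrix(X)
  res <- lapply(seq_len(nrow(X)), function(i)
    exact_shapley(model_fn, X[i, ], background, groups))
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  rep_ <- global_importance(phi)
  rep_$efficiency_gap <- vapply(res, function(r)
    r$fx - r$baseline - sum(r$phi), numeric(1))
  rep_
}
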