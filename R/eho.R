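#' Configuration for elephant herding optimisation
#'
#' Defaults follow the reference protocol: 5 clans of 10 elephants, scaling
#' factor a = 0.5, clan-influence coefficient beta = 0.7, tolerance 0.001,
#' and a 50-iteration cap.  Default search bounds cover the four network
#' hyperparameters: log10 learning rate, momentum, log10 weight decay, and
#' first hidden-layer width (the second layer is half the first, rounded).
#'
#' @param n_clans number of clans C.
#' @param clan_size elephants per clan.
#' @param a matriarch-attraction scaling factor in (0,1].
#' @param beta clan-centre influence coefficient in (0,1].
#' @param max_iter iteration cap.
#' @param tol stop when the best objective improves by less than this
#'   between consecutive iterations.
#' @param bounds 2 x P matrix; row 1 lower, row 2 upper bounds.
#' @param seed integer RNG seed.
#' @return An object of class `eho_config`.
#' @export
eho_config <- function(n_clans = 5, clan_size = 10, a = 0.5, beta = 0.7,
                       max_iter = 50, tol = 0.001,
                       bounds = default_hyper_bounds(), seed = 1) {
  stopifnot(n_clans >= 1, clan_size >= 1, a > 0, a <= 1, beta > 0, beta <= 1,
            max_iter >= 1, tol >= 0, is.matrix(bounds), nrow(bounds) == 2,
            all(bounds[1, ] < bounds[2, ]))
  structure(list(n_clans = as.integer(n_clans),
                 clan_size = as.integer(clan_size), a = a, beta = beta,
                 max_iter = as.integer(max_iter), tol = tol, bounds = bounds,
                 seed = as.integer(seed)),
            class = "eho_config")
}

#' Default hyperparameter search box
#'
#' Columns: `log10_eta` in [-4, -1], `momentum` in [0.5, 0.99],
#' `log10_lambda` in [-6, -2], `n_hidden` in [16, 128].
#'
#' @return A 2 x 4 bounds matrix.
#' @export
default_hyper_bounds <- function() {
  b <- rbind(c(-4, 0.5, -6, 16), c(-1, 0.99, -2, 128))
  colnames(b) <- c("log10_eta", "momentum", "log10_lambda", "n_hidden")
  b
}

#' Decode a real-valued position into network hyperparameters
#'
#' The width dimension evolves continuously and is rounded at evaluation
#' time; the second hidden layer is half the first, rounded, floor 2.
#'
#' @param x position vector in the [default_hyper_bounds()] box.
#' @return list with `learning_rate`, `momentum`, `weight_decay`,
#'   `layer_sizes`.
#' @export
decode_hyper <- function(x) {
  n1 <- max(2L, as.integer(round(x[4])))
  list(learning_rate = 10^x[1], momentum = x[2], weight_decay = 10^x[3],
       layer_sizes = c(n1, max(2L, as.integer(round(n1 / 2)))))
}

#' Clan operator: move toward the matriarch
#'
#' `x' = x + a * (x_best - x) * r`, with `r ~ U(0,1)`.
#'
#' @param x current position.
#' @param x_best clan-best (matriarch) position.
#' @param a scaling factor.
#' @param r optional uniform draw(s) (tests); drawn when `NULL`.
#' @return The updated position.
#' @export
clan_update <- function(x, x_best, a = 0.5, r = NULL) {
  stopifnot(length(x) == length(x_best))
  if (is.null(r)) r <- stats::runif(length(x))
  x + a * (x_best - x) * r
}

#' Reinitialise the worst member of a clan
#'
#' The clan's argmax-objective member is resampled as
#' `x_min + (x_max - x_min + 1) * rand` and then clamped into the bounds
#' (the `+1` term can overshoot the upper bound; clamping keeps bound
#' integrity).
#'
#' @param positions clan_size x P matrix.
#' @param values objective values for the clan.
#' @param bounds 2 x P bounds matrix.
#' @param rand optional uniform draw(s) (tests); drawn when `NULL`.
#' @return The positions matrix with the worst row resampled.
#' @export
replace_worst <- function(positions, values, bounds, rand = NULL) {
  stopifnot(nrow(positions) == length(values))
  P <- ncol(positions)
  if (is.null(rand)) rand <- stats::runif(P)
  worst <- which.max(values)
  new <- bounds[1, ] + (bounds[2, ] - bounds[1, ] + 1) * rand
  positions[worst, ] <- pmin(pmax(new, bounds[1, ]), bounds[2, ])
  positions
}

#' Clan centre and matriarch centre-move
#'
#' The centre is the componentwise clan mean; the matriarch's centre-move
#' places it at `beta * centre`.
#'
#' @param positions clan_size x P matrix.
#' @return `clan_center`: the centre vector.
#' @export
clan_center <- function(positions) colMeans(positions)

#' @rdname clan_center
#' @param x_center centre vector.
#' @param beta influence coefficient.
#' @return `center_update`: the matriarch's new position `beta * x_center`.
#' @export
center_update <- function(x_center, beta = 0.7) beta * x_center

#' Inner-cross-validated MSE objective for hyperparameter tuning
#'
#' Trains the network with the candidate hyperparameters on each inner
#' training split and returns the mean, across inner folds, of the
#' per-instance sum of squared differences between the one-hot targets and
#' the softmax outputs, averaged over instances.
#'
#' @param X encoded training matrix.
#' @param y 0/1 labels.
#' @param inner_folds number of stratified inner folds.
#' @param cfg_base a [train_config()] supplying the non-tuned settings
#'   (epochs, dropout, batch size, patience, seed).
#' @param seed RNG seed for the fold split.
#' @param synthetic optional logical flags marking oversampled rows; inner
#'   validation folds are built from real rows only, synthetic rows always
#'   train.
#' @return A function `position -> mean inner-validation MSE`.
#' @export
mse_objective <- function(X, y, inner_folds = 2, cfg_base = train_config(),
                          seed = 1, synthetic = NULL) {
  X <- as.matrix(X)
  real <- if (is.null(synthetic)) seq_along(y) else which(!synthetic)
  set.seed(seed)
  folds <- lapply(caret::createFolds(factor(y[real]), k = inner_folds),
                  function(i) real[i])
  for (f in folds)
    if (length(unique(y[-f])) < 2 || length(unique(y[f])) < 2)
      stop("degenerate inner fold: one class absent")
  function(pos) {
    hp <- decode_hyper(pos)
    cfg <- cfg_base
    cfg$learning_rate <- hp$learning_rate
    cfg$momentum <- hp$momentum
    cfg$weight_decay <- hp$weight_decay
    errs <- vapply(folds, function(test_idx) {
      model <- dbnn_train(X[-test_idx, , drop = FALSE], y[-test_idx],
                          layer_sizes = hp$layer_sizes, cfg = cfg,
                          synthetic = if (!is.null(synthetic))
                            synthetic[-test_idx])
      P <- predict_proba(model, X[test_idx, , drop = FALSE])
      Yv <- cbind(1 - y[test_idx], y[test_idx])
      mean(rowSums((Yv - P)^2))
    }, numeric(1))
    mean(errs)
  }
}

#' Mean squared error between one-hot targets and softmax outputs
#'
#' `(1/T) * sum_t sum_j (D_j(t) - Y_j(t))^2`.
#'
#' @param targets T x N one-hot target matrix.
#' @param outputs T x N network output matrix.
#' @return The scalar MSE.
#' @export
output_mse <- function(targets, outputs) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  stopifnot(all(dim(targets) == dim(outputs)))
  mean(rowSums((targets - outputs)^2))
}

#' Run elephant herding optimisation
#'
#' Clans of candidate positions move toward their matriarch (clan best),
#' the worst member of each clan is reinitialised, and each matriarch takes
#' a clan-centre move; the global best is tracked outside the herd
#' (elitism) so no operator can lose it.  Stops when the best objective
#' improves by less than `tol` between consecutive iterations, or at
#' `max_iter`.
#'
#' @param objective function `position -> value` (smaller is better),
#'   defined on the bounded box.
#' @param cfg an [eho_config()].
#' @param init optional position used to warm-start one elephant (e.g. the
#'   default hyperparameters, so the tuned result can only improve on
#'   them under the inner objective).
#' @return list with `best` (position), `value`, and `trace`
#'   (per-iteration best value, non-increasing).
#' @export
run_eho <- function(objective, cfg = eho_config(), init = NULL) {
  set.seed(cfg$seed)
  P <- ncol(cfg$bounds)
  C <- cfg$n_clans; S <- cfg$clan_size
  clamp <- function(x) pmin(pmax(x, rep(cfg$bounds[1, ], each = nrow(x))),
                            rep(cfg$bounds[2, ], each = nrow(x)))
  pos <- lapply(seq_len(C), function(c)
    clamp(matrix(stats::runif(S * P, cfg$bounds[1, ], cfg$bounds[2, ]),
                 S, P, byrow = TRUE)))
  if (!is.null(init)) {
    stopifnot(length(init) == P)
    pos[[1]][1, ] <- pmin(pmax(init, cfg$bounds[1, ]), cfg$bounds[2, ])
  }
  val <- lapply(pos, function(m) apply(m, 1, objective))
  gb_i <- which.min(vapply(val, min, numeric(1)))
  gbest <- pos[[gb_i]][which.min(val[[gb_i]]), ]
  gval <- min(val[[gb_i]])
  trace <- numeric(0)
  for (it in seq_len(cfg$max_iter)) {
    prev <- gval
    for (c in seq_len(C)) {
      mat_i <- which.min(val[[c]])
      xbest <- pos[[c]][mat_i, ]
      for (j in seq_len(S)) {
        if (j == mat_i) {
          pos[[c]][j, ] <- pmin(pmax(center_update(clan_center(pos[[c]]),
                                                   cfg$beta),
                                     cfg$bounds[1, ]), cfg$bounds[2, ])
        } else {
          pos[[c]][j, ] <- pmin(pmax(clan_update(pos[[c]][j, ], xbest,
                                                 cfg$a),
                                     cfg$bounds[1, ]), cfg$bounds[2, ])
        }
      }
      val[[c]] <- apply(pos[[c]], 1, objective)
      pos[[c]] <- replace_worst(pos[[c]], val[[c]], cfg$bounds)
      worst <- which.max(val[[c]])
      val[[c]][worst] <- objective(pos[[c]][worst, ])
      if (min(val[[c]]) < gval) {
        gval <- min(val[[c]])
        gbest <- pos[[c]][which.min(val[[c]]), ]
      }
    }
    trace <- c(trace, gval)
    if (prev - gval < cfg$tol) break
  }
  list(best = gbest, value = gval, trace = trace)
}
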