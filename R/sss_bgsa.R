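#' Configuration for spiral-search binary gravitational feature selection
#'
#' Defaults follow the reference settings where printed (20 agents, 100
#' iterations, fitness weights 0.9/0.1, spiral radius 0.5) and standard
#' gravitational-search conventions elsewhere (G0 = 100, exponential decay
#' constant 15, inertia weight 0.9 -> 0.4, Kbest linearly shrinking from N
#' to 1).
#'
#' @param n_agents population size N.
#' @param max_iter maximum iterations Tmax.
#' @param G0 initial gravitational constant.
#' @param g_decay decay constant in `G = G0 * exp(-g_decay * t / Tmax)`.
#' @param w_max,w_min inertia weight bounds, interpolated linearly over t.
#' @param alpha,beta fitness weights on classification error and on
#'   selected-subset fraction respectively.
#' @param spiral_prob probability SP of the spiral local-search jump;
#'   `spiral_prob = 0` recovers the plain binary gravitational search
#'   used as the ablation baseline.
#' @param spiral_b logarithmic-spiral expansion constant b.
#' @param spiral_r spiral radius: the angular draw is
#'   `theta = spiral_r * U(-1, 1)`.
#' @param eps small constant guarding divisions.
#' @param velocity_rule `"inertia"` uses the inertia weight w(t) as the
#'   velocity memory coefficient; `"random"` uses an independent U(0,1)
#'   coefficient per agent and dimension.
#' @param transfer_on `"velocity"` feeds the sigmoid transfer with the
#'   updated velocity; `"position"` feeds it with the continuous position.
#'   Agents taking the spiral jump always binarise their spiral position,
#'   since the velocity channel cannot carry the jump.
#' @param seed integer RNG seed.
#' @return An object of class `fs_config`.
#' @export
fs_config <- function(n_agents = 20, max_iter = 100, G0 = 100, g_decay = 15,
                      w_max = 0.9, w_min = 0.4, alpha = 0.9, beta = 0.1,
                      spiral_prob = 0.5, spiral_b = 1, spiral_r = 0.5,
                      eps = 1e-10,
                      velocity_rule = c("inertia", "random"),
                      transfer_on = c("velocity", "position"),
                      seed = 1) {
  stopifnot(n_agents >= 1, max_iter >= 0, alpha >= 0, beta >= 0,
            spiral_prob >= 0, spiral_prob <= 1, w_min <= w_max,
            spiral_b > 0, spiral_r > 0, eps > 0)
  structure(list(n_agents = as.integer(n_agents),
                 max_iter = as.integer(max_iter),
                 G0 = G0, g_decay = g_decay, w_max = w_max, w_min = w_min,
                 alpha = alpha, beta = beta, spiral_prob = spiral_prob,
                 spiral_b = spiral_b, spiral_r = spiral_r, eps = eps,
                 velocity_rule = match.arg(velocity_rule),
                 transfer_on = match.arg(transfer_on),
                 seed = as.integer(seed)),
            class = "fs_config")
}

#' Wrapper fitness of a feature mask
#'
#' `alpha * error_rate + beta * |S| / D`: classification error traded off
#' against subset size.  Smaller is better.
#'
#' @param mask binary selection vector.
#' @param error_rate classification error in [0,1] for the subset.
#' @param cfg an [fs_config()] supplying `alpha` and `beta`.
#' @return The scalar fitness.
#' @export
fitness_value <- function(mask, error_rate, cfg = fs_config()) {
  stopifnot(length(mask) > 0, error_rate >= 0, error_rate <= 1)
  cfg$alpha * error_rate + cfg$beta * sum(mask != 0) / length(mask)
}

#' Iteration-dependent gravitational constant and inertia weight
#'
#' `G(t) = G0 * exp(-g_decay * t / Tmax)`;
#' `w(t) = w_max - (w_max - w_min) * t / Tmax`.
#'
#' @param t iteration, `0 <= t <= max_iter`.
#' @param cfg an [fs_config()].
#' @return list with elements `G` and `w`.
#' @export
update_constants <- function(t, cfg = fs_config()) {
  stopifnot(t >= 0, t <= cfg$max_iter)
  frac <- if (cfg$max_iter > 0) t / cfg$max_iter else 0
  list(G = cfg$G0 * exp(-cfg$g_decay * frac),
       w = cfg$w_max - (cfg$w_max - cfg$w_min) * frac)
}

#' Normalised gravitational masses from fitness values
#'
#' `m_i = (f_max - f_i) / (f_max - f_min + eps)`, normalised to sum to 1.
#' When every agent has equal fitness the masses are uniform.
#'
#' @param f vector of fitness values (smaller = better).
#' @param eps small positive guard.
#' @return Mass vector summing to 1.
#' @export
compute_masses <- function(f, eps = 1e-10) {
  stopifnot(length(f) >= 1)
  fmax <- max(f); fmin <- min(f)
  if (fmax == fmin) return(rep(1 / length(f), length(f)))
  m <- (fmax - f) / (fmax - fmin + eps)
  m / sum(m)
}

# Kbest: linearly decreasing from N to 1 over the run
kbest_count <- function(t, cfg) {
  frac <- if (cfg$max_iter > 0) t / cfg$max_iter else 1
  max(1L, as.integer(round(cfg$n_agents - (cfg$n_agents - 1) * frac)))
}

#' Gravitational accelerations on every agent
#'
#' Force of agent j on agent i: `G * M_i * M_j / (R_ij + eps) * (X_j - X_i)`
#' with Euclidean `R_ij`, summed over the `kbest` highest-mass agents with
#' independent U(0,1) weights per (i, j) pair.  The acceleration divides by
#' `M_i`, which is cancelled analytically before the division so massless
#' agents receive finite acceleration.
#'
#' @param X N x D binary position matrix.
#' @param M mass vector (sums to 1).
#' @param G gravitational constant at this iteration.
#' @param kbest number of attracting agents.
#' @param cfg an [fs_config()] (for `eps`).
#' @param weights optional N x N matrix of force weights (tests); drawn
#'   U(0,1) from the current RNG stream when `NULL`.
#' @return N x D matrix of accelerations.
#' @export
accelerations <- function(X, M, G, kbest, cfg = fs_config(), weights = NULL) {
  N <- nrow(X); D <- ncol(X)
  stopifnot(kbest >= 1, kbest <= N, length(M) == N)
  if (N == 1) return(matrix(0, 1, D))
  if (is.null(weights)) weights <- matrix(stats::runif(N * N), N, N)
  kset <- order(M, decreasing = TRUE)[seq_len(kbest)]
  R <- as.matrix(stats::dist(X))
  A <- matrix(0, N, D)
  for (j in kset) {
    # coefficient of (X_j - X_i) in a_i: rand_ij * G * M_j / (R_ij + eps)
    coef <- weights[, j] * G * M[j] / (R[, j] + cfg$eps)
    coef[j] <- 0
    A <- A + coef * (matrix(X[j, ], N, D, byrow = TRUE) - X)
  }
  A
}

#' Sigmoid transfer of a continuous value to a bit
#'
#' Returns 1 when `1 / (1 + exp(-v))` exceeds an independent U(0,1) draw.
#'
#' @param v continuous value(s).
#' @param u optional uniform draw(s) (tests); drawn when `NULL`.
#' @return 0/1 bit(s).
#' @export
binarize <- function(v, u = NULL) {
  if (is.null(u)) u <- stats::runif(length(v))
  as.integer(stats::plogis(v) > u)
}

#' Logarithmic-spiral step toward an attractor
#'
#' `x + (xbest - x) * exp(b * theta) * cos(2 * pi * theta)`: at
#' `theta = 0` the step lands exactly on the attractor; at
#' `theta = 0.25` the cosine factor vanishes and the position is
#' unchanged.
#'
#' @param x current (continuous) position vector.
#' @param xbest attractor (incumbent best) vector.
#' @param theta spiral angle.
#' @param b spiral expansion constant.
#' @return The continuous spiral position.
#' @export
spiral_step <- function(x, xbest, theta, b = 1) {
  x + (xbest - x) * exp(b * theta) * cos(2 * pi * theta)
}

#' One velocity/position update of the swarm
#'
#' Velocities take `v <- w * v + a` (or a random memory coefficient under
#' `velocity_rule = "random"`).  Each agent then either performs, with
#' probability SP, a logarithmic-spiral jump toward the incumbent best
#' `X_d <- X_d + (Xbest_d - X_d) * exp(b * theta) * cos(2 * pi * theta)`
#' with `theta = spiral_r * U(-1, 1)` drawn once per agent, or the
#' gravitational drift `X <- X + v`.  Continuous values are mapped back to
#' bits by the sigmoid transfer: spiral agents binarise their spiral
#' position; drift agents binarise the velocity or the position according
#' to `transfer_on`.
#'
#' @param X,V N x D binary positions and real velocities.
#' @param Xbest incumbent best binary vector.
#' @param A N x D acceleration matrix.
#' @param w inertia weight at this iteration.
#' @param cfg an [fs_config()].
#' @return list with updated `X` (binary) and `V`.
#' @export
swarm_move <- function(X, V, Xbest, A, w, cfg = fs_config()) {
  N <- nrow(X); D <- ncol(X)
  mem <- if (cfg$velocity_rule == "inertia") w
         else matrix(stats::runif(N * D), N, D)
  V <- mem * V + A
  newX <- X
  for (i in seq_len(N)) {           # agent-major draw order, reproducible
    if (stats::runif(1) < cfg$spiral_prob) {
      theta <- cfg$spiral_r * stats::runif(1, -1, 1)
      s <- spiral_step(X[i, ], Xbest, theta, cfg$spiral_b)
      # the spiral is a local-exploitation orbit: its continuous position
      # is already on the [0,1] bit scale, so it is rounded
      # probabilistically (theta = 0 lands exactly on the incumbent);
      # a sigmoid transfer here would re-randomise bits even at the
      # spiral centre and reduce the jump to noise
      newX[i, ] <- as.integer(pmin(pmax(s, 0), 1) >
                                stats::runif(length(s)))
    } else {
      val <- if (cfg$transfer_on == "velocity") V[i, ] else X[i, ] + V[i, ]
      newX[i, ] <- binarize(val)
    }
  }
  list(X = newX, V = V)
}

#' Cross-validated surrogate fitness evaluator
#'
#' Builds the wrapper-fitness error oracle: for a candidate feature mask
#' it returns the cross-validated misclassification rate (threshold 0.5)
#' of a fast least-squares linear probability classifier fit on the
#' encoded columns of the selected features.  A fast surrogate is used
#' here because retraining the full deep belief network for every agent
#' at every iteration is disproportionate; the final model on the
#' selected mask is always the tuned network.
#'
#' Two estimators are available.  `"loo"` (default) computes the exact
#' leave-one-out error of the linear fit through the hat-matrix identity
#' `e_loo = e / (1 - h)` — deterministic and markedly lower-variance than
#' few-fold splitting, which matters because the subset-size reward for
#' dropping one feature is only `beta / D`.  `"kfold"` retains stratified
#' `inner_folds`-fold splitting averaged over `repeats` splits.  Either
#' way the error is measured on real rows only; oversampled rows
#' contribute to the fit but never to the estimate.
#'
#' @param enc an [transform_dataset()] `encoded_dataset` of the training
#'   fold.
#' @param inner_folds number of stratified inner folds (`"kfold"` only).
#' @param seed RNG seed for the fold split (`"kfold"` only).
#' @param repeats number of independent fold splits averaged per mask
#'   (`"kfold"` only).
#' @param method `"loo"` or `"kfold"`.
#' @return A function `mask -> error rate` in [0,1].
#' @export
surrogate_evaluator <- function(enc, inner_folds = 3, seed = 1,
                                repeats = 2,
                                method = c("loo", "kfold")) {
  stopifnot(inherits(enc, "encoded_dataset"))
  method <- match.arg(method)
  y <- enc$labels
  real <- which(!enc$synthetic)    # error is measured on real rows only
  if (method == "loo") {
    return(function(mask) {
      keep <- enc$feature_map %in% which(mask != 0)
      if (!any(keep)) return(1)
      X1 <- cbind(1, enc$X[, keep, drop = FALSE])
      fit <- stats::lm.fit(X1, y)
      h <- rowSums(qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]^2)
      p_loo <- y - fit$residuals / pmax(1 - h, 1e-8)
      mean((p_loo[real] > 0.5) != y[real])
    })
  }
  set.seed(seed)
  folds <- unlist(lapply(seq_len(repeats), function(r)
    lapply(caret::createFolds(factor(y[real]), k = inner_folds),
           function(i) real[i])), recursive = FALSE)
  function(mask) {
    keep <- enc$feature_map %in% which(mask != 0)
    if (!any(keep)) return(1)
    Xs <- enc$X[, keep, drop = FALSE]
    errs <- vapply(folds, function(test_idx) {
      Xtr <- cbind(1, Xs[-test_idx, , drop = FALSE])
      fit <- stats::lm.fit(Xtr, y[-test_idx])
      b <- fit$coefficients
      b[is.na(b)] <- 0
      p <- as.numeric(cbind(1, Xs[test_idx, , drop = FALSE]) %*% b)
      mean((p > 0.5) != y[test_idx])
    }, numeric(1))
    mean(errs)
  }
}

#' Run the spiral-search binary gravitational search
#'
#' Wrapper feature selection over D binary dimensions: initialise N random
#' masks, evaluate the wrapper fitness (error evaluator + subset penalty),
#' keep the incumbent best (elitism), update the gravitational constant,
#' inertia weight, masses, Kbest forces and velocities, and move agents
#' with the spiral local-search jump at probability `spiral_prob`.  The
#' all-zero mask is assigned worst-case error 1 so it is never selected.
#' Error evaluations are memoised per mask within the run.
#'
#' @param evaluator function `mask -> error rate` (see
#'   [surrogate_evaluator()]).
#' @param D number of candidate features.
#' @param cfg an [fs_config()].
#' @return list with `mask` (best binary vector), `fitness` (its wrapper
#'   fitness), and `trace` (per-iteration incumbent fitness,
#'   non-increasing; `trace[1]` is the post-initialisation value).
#' @export
run_sss_bgsa <- function(evaluator, D, cfg = fs_config()) {
  stopifnot(D >= 1)
  set.seed(cfg$seed)
  N <- cfg$n_agents
  X <- matrix(as.integer(stats::runif(N * D) < 0.5), N, D)
  V <- matrix(0, N, D)
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    err <- if (!any(mask != 0)) 1 else evaluator(mask)
    f <- fitness_value(mask, err, cfg)
    cache[[key]] <- f
    f
  }
  f <- apply(X, 1, eval_mask)
  best_i <- which.min(f)
  Xbest <- X[best_i, ]; fbest <- f[best_i]
  trace <- numeric(0)
  if (cfg$max_iter > 0) {
    for (t in seq_len(cfg$max_iter)) {
      f <- apply(X, 1, eval_mask)
      if (min(f) < fbest) {
        fbest <- min(f); Xbest <- X[which.min(f), ]
      }
      trace <- c(trace, fbest)
      cst <- update_constants(t, cfg)
      M <- compute_masses(f, cfg$eps)
      A <- accelerations(X, M, cst$G, kbest_count(t, cfg), cfg)
      mv <- swarm_move(X, V, Xbest, A, cst$w, cfg)
      X <- mv$X; V <- mv$V
    }
  } else trace <- fbest
  list(mask = Xbest, fitness = fbest, trace = trace)
}
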