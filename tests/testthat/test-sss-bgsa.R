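test_that("wrapper fitness matches its closed form", {
  cfg <- fs_config()                        # alpha 0.9, beta 0.1
  expect_equal(fitness_value(rep(0, 10), 0, cfg), 0)
  expect_equal(fitness_value(rep(1, 10), 1, cfg), 1.0)
  mask <- c(rep(1, 7), rep(0, 18))          # 7 of 25 selected
  expect_equal(fitness_value(mask, 0.1, cfg), 0.118)
})

test_that("gravitational constant decays and inertia interpolates", {
  cfg <- fs_config(G0 = 100, g_decay = 15, w_max = 0.9, w_min = 0.4,
                   max_iter = 100)
  c0 <- update_constants(0, cfg)
  expect_equal(c0$G, 100)
  expect_equal(c0$w, 0.9)
  expect_equal(update_constants(100, cfg)$G, 100 * exp(-15))
  expect_equal(update_constants(50, cfg)$w, 0.65)
})

test_that("masses normalise and concentrate on the best agent", {
  expect_equal(compute_masses(c(0.2, 0.2, 0.2)), rep(1 / 3, 3))
  for (i in 1:20) {
    set.seed(i)
    f <- runif(sample(2:30, 1))
    M <- compute_masses(f)
    expect_equal(sum(M), 1)
    expect_true(all(M >= 0))
    expect_equal(which.max(M), which.min(f))
  }
  expect_equal(compute_masses(c(0.1, 0.3), eps = 1e-300), c(1, 0))
})

test_that("accelerations match a brute-force pairwise oracle", {
  set.seed(7)
  N <- 3; D <- 5
  X <- matrix(rbinom(N * D, 1, 0.5), N, D)
  M <- compute_masses(c(0.1, 0.5, 0.3))
  G <- 42; eps <- fs_config()$eps
  W1 <- matrix(1, N, N)
  A <- accelerations(X, M, G, kbest = N, weights = W1)
  # independent O(N^2 D) reference with unit weights
  ref <- matrix(0, N, D)
  for (i in 1:N) for (j in 1:N) {
    if (i == j) next
    Rij <- sqrt(sum((X[j, ] - X[i, ])^2))
    ref[i, ] <- ref[i, ] + G * M[j] / (Rij + eps) * (X[j, ] - X[i, ])
  }
  expect_equal(A, ref)
  # single agent: nothing attracts it
  expect_equal(accelerations(X[1, , drop = FALSE], 1, G, 1),
               matrix(0, 1, D))
  # coincident agents exert zero force
  X2 <- rbind(X[1, ], X[1, ])
  expect_equal(accelerations(X2, c(0.5, 0.5), G, 2,
                             weights = matrix(1, 2, 2)),
               matrix(0, 2, D))
})

test_that("sigmoid transfer hits its exact probabilities", {
  expect_equal(binarize(0, u = c(0.49, 0.51)), c(1L, 0L))
  expect_equal(binarize(log(3), u = c(0.74, 0.76)), c(1L, 0L))
  expect_equal(binarize(1e6, u = 1 - 1e-12), 1L)
  set.seed(2)
  expect_equal(mean(binarize(rep(log(3), 2e4))), 0.75, tolerance = 0.02)
})

test_that("spiral step centres on the incumbent and nulls at quarter angle", {
  x <- c(0, 1, 0, 1); xb <- c(1, 1, 0, 0)
  expect_equal(spiral_step(x, xb, theta = 0, b = 1), xb)
  expect_equal(spiral_step(x, xb, theta = 0.25, b = 1), x,
               tolerance = 1e-12)
})

test_that("swarm moves stay binary and SP = 0 is a pure velocity update", {
  set.seed(3)
  N <- 6; D <- 8
  X <- matrix(rbinom(N * D, 1, 0.5), N, D)
  V <- matrix(rnorm(N * D), N, D)
  A <- matrix(rnorm(N * D), N, D)
  cfg <- fs_config(spiral_prob = 0)
  mv <- swarm_move(X, V, X[1, ], A, w = 0.7, cfg)
  expect_equal(mv$V, 0.7 * V + A)
  expect_true(all(mv$X %in% c(0L, 1L)))
  mv2 <- swarm_move(X, V, X[1, ], A, w = 0.7, fs_config(spiral_prob = 1))
  expect_true(all(mv2$X %in% c(0L, 1L)))
})

test_that("a zero-error evaluator drives selection to a singleton mask", {
  cfg <- fs_config(n_agents = 10, max_iter = 30, seed = 5)
  res <- run_sss_bgsa(function(mask) 0, D = 3, cfg)
  expect_equal(res$fitness, cfg$beta / 3)
  expect_equal(sum(res$mask), 1)
})

test_that("the incumbent fitness trace never increases", {
  ds <- generate_dataset(synthetic_spec(n_samples = 150, seed = 19))
  st <- fit_preprocessor(ds)
  enc <- transform_dataset(ds, st)
  ev <- surrogate_evaluator(enc, inner_folds = 3, seed = 19)
  res <- run_sss_bgsa(ev, ncol(ds$values),
                      fs_config(n_agents = 8, max_iter = 20, seed = 19))
  expect_true(all(diff(res$trace) <= 0))
  expect_true(all(res$mask %in% c(0L, 1L)))
  expect_equal(res$fitness, min(res$trace))
  # Tmax = 0 returns the initial best
  res0 <- run_sss_bgsa(ev, ncol(ds$values),
                       fs_config(n_agents = 8, max_iter = 0, seed = 19))
  expect_length(res0$trace, 1)
})

test_that("the all-zero mask is penalised as worst-case error", {
  # an evaluator rewarding nothing: search must still avoid the empty mask
  res <- run_sss_bgsa(function(mask) 0.5, D = 4,
                      fs_config(n_agents = 6, max_iter = 10, seed = 8))
  expect_gte(sum(res$mask), 1)
})
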