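# exact Boltzmann distribution of a small RBM by enumerating all states
enumerate_rbm <- function(rbm) {
  m <- nrow(rbm$W); n <- ncol(rbm$W)
  vs <- as.matrix(expand.grid(rep(list(0:1), m)))
  hs <- as.matrix(expand.grid(rep(list(0:1), n)))
  grid <- expand.grid(v = seq_len(nrow(vs)), h = seq_len(nrow(hs)))
  E <- mapply(function(iv, ih) rbm_energy(rbm, vs[iv, ], hs[ih, ]),
              grid$v, grid$h)
  p <- exp(-E) / sum(exp(-E))
  list(vs = vs, hs = hs, grid = grid, p = p)
}

test_that("the energy function evaluates its closed form", {
  rbm <- rbm_params(matrix(0, 2, 1), c(0, 0), 0)
  expect_equal(rbm_energy(rbm, c(1, 1), 1), 0)
  rbm2 <- rbm_params(matrix(c(1, 1), 2, 1), c(0.3, -0.2), 0.7)
  expect_equal(rbm_energy(rbm2, c(0, 0), 0), 0)
  rbm3 <- rbm_params(matrix(c(1, 1), 2, 1), c(0, 0), 0)
  expect_equal(rbm_energy(rbm3, c(1, 1), 1), -2)
  expect_error(rbm_energy(rbm3, c(1, 1, 1), 1), "dimension")
})

test_that("conditionals are sigmoid and agree with the Boltzmann joint", {
  rbm0 <- rbm_params(matrix(0, 3, 2), rep(0, 3), rep(0, 2))
  expect_equal(hidden_given_visible(rbm0, c(1, 0, 1)),
               matrix(0.5, 1, 2))
  expect_equal(visible_given_hidden(rbm0, c(1, 0)),
               matrix(0.5, 1, 3))
  set.seed(4)
  rbm <- rbm_params(matrix(rnorm(6, 0, 0.8), 3, 2),
                    rnorm(3, 0, 0.3), rnorm(2, 0, 0.3))
  ex <- enumerate_rbm(rbm)
  # p(h_j = 1 | v) from the exact joint must match the sigmoid formula
  for (iv in seq_len(nrow(ex$vs))) {
    rows <- ex$grid$v == iv
    pv <- sum(ex$p[rows])
    for (j in 1:2) {
      on <- rows & (ex$hs[ex$grid$h, j] == 1)
      expect_equal(sum(ex$p[on]) / pv,
                   hidden_given_visible(rbm, ex$vs[iv, ])[1, j],
                   tolerance = 1e-12)
    }
  }
  probs <- hidden_given_visible(rbm, ex$vs)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("CD-1 with zero learning rate leaves parameters unchanged", {
  set.seed(1)
  rbm <- rbm_init(4, 3, sd = 0.1)
  cfg <- train_config(learning_rate = 0)   # cd1_step uses learning_rate
  out <- cd1_step(rbm, matrix(rbinom(8, 1, 0.5), 2, 4), cfg)
  expect_equal(out$W, rbm$W)
  expect_equal(out$a, rbm$a)
  expect_equal(out$b, rbm$b)
})

test_that("pretraining reduces reconstruction error on a two-mode toy set", {
  set.seed(6)
  proto <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  data <- proto[rep(1:2, each = 30), ]
  data <- abs(data - (matrix(runif(length(data)), nrow(data)) < 0.05))
  stack <- pretrain_stack(data, 4,
                          train_config(epochs = 50, batch_size = 10,
                                       seed = 6))
  rec <- stack[[1]]$recon_history
  expect_lt(mean(tail(rec, 5)), mean(head(rec, 3)))
})

test_that("stacked pretraining chains layer shapes and is seed-deterministic", {
  set.seed(2)
  data <- matrix(runif(7 * 40), 40, 7)
  cfg <- train_config(epochs = 3, seed = 9)
  stack <- pretrain_stack(data, c(64, 32), cfg)
  expect_equal(dim(stack[[1]]$W), c(7, 64))
  expect_equal(dim(stack[[2]]$W), c(64, 32))
  stack2 <- pretrain_stack(data, c(64, 32), cfg)
  expect_identical(stack[[1]]$W, stack2[[1]]$W)
  # zero epochs: the stack is its (seeded) random initialisation
  s0 <- pretrain_stack(data, c(5, 3), train_config(epochs = 0, seed = 9))
  expect_equal(length(s0[[1]]$recon_history), 0)
})

test_that("backprop gradients agree with finite differences", {
  set.seed(11)
  X <- matrix(rnorm(4 * 5), 4, 5)
  y <- c(0, 1, 1, 0); Y <- cbind(1 - y, y)
  stack <- pretrain_stack(matrix(runif(20), 4, 5), c(4, 3),
                          train_config(epochs = 0, seed = 1))
  wts <- dbnn_from_stack(stack, seed = 1)$wts
  for (l in 1:2) wts$W[[l]] <- matrix(rnorm(length(wts$W[[l]]), 0, 0.5),
                                      nrow(wts$W[[l]]))
  wts$Ws <- matrix(rnorm(length(wts$Ws), 0, 0.5), nrow(wts$Ws))
  g <- spiralselect:::.dbnn_grad(wts, X, Y, lambda = 1e-4)
  eps <- 1e-6
  for (l in 1:2) for (k in sample(length(wts$W[[l]]), 4)) {
    wp <- wts; wp$W[[l]][k] <- wp$W[[l]][k] + eps
    wm <- wts; wm$W[[l]][k] <- wm$W[[l]][k] - eps
    num <- (spiralselect:::.dbnn_grad(wp, X, Y, 1e-4)$loss -
              spiralselect:::.dbnn_grad(wm, X, Y, 1e-4)$loss) / (2 * eps)
    expect_equal(g$gW[[l]][k], num, tolerance = 1e-5)
  }
  for (k in seq_along(wts$Ws)) {
    wp <- wts; wp$Ws[k] <- wp$Ws[k] + eps
    wm <- wts; wm$Ws[k] <- wm$Ws[k] - eps
    num <- (spiralselect:::.dbnn_grad(wp, X, Y, 1e-4)$loss -
              spiralselect:::.dbnn_grad(wm, X, Y, 1e-4)$loss) / (2 * eps)
    expect_equal(g$gWs[k], num, tolerance = 1e-5)
  }
})

test_that("fine-tuning fits separable data and keeps the best snapshot", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  cfg <- train_config(learning_rate = 0.1, epochs = 5,
                      finetune_epochs = 150, patience = 30, seed = 12)
  m <- dbnn_train(X, y, c(16, 8), cfg)
  p_tr <- predict_proba(m, X)[, 2]
  expect_gt(mean((p_tr > 0.5) == y), 0.95)
  h <- m$train_history
  expect_lte(m$best_valid_loss, min(h$valid_loss))
  expect_error(dbnn_finetune(m, X, y, X[0, , drop = FALSE], integer(0),
                             cfg), "validation")
})

test_that("predicted probabilities are deterministic simplex rows", {
  set.seed(13)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- rbinom(20, 1, 0.5)
  m <- dbnn_train(X, y, c(6, 3),
                  train_config(epochs = 2, finetune_epochs = 10,
                               patience = 5, seed = 13))
  P <- predict_proba(m, X)
  expect_equal(rowSums(P), rep(1, 20))
  expect_equal(predict_proba(m, X[c(1, 1), ])[1, ],
               predict_proba(m, X[c(1, 1), ])[2, ])
  expect_error(predict_proba(m, X[, 1:3]), "expects")
  # zero-weight softmax head is indifferent
  m0 <- m
  m0$wts$Ws[] <- 0; m0$wts$bs[] <- 0
  expect_equal(predict_proba(m0, X), matrix(0.5, 20, 2),
               ignore_attr = TRUE)
})
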