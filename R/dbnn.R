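#' Restricted Boltzmann machine parameters
#'
#' @param W m x n weight matrix (visible x hidden).
#' @param a visible bias vector, length m.
#' @param b hidden bias vector, length n.
#' @return An object of class `rbm_params`.
#' @export
rbm_params <- function(W, a, b) {
  W <- as.matrix(W)
  stopifnot(length(a) == nrow(W), length(b) == ncol(W),
            all(is.finite(W)), all(is.finite(a)), all(is.finite(b)))
  structure(list(W = W, a = as.numeric(a), b = as.numeric(b),
                 dW = W * 0, da = a * 0, db = b * 0),
            class = "rbm_params")
}

#' @rdname rbm_params
#' @param m,n visible and hidden layer sizes.
#' @param sd weight initialisation scale.
#' @param visible `"bernoulli"` (binary/mean-field visibles) or
#'   `"gaussian"` (unit-variance linear visibles, for standardised
#'   continuous inputs).
#' @export
rbm_init <- function(m, n, sd = 0.01, visible = "bernoulli") {
  r <- rbm_params(matrix(stats::rnorm(m * n, 0, sd), m, n),
                  rep(0, m), rep(0, n))
  r$visible <- visible
  r
}

#' Training configuration for RBM pretraining and network fine-tuning
#'
#' Defaults follow the reference protocol: learning rate 0.01, momentum
#' 0.9, 50 pretraining epochs, dropout 0.3 and L2 weight decay 1e-4 during
#' fine-tuning, early-stopping patience 10, batch size 16.
#'
#' @param learning_rate SGD learning rate eta for supervised fine-tuning
#'   (the hyperparameter the herding optimiser tunes).
#' @param pretrain_learning_rate CD-1 learning rate for RBM pretraining
#'   (0.01 per the pretraining protocol; kept separate so tuning the
#'   fine-tuning rate cannot destabilise the generative init).
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty lambda (weights only, not biases).
#' @param epochs pretraining epochs per RBM.
#' @param finetune_epochs cap on supervised fine-tuning epochs (early
#'   stopping usually halts sooner).
#' @param dropout_rate hidden-unit dropout probability during fine-tuning.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param batch_size minibatch size.
#' @param seed integer RNG seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, pretrain_learning_rate = 0.01,
                         momentum = 0.9, weight_decay = 1e-4, epochs = 50,
                         finetune_epochs = 200, dropout_rate = 0.3,
                         patience = 20, batch_size = 16, seed = 1) {
  stopifnot(learning_rate >= 0, pretrain_learning_rate >= 0,
            momentum >= 0, momentum < 1,
            weight_decay >= 0, dropout_rate >= 0, dropout_rate < 1,
            epochs >= 0, finetune_epochs >= 0, patience >= 1,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 pretrain_learning_rate = pretrain_learning_rate,
                 momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 dropout_rate = dropout_rate, patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' RBM energy of a joint (visible, hidden) configuration
#'
#' `E(v,h) = -sum(a*v) - sum(b*h) - v' W h`.
#'
#' @param rbm an [rbm_params()].
#' @param v visible vector.
#' @param h hidden vector.
#' @return The scalar energy.
#' @export
rbm_energy <- function(rbm, v, h) {
  if (length(v) != nrow(rbm$W) || length(h) != ncol(rbm$W))
    stop("dimension mismatch between (v, h) and the RBM")
  -sum(rbm$a * v) - sum(rbm$b * h) - as.numeric(t(v) %*% rbm$W %*% h)
}

#' RBM conditional distributions
#'
#' `p(h_j = 1 | v) = sigmoid(W' v + b)` and
#' `p(v_i = 1 | h) = sigmoid(W h + a)`, rowwise over a matrix of
#' configurations.
#'
#' @param rbm an [rbm_params()].
#' @param V matrix of visible rows (or a single vector).
#' @param H matrix of hidden rows (or a single vector).
#' @return Matrix of Bernoulli probabilities in (0,1).
#' @export
hidden_given_visible <- function(rbm, V) {
  V <- matrix(V, ncol = nrow(rbm$W))
  stats::plogis(sweep(V %*% rbm$W, 2, rbm$b, "+"))
}

#' @rdname hidden_given_visible
#' @export
visible_given_hidden <- function(rbm, H) {
  H <- matrix(H, ncol = ncol(rbm$W))
  pre <- sweep(H %*% t(rbm$W), 2, rbm$a, "+")
  if (identical(rbm$visible, "gaussian")) pre else stats::plogis(pre)
}

#' One CD-1 parameter update on a minibatch
#'
#' Contrastive divergence with a single Gibbs step: hidden states are
#' sampled from `p(h|v)`, visibles reconstructed as probabilities, and the
#' positive/negative statistics differenced.  Updates use learning rate
#' eta, momentum alpha and weight decay lambda (applied to W only).
#'
#' @param rbm an [rbm_params()] (carries its momentum buffers).
#' @param batch matrix of visible rows in [0,1].
#' @param cfg a [train_config()].
#' @return The updated `rbm_params`.
#' @export
cd1_step <- function(rbm, batch, cfg = train_config()) {
  batch <- matrix(batch, ncol = nrow(rbm$W))
  nb <- nrow(batch)
  stopifnot(nb >= 1)
  ph <- hidden_given_visible(rbm, batch)
  hs <- matrix(as.numeric(stats::runif(length(ph)) < ph), nrow(ph), ncol(ph))
  pv <- visible_given_hidden(rbm, hs)
  ph2 <- hidden_given_visible(rbm, pv)
  gW <- (t(batch) %*% ph - t(pv) %*% ph2) / nb
  ga <- colMeans(batch) - colMeans(pv)
  gb <- colMeans(ph) - colMeans(ph2)
  rbm$dW <- cfg$learning_rate * (gW - cfg$weight_decay * rbm$W) +
    cfg$momentum * rbm$dW
  rbm$da <- cfg$learning_rate * ga + cfg$momentum * rbm$da
  rbm$db <- cfg$learning_rate * gb + cfg$momentum * rbm$db
  rbm$W <- rbm$W + rbm$dW
  rbm$a <- rbm$a + rbm$da
  rbm$b <- rbm$b + rbm$db
  rbm
}

# one pretraining pass over the data in shuffled minibatches;
# returns the rbm and the epoch's mean reconstruction error
.rbm_epoch <- function(rbm, data, cfg) {
  n <- nrow(data)
  ord <- sample.int(n)
  rec <- 0
  for (start in seq(1, n, by = cfg$batch_size)) {
    idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
    batch <- data[idx, , drop = FALSE]
    rbm <- cd1_step(rbm, batch, cfg)
    ph <- hidden_given_visible(rbm, batch)
    hs <- matrix(as.numeric(stats::runif(length(ph)) < ph),
                 nrow(ph), ncol(ph))
    rec <- rec + sum((batch - visible_given_hidden(rbm, hs))^2)
  }
  list(rbm = rbm, recon = rec / n)
}

#' Greedy layerwise pretraining of an RBM stack
#'
#' Trains the first RBM on the encoded input data (Gaussian visibles for
#' standardised inputs, Bernoulli/mean-field for [0,1] inputs), then each
#' further RBM — always Bernoulli — on the hidden activation probabilities
#' of the previous one.
#'
#' @param data matrix of visible rows.
#' @param layer_sizes hidden layer widths, e.g. `c(64, 32)`.
#' @param cfg a [train_config()].
#' @param visible visible-unit type of the first RBM.
#' @return list of `rbm_params`, one per hidden layer, each carrying its
#'   per-epoch reconstruction-error history as `recon_history`.
#' @export
pretrain_stack <- function(data, layer_sizes, cfg = train_config(),
                           visible = "bernoulli") {
  set.seed(cfg$seed)
  if (!is.null(cfg$pretrain_learning_rate))
    cfg$learning_rate <- cfg$pretrain_learning_rate
  stack <- vector("list", length(layer_sizes))
  input <- as.matrix(data)
  for (l in seq_along(layer_sizes)) {
    rbm <- rbm_init(ncol(input), layer_sizes[l],
                    visible = if (l == 1) visible else "bernoulli")
    recon <- numeric(0)
    if (cfg$epochs > 0)
      for (e in seq_len(cfg$epochs)) {
        res <- .rbm_epoch(rbm, input, cfg)
        rbm <- res$rbm
        recon <- c(recon, res$recon)
      }
    rbm$recon_history <- recon
    stack[[l]] <- rbm
    input <- hidden_given_visible(rbm, input)
  }
  stack
}

# forward pass of the feed-forward net; drop_masks NULL at inference.
# S[[l]] is the sigmoid activation, H[[l]] the (possibly dropout-masked)
# layer output actually fed forward.
.dbnn_forward <- function(wts, X, drop_masks = NULL) {
  S <- list(); H <- list(); A <- X
  for (l in seq_along(wts$W)) {
    S[[l]] <- stats::plogis(sweep(A %*% wts$W[[l]], 2, wts$b[[l]], "+"))
    A <- if (is.null(drop_masks)) S[[l]] else S[[l]] * drop_masks[[l]]
    H[[l]] <- A
  }
  logits <- sweep(A %*% wts$Ws, 2, wts$bs, "+")
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits) / rowSums(exp(logits))
  list(S = S, H = H, P = P)
}

# cross-entropy + L2 loss and analytic gradients for one batch
.dbnn_grad <- function(wts, X, Y, lambda, drop_masks = NULL) {
  fw <- .dbnn_forward(wts, X, drop_masks)
  n <- nrow(X)
  loss <- -mean(rowSums(Y * log(pmax(fw$P, 1e-12)))) +
    lambda / 2 * (sum(unlist(lapply(wts$W, function(w) sum(w^2)))) +
                    sum(wts$Ws^2))
  delta <- (fw$P - Y) / n
  L <- length(wts$W)
  gWs <- t(fw$H[[L]]) %*% delta + lambda * wts$Ws
  gbs <- colSums(delta)
  gW <- vector("list", L); gb <- vector("list", L)
  back <- delta %*% t(wts$Ws)            # gradient wrt layer output H[[l]]
  for (l in L:1) {
    if (!is.null(drop_masks)) back <- back * drop_masks[[l]]
    back <- back * fw$S[[l]] * (1 - fw$S[[l]])  # through the sigmoid
    Ain <- if (l == 1) X else fw$H[[l - 1]]
    gW[[l]] <- t(Ain) %*% back + lambda * wts$W[[l]]
    gb[[l]] <- colSums(back)
    if (l > 1) back <- back %*% t(wts$W[[l]])
  }
  list(loss = loss, gW = gW, gb = gb, gWs = gWs, gbs = gbs, P = fw$P)
}

#' Deep belief network classifier from a pretrained stack
#'
#' Initialises the feed-forward weights from the RBM stack and attaches a
#' small random softmax head for the two classes.
#'
#' @param stack list of [rbm_params()] from [pretrain_stack()].
#' @param scale list with `min` and `rng` giving the per-column [0,1]
#'   input rescaling (see [dbnn_train()]).
#' @param seed RNG seed for the softmax head initialisation.
#' @return An object of class `dbnn` (untuned).
#' @export
dbnn_from_stack <- function(stack, scale = NULL, seed = 1) {
  set.seed(seed)
  wts <- list(W = lapply(stack, `[[`, "W"),
              b = lapply(stack, `[[`, "b"),
              Ws = matrix(stats::rnorm(ncol(stack[[length(stack)]]$W) * 2,
                                       0, 0.01),
                          ncol(stack[[length(stack)]]$W), 2),
              bs = c(0, 0))
  structure(list(rbm_stack = stack, wts = wts, scale = scale,
                 train_history = NULL, finetuned = FALSE),
            class = "dbnn")
}

#' Supervised fine-tuning with dropout, L2 and early stopping
#'
#' Minimises cross-entropy by momentum SGD with inverted dropout on the
#' hidden layers and L2 decay on the weight matrices; training stops when
#' the validation loss has not improved for `patience` epochs, and the
#' best-validation snapshot is returned.
#'
#' @param model a [dbnn_from_stack()] model.
#' @param X,y training inputs (already on the model's [0,1] scale) and 0/1
#'   labels.
#' @param Xv,yv validation inputs and labels (must be nonempty).
#' @param cfg a [train_config()].
#' @return The fine-tuned `dbnn` with `train_history` (per-epoch train and
#'   validation loss) and `best_valid_loss`.
#' @export
dbnn_finetune <- function(model, X, y, Xv, yv, cfg = train_config()) {
  stopifnot(inherits(model, "dbnn"))
  if (is.null(Xv) || nrow(as.matrix(Xv)) == 0)
    stop("fine-tuning requires a nonempty validation split")
  set.seed(cfg$seed + 1L)
  X <- as.matrix(X); Xv <- as.matrix(Xv)
  Y <- cbind(1 - y, y); Yv <- cbind(1 - yv, yv)
  wts <- model$wts
  L <- length(wts$W)
  vel <- list(W = lapply(wts$W, function(w) w * 0),
              b = lapply(wts$b, function(b) b * 0),
              Ws = wts$Ws * 0, bs = wts$bs * 0)
  valid_loss <- function(w) .dbnn_grad(w, Xv, Yv, cfg$weight_decay)$loss
  best <- list(wts = wts, loss = valid_loss(wts), epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     valid_loss = numeric(0))
  stall <- 0L
  n <- nrow(X)
  n_epochs <- if (!is.null(cfg$finetune_epochs)) cfg$finetune_epochs
              else cfg$epochs
  for (e in seq_len(n_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      masks <- NULL
      if (cfg$dropout_rate > 0)
        masks <- lapply(seq_len(L), function(l)
          matrix(as.numeric(stats::runif(length(idx) * ncol(wts$W[[l]])) >
                              cfg$dropout_rate) / (1 - cfg$dropout_rate),
                 length(idx), ncol(wts$W[[l]])))
      g <- .dbnn_grad(wts, X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                      cfg$weight_decay, masks)
      for (l in seq_len(L)) {
        vel$W[[l]] <- cfg$momentum * vel$W[[l]] - cfg$learning_rate * g$gW[[l]]
        vel$b[[l]] <- cfg$momentum * vel$b[[l]] - cfg$learning_rate * g$gb[[l]]
        wts$W[[l]] <- wts$W[[l]] + vel$W[[l]]
        wts$b[[l]] <- wts$b[[l]] + vel$b[[l]]
      }
      vel$Ws <- cfg$momentum * vel$Ws - cfg$learning_rate * g$gWs
      vel$bs <- cfg$momentum * vel$bs - cfg$learning_rate * g$gbs
      wts$Ws <- wts$Ws + vel$Ws
      wts$bs <- wts$bs + vel$bs
      ep_loss <- ep_loss + g$loss; nb <- nb + 1
    }
    vl <- valid_loss(wts)
    hist <- rbind(hist, data.frame(epoch = e, train_loss = ep_loss / nb,
                                   valid_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(wts = wts, loss = vl, epoch = e)
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= cfg$patience) break
  }
  model$wts <- best$wts
  model$train_history <- hist
  model$best_valid_loss <- best$loss
  model$finetuned <- TRUE
  model
}

#' Class probabilities from a fine-tuned network
#'
#' Deterministic forward pass (dropout disabled); rows sum to 1.  Column 1
#' is the negative class, column 2 the positive (disease) class.
#'
#' @param model a fine-tuned `dbnn`.
#' @param X input matrix on the raw encoded scale used at training time
#'   (the model applies its stored [0,1] rescaling), or already scaled if
#'   the model has no `scale`.
#' @return n x 2 matrix of class probabilities.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "dbnn"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$wts$W[[1]]))
    stop("input has ", ncol(X), " columns but the model expects ",
         nrow(model$wts$W[[1]]))
  if (!is.null(model$scale)) {
    X <- sweep(sweep(X, 2, model$scale$center), 2, model$scale$scale, "/")
    if (identical(model$scale$type, "minmax")) X <- pmin(pmax(X, 0), 1)
  }
  .dbnn_forward(model$wts, X)$P
}

#' Pretrain and fine-tune a network on an encoded training fold
#'
#' Convenience wrapper binding the full classifier protocol: rescale the
#' encoded inputs, greedily pretrain the RBM stack, then fine-tune with a
#' stratified validation split carved from the training rows.  With
#' `visible = "gaussian"` (default) inputs are column-standardised and the
#' first RBM has Gaussian visible units; `visible = "meanfield"` min-max
#' rescales to [0,1] and treats inputs as Bernoulli probabilities.
#'
#' @param X encoded training matrix.
#' @param y 0/1 labels.
#' @param layer_sizes hidden widths (default `c(64, 32)`).
#' @param cfg a [train_config()].
#' @param valid_frac fraction of rows held out (stratified) for
#'   early-stopping validation when `Xv` is not supplied.
#' @param Xv,yv explicit validation split; when given, all of `X` is used
#'   for training.
#' @param synthetic optional logical flags marking oversampled rows of
#'   `X`; the carved validation split is drawn from real rows only, so
#'   synthetic rows never steer early stopping.
#' @param visible visible-unit handling: `"gaussian"` or `"meanfield"`.
#' @return A fine-tuned `dbnn`.
#' @export
dbnn_train <- function(X, y, layer_sizes = c(64, 32), cfg = train_config(),
                       valid_frac = 0.2, Xv = NULL, yv = NULL,
                       synthetic = NULL,
                       visible = c("gaussian", "meanfield")) {
  visible <- match.arg(visible)
  X <- as.matrix(X)
  if (visible == "meanfield") {
    center <- apply(X, 2, min)
    scl <- apply(X, 2, max) - center
  } else {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
  }
  scl[scl == 0] <- 1
  rescale <- function(M) {
    M <- sweep(sweep(as.matrix(M), 2, center), 2, scl, "/")
    if (visible == "meanfield") pmin(pmax(M, 0), 1) else M
  }
  Xs <- rescale(X)
  if (is.null(Xv)) {
    real <- if (is.null(synthetic)) seq_along(y) else which(!synthetic)
    set.seed(cfg$seed)
    vidx <- real[unlist(caret::createDataPartition(factor(y[real]),
                                                   p = valid_frac,
                                                   list = TRUE))]
    Xv <- Xs[vidx, , drop = FALSE]; yv <- y[vidx]
    Xtr <- Xs[-vidx, , drop = FALSE]; ytr <- y[-vidx]
  } else {
    Xv <- rescale(Xv)
    Xtr <- Xs; ytr <- y
  }
  stack <- pretrain_stack(Xtr, layer_sizes, cfg,
                          visible = if (visible == "gaussian") "gaussian"
                                    else "bernoulli")
  model <- dbnn_from_stack(
    stack,
    scale = list(type = if (visible == "meanfield") "minmax" else "standard",
                 center = center, scale = scl),
    seed = cfg$seed)
  dbnn_finetune(model, Xtr, ytr, Xv, yv, cfg)
}
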