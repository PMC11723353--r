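# Pulse-level 1D convolutional classifier. The network maps one normalized
# 27-sample pulse to a threat probability through five convolution layers
# (two overlapping max-pool stages), a 64-wide flatten and an 8-4-1 dense
# head with sigmoid output. Feature lengths along the stack are
# 27 -> 25 -> 25 -> 11 -> 9 -> 7 -> 3 -> 1.
#
# The network is small enough that training is implemented directly in
# vectorized R (im2col convolutions over BLAS matrix products, hand-derived
# backpropagation, Adam, inverted dropout, validation-loss early stopping),
# which keeps every arithmetic step seeded and reproducible. Gradients are
# verified against finite differences in the test suite.

#' Classifier configuration
#'
#' @param conv_filters filter counts of the five convolution layers.
#' @param kernel_size convolution kernel length.
#' @param pool1,pool2 `c(pool, stride)` of the two max-pool stages (after the
#'   second and fourth convolutions).
#' @param dense_units widths of the two hidden dense layers.
#' @param dropout_rate dropout after each hidden dense layer (training only).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap (training never passes the 30th epoch at the
#'   default, with validation-loss early stopping allowed to end it sooner).
#' @param val_fraction fraction held out as a stratified validation set.
#' @param early_stop_patience epochs without validation improvement tolerated
#'   before stopping (best weights are restored).
#' @param input_len pulse length accepted by the network.
#' @param decision_threshold probability at or above which a pulse is
#'   labeled 1.
#' @param seed RNG seed for initialization, the validation split, shuffling
#'   and dropout.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(conv_filters = c(32L, 32L, 32L, 32L, 64L),
                              kernel_size = 3L,
                              pool1 = c(4L, 2L), pool2 = c(2L, 2L),
                              dense_units = c(8L, 4L),
                              dropout_rate = 0.2,
                              learning_rate = 1e-3,
                              batch_size = 128L,
                              max_epochs = 30L,
                              val_fraction = 0.2,
                              early_stop_patience = 5L,
                              input_len = 27L,
                              decision_threshold = 0.5,
                              seed = 1L) {
  if (length(conv_filters) != 5L || any(conv_filters < 1))
    stop_cfg("conv_filters", "must be five positive filter counts")
  if (length(dense_units) != 2L || any(dense_units < 1))
    stop_cfg("dense_units", "must be two positive widths")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_cfg("val_fraction", "must lie strictly in (0, 1)")
  cfg <- list(conv_filters = as.integer(conv_filters),
              kernel_size = check_positive_int(kernel_size, "kernel_size"),
              pool1 = as.integer(pool1), pool2 = as.integer(pool2),
              dense_units = as.integer(dense_units),
              dropout_rate = check_prob(dropout_rate, "dropout_rate"),
              learning_rate = check_nonneg(learning_rate, "learning_rate"),
              batch_size = check_positive_int(batch_size, "batch_size"),
              max_epochs = check_positive_int(max_epochs, "max_epochs"),
              val_fraction = as.numeric(val_fraction),
              early_stop_patience = check_positive_int(early_stop_patience, "early_stop_patience"),
              input_len = check_positive_int(input_len, "input_len"),
              decision_threshold = check_prob(decision_threshold, "decision_threshold"),
              seed = as.integer(seed))
  class(cfg) <- "classifier_config"
  cfg
}

pool_out_len <- function(len, p, s) (len - p) %/% s + 1L

#' Feature-length trace through the convolution/pooling stack
#'
#' @param cfg a [classifier_config()].
#' @return list with `conv_lengths` (feature length after each of the seven
#'   conv/pool stages), `flatten_width` and `dense_units`.
#' @export
model_feature_trace <- function(cfg = classifier_config()) {
  k <- cfg$kernel_size
  l <- cfg$input_len
  lens <- integer(7)
  lens[1] <- l - k + 1L                            # conv 1, valid
  lens[2] <- lens[1]                               # conv 2, same padding
  lens[3] <- pool_out_len(lens[2], cfg$pool1[1], cfg$pool1[2])
  lens[4] <- lens[3] - k + 1L                      # conv 3
  lens[5] <- lens[4] - k + 1L                      # conv 4
  lens[6] <- pool_out_len(lens[5], cfg$pool2[1], cfg$pool2[2])
  lens[7] <- lens[6] - k + 1L                      # conv 5
  if (any(lens < 1L))
    stop_cfg("input_len", "conv/pool stack collapses a feature map below length 1")
  list(conv_lengths = lens,
       flatten_width = lens[7] * cfg$conv_filters[5],
       dense_units = c(cfg$dense_units, 1L))
}

#' Build an untrained pulse classifier
#'
#' Initializes all weights deterministically from `cfg$seed` (He-style
#' scaling for the rectified layers).
#'
#' @param cfg a [classifier_config()].
#' @return an untrained `classifier_model`.
#' @export
build_model <- function(cfg = classifier_config()) {
  trace <- model_feature_trace(cfg)
  k <- cfg$kernel_size
  f <- cfg$conv_filters
  in_ch <- c(1L, f[1], f[2], f[3], f[4])  # channels entering conv 1..5
  set.seed(derive_seed(cfg$seed, 41L))
  weights <- list()
  for (i in 1:5) {
    fan_in <- k * in_ch[i]
    weights[[paste0("Wc", i)]] <- matrix(stats::rnorm(fan_in * f[i], 0, sqrt(2 / fan_in)),
                                         fan_in, f[i])
    weights[[paste0("bc", i)]] <- numeric(f[i])
  }
  dims <- c(trace$flatten_width, cfg$dense_units, 1L)
  for (i in 1:3) {
    sdw <- if (i == 3) sqrt(1 / dims[i]) else sqrt(2 / dims[i])
    weights[[paste0("Wd", i)]] <- matrix(stats::rnorm(dims[i] * dims[i + 1], 0, sdw),
                                         dims[i], dims[i + 1])
    weights[[paste0("bd", i)]] <- numeric(dims[i + 1])
  }
  structure(list(cfg = cfg, trace = trace, weights = weights,
                 normalization = NULL, trained = FALSE, history = NULL),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("classifier_model: 1D-CNN, input %d, %d parameters, %s\n",
              x$cfg$input_len, np,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# ---- layer primitives (batch-first arrays: n x len x channels) -------------

conv1d_forward <- function(X, W, b, pad = 0L, k) {
  d <- dim(X); n <- d[1]; len <- d[2]; ch <- d[3]
  if (pad > 0L) {
    Xp <- array(0, c(n, len + 2L * pad, ch))
    Xp[, (pad + 1L):(pad + len), ] <- X
    X <- Xp; len <- len + 2L * pad
  }
  out_len <- len - k + 1L
  M <- matrix(0, n * out_len, k * ch)
  for (j in seq_len(k)) {
    s <- X[, j:(j + out_len - 1L), , drop = FALSE]
    dim(s) <- c(n * out_len, ch)
    M[, ((j - 1L) * ch + 1L):(j * ch)] <- s
  }
  Y <- M %*% W
  Y <- Y + rep(b, each = n * out_len) # per-channel bias, recycled column-wise
  dim(Y) <- c(n, out_len, ncol(W))
  list(Y = Y, M = M, n = n, len = len, ch = ch, out_len = out_len, pad = pad, k = k)
}

conv1d_backward <- function(dY, cache, W) {
  n <- cache$n; out_len <- cache$out_len; ch <- cache$ch; k <- cache$k
  dYm <- dY; dim(dYm) <- c(n * out_len, ncol(W))
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(W)
  dX <- array(0, c(n, cache$len, ch))
  for (j in seq_len(k)) {
    s <- dM[, ((j - 1L) * ch + 1L):(j * ch), drop = FALSE]
    dim(s) <- c(n, out_len, ch)
    dX[, j:(j + out_len - 1L), ] <- dX[, j:(j + out_len - 1L), , drop = FALSE] + s
  }
  if (cache$pad > 0L) {
    orig <- cache$len - 2L * cache$pad
    dX <- dX[, (cache$pad + 1L):(cache$pad + orig), , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

maxpool_forward <- function(X, p, s) {
  d <- dim(X); n <- d[1]; len <- d[2]; ch <- d[3]
  out_len <- pool_out_len(len, p, s)
  starts <- (seq_len(out_len) - 1L) * s + 1L
  maxv <- array(-Inf, c(n, out_len, ch))
  arg <- array(1L, c(n, out_len, ch))
  for (j in seq_len(p)) {
    cand <- X[, starts + j - 1L, , drop = FALSE]
    upd <- cand > maxv
    maxv[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(Y = maxv, arg = arg, starts = starts, p = p, len = len, n = n, ch = ch)
}

maxpool_backward <- function(dY, cache) {
  dX <- array(0, c(cache$n, cache$len, cache$ch))
  for (j in seq_len(cache$p)) {
    idx <- cache$starts + j - 1L
    dX[, idx, ] <- dX[, idx, , drop = FALSE] + dY * (cache$arg == j)
  }
  dX
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass. X: n x input_len normalized matrix. In training mode dropout
# masks are drawn from the current RNG stream (inverted dropout).
nn_forward <- function(model, X, train = FALSE) {
  cfg <- model$cfg; w <- model$weights; k <- cfg$kernel_size
  n <- nrow(X)
  A <- X; dim(A) <- c(n, ncol(X), 1L)
  cache <- list()

  c1 <- conv1d_forward(A, w$Wc1, w$bc1, 0L, k); Z1 <- c1$Y; A1 <- relu(Z1)
  c2 <- conv1d_forward(A1, w$Wc2, w$bc2, (k - 1L) %/% 2L, k); Z2 <- c2$Y; A2 <- relu(Z2)
  p1 <- maxpool_forward(A2, cfg$pool1[1], cfg$pool1[2])
  c3 <- conv1d_forward(p1$Y, w$Wc3, w$bc3, 0L, k); Z3 <- c3$Y; A3 <- relu(Z3)
  c4 <- conv1d_forward(A3, w$Wc4, w$bc4, 0L, k); Z4 <- c4$Y; A4 <- relu(Z4)
  p2 <- maxpool_forward(A4, cfg$pool2[1], cfg$pool2[2])
  c5 <- conv1d_forward(p2$Y, w$Wc5, w$bc5, 0L, k); Z5 <- c5$Y; A5 <- relu(Z5)

  Fl <- A5; dim(Fl) <- c(n, model$trace$flatten_width)
  H1 <- relu(sweep(Fl %*% w$Wd1, 2, w$bd1, "+"))
  m1 <- NULL
  if (train && cfg$dropout_rate > 0) {
    m1 <- matrix(stats::runif(length(H1)) >= cfg$dropout_rate, nrow(H1), ncol(H1)) /
      (1 - cfg$dropout_rate)
    H1 <- H1 * m1
  }
  H2 <- relu(sweep(H1 %*% w$Wd2, 2, w$bd2, "+"))
  m2 <- NULL
  if (train && cfg$dropout_rate > 0) {
    m2 <- matrix(stats::runif(length(H2)) >= cfg$dropout_rate, nrow(H2), ncol(H2)) /
      (1 - cfg$dropout_rate)
    H2 <- H2 * m2
  }
  logit <- sweep(H2 %*% w$Wd3, 2, w$bd3, "+")
  prob <- sigmoid(as.numeric(logit))
  list(prob = prob,
       cache = list(c1 = c1, Z1 = Z1, A1 = A1, c2 = c2, Z2 = Z2, p1 = p1,
                    c3 = c3, Z3 = Z3, A3 = A3, c4 = c4, Z4 = Z4, p2 = p2,
                    c5 = c5, Z5 = Z5, Fl = Fl, H1 = H1, m1 = m1,
                    H2 = H2, m2 = m2, n = n))
}

# Backward pass for mean binary cross-entropy; returns gradients named like
# the weights.
nn_backward <- function(model, fw, y) {
  w <- model$weights; ca <- fw$cache; n <- ca$n
  g <- list()
  dlogit <- matrix((fw$prob - y) / n, n, 1L)
  g$Wd3 <- crossprod(ca$H2, dlogit); g$bd3 <- colSums(dlogit)
  dH2 <- dlogit %*% t(w$Wd3)
  if (!is.null(ca$m2)) dH2 <- dH2 * ca$m2
  dH2 <- dH2 * (ca$H2 > 0)
  g$Wd2 <- crossprod(ca$H1, dH2); g$bd2 <- colSums(dH2)
  dH1 <- dH2 %*% t(w$Wd2)
  if (!is.null(ca$m1)) dH1 <- dH1 * ca$m1
  dH1 <- dH1 * (ca$H1 > 0)
  g$Wd1 <- crossprod(ca$Fl, dH1); g$bd1 <- colSums(dH1)
  dFl <- dH1 %*% t(w$Wd1)
  dA5 <- dFl; dim(dA5) <- dim(ca$Z5)
  dZ5 <- dA5 * (ca$Z5 > 0)
  b5 <- conv1d_backward(dZ5, ca$c5, w$Wc5); g$Wc5 <- b5$dW; g$bc5 <- b5$db
  dA4 <- maxpool_backward(b5$dX, ca$p2)
  dZ4 <- dA4 * (ca$Z4 > 0)
  b4 <- conv1d_backward(dZ4, ca$c4, w$Wc4); g$Wc4 <- b4$dW; g$bc4 <- b4$db
  dZ3 <- b4$dX * (ca$Z3 > 0)
  b3 <- conv1d_backward(dZ3, ca$c3, w$Wc3); g$Wc3 <- b3$dW; g$bc3 <- b3$db
  dA2 <- maxpool_backward(b3$dX, ca$p1)
  dZ2 <- dA2 * (ca$Z2 > 0)
  b2 <- conv1d_backward(dZ2, ca$c2, w$Wc2); g$Wc2 <- b2$dW; g$bc2 <- b2$db
  dZ1 <- b2$dX * (ca$Z1 > 0)
  b1 <- conv1d_backward(dZ1, ca$c1, w$Wc1); g$Wc1 <- b1$dW; g$bc1 <- b1$db
  g
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(x) x * 0),
       v = lapply(weights, function(x) x * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

#' Stratified validation split
#'
#' Deterministic function of the seed only: per class, a `val_fraction`
#' share of indices is drawn without replacement for validation; the rest
#' train. The two index sets are disjoint by construction.
#'
#' @param y 0/1 label vector.
#' @param val_fraction validation share in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `val`.
#' @export
stratified_split <- function(y, val_fraction, seed) {
  set.seed(derive_seed(seed, 21L))
  val <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_val <- max(1L, floor(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Train the pulse classifier
#'
#' Minimizes mean binary cross-entropy with Adam over minibatches, using a
#' stratified validation split, dropout on the dense head, an epoch cap of
#' `max_epochs` (30 by default) and validation-loss early stopping with
#' best-weight restoration. Fully deterministic given the seed and data.
#'
#' @param model an untrained model from [build_model()].
#' @param pulses a labeled [pulse_set()] containing both classes.
#' @param cfg a [classifier_config()]; defaults to the model's.
#' @param normalization optional shared statistics from
#'   [compute_normalization()]; computed from the training pulses when `NULL`.
#' @return the trained `classifier_model`, with `history` (per-epoch train
#'   loss, validation loss and validation accuracy) attached.
#' @export
train_classifier <- function(model, pulses, cfg = model$cfg, normalization = NULL) {
  X0 <- pulses$values
  y <- pulses$label
  if (anyNA(y)) stop("train_classifier(): all training pulses must be labeled", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("train_classifier(): training pulses contain a single class", call. = FALSE)
  if (ncol(X0) != cfg$input_len)
    stop(sprintf("train_classifier(): pulse length %d, network expects %d",
                 ncol(X0), cfg$input_len), call. = FALSE)
  if (is.null(normalization)) normalization <- compute_normalization(X0)
  X <- apply_normalization(X0, normalization)

  sp <- stratified_split(y, cfg$val_fraction, cfg$seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xva <- X[sp$val, , drop = FALSE]; yva <- y[sp$val]

  weights <- model$weights
  state <- adam_init(weights)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  hist <- vector("list", cfg$max_epochs)
  set.seed(derive_seed(cfg$seed, 31L))
  wait <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample(nrow(Xtr))
    bstarts <- seq(1L, length(ord), by = cfg$batch_size)
    tr_losses <- numeric(length(bstarts))
    for (bi in seq_along(bstarts)) {
      idx <- ord[bstarts[bi]:min(bstarts[bi] + cfg$batch_size - 1L, length(ord))]
      mtmp <- model; mtmp$weights <- weights
      fw <- nn_forward(mtmp, Xtr[idx, , drop = FALSE], train = TRUE)
      tr_losses[bi] <- bce_loss(fw$prob, ytr[idx])
      g <- nn_backward(mtmp, fw, ytr[idx])
      upd <- adam_step(weights, g, state, cfg$learning_rate)
      weights <- upd$weights; state <- upd$state
    }
    mtmp <- model; mtmp$weights <- weights
    pv <- nn_forward(mtmp, Xva, train = FALSE)$prob
    val_loss <- bce_loss(pv, yva)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(tr_losses),
                             val_loss = val_loss,
                             val_acc = mean((pv >= cfg$decision_threshold) == (yva == 1)))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, weights = weights, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$weights <- best$weights
  model$cfg <- cfg
  model$normalization <- normalization
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best$epoch
  model
}

#' Predict threat probability for pulses
#'
#' @param model a trained `classifier_model`.
#' @param pulse a [pulse_set()], numeric matrix (pulses in rows) or a single
#'   pulse vector.
#' @return data.frame with `prob` in \[0, 1\] and binary `label`
#'   (1 iff `prob >= decision_threshold`), one row per pulse.
#' @export
predict_pulse <- function(model, pulse) {
  if (!isTRUE(model$trained))
    stop("predict_pulse(): model has not been trained", call. = FALSE)
  X0 <- if (inherits(pulse, "pulse_set")) pulse$values else rbind(pulse)
  if (ncol(X0) != model$cfg$input_len)
    stop(sprintf("predict_pulse(): pulse length %d, network expects %d",
                 ncol(X0), model$cfg$input_len), call. = FALSE)
  if (nrow(X0) == 0) return(data.frame(prob = numeric(0), label = integer(0)))
  X <- apply_normalization(X0, model$normalization)
  p <- nn_forward(model, X, train = FALSE)$prob
  data.frame(prob = p, label = as.integer(p >= model$cfg$decision_threshold))
}
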