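# Stacked-LSTM branch network: a fully connected input layer, two LSTM
# layers and a fully connected output layer applied to the final time step,
# followed by softmax. Written directly against the standard gate equations
#   f_t = sigmoid(W_f [h_{t-1}, x_t] + b_f)
#   i_t = sigmoid(W_i [h_{t-1}, x_t] + b_i)
#   o_t = sigmoid(W_o [h_{t-1}, x_t] + b_o)
#   g_t = tanh  (W_c [h_{t-1}, x_t] + b_c)
#   c_t = f_t * c_{t-1} + i_t * g_t
#   h_t = o_t * tanh(c_t)
# with full backpropagation through time and Adam optimisation. Gate blocks
# are stored in the column order (f, i, g, o) of a single 4H-wide matrix.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Branch network configuration
#'
#' @param input_dim Per-step feature dimension: 96 (branch A,
#'   static + motion) or 62 (branch B, geometric).
#' @param num_classes Number of action classes.
#' @param hidden_size LSTM hidden size (default 128).
#' @param dropout_rate Dropout applied between the two LSTM layers during
#'   training (default 0.5).
#' @param learning_rate_init Initial Adam learning rate.
#' @param lr_halving_period_epochs Halve the learning rate every this many
#'   epochs (default 30).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (default 32).
#' @param class_weights Optional positive per-class loss weights; by default
#'   weights proportional to inverse class counts are derived from the
#'   training labels.
#' @param validation_fraction Stratified fraction of windows held out for
#'   per-epoch validation accuracy (default 0.3).
#' @param seed Integer seed controlling initialisation, shuffling, dropout
#'   and the validation split.
#' @return A `branch_config` list.
#' @export
branch_config <- function(input_dim, num_classes, hidden_size = 128,
                          dropout_rate = 0.5, learning_rate_init = 1e-3,
                          lr_halving_period_epochs = 30, epochs = 30,
                          batch_size = 32, class_weights = NULL,
                          validation_fraction = 0.3, seed = 1) {
  stopifnot(input_dim >= 1, num_classes >= 2, hidden_size >= 1,
            dropout_rate >= 0, dropout_rate < 1, learning_rate_init > 0,
            batch_size >= 1, epochs >= 1)
  structure(list(
    input_dim = as.integer(input_dim), num_classes = as.integer(num_classes),
    hidden_size = as.integer(hidden_size), dropout_rate = dropout_rate,
    learning_rate_init = learning_rate_init,
    lr_halving_period_epochs = as.integer(lr_halving_period_epochs),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    class_weights = class_weights,
    validation_fraction = validation_fraction,
    seed = as.integer(seed)
  ), class = "branch_config")
}

uinit <- function(nr, nc, fan_in) {
  k <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

#' Build an untrained branch network
#'
#' Allocates seeded parameters for the FC -> LSTM x2 -> FC architecture.
#' The forget-gate bias is initialised to 1, a standard stabilisation.
#'
#' @param config A [branch_config()].
#' @return An object of class `lstm_branch` (untrained).
#' @export
build_branch <- function(config) {
  D <- config$input_dim; H <- config$hidden_size; C <- config$num_classes
  set.seed(config$seed)
  params <- list(
    W_in = uinit(D, H, D), b_in = numeric(H),
    W1 = uinit(H, 4 * H, H), U1 = uinit(H, 4 * H, H), b1 = numeric(4 * H),
    W2 = uinit(H, 4 * H, H), U2 = uinit(H, 4 * H, H), b2 = numeric(4 * H),
    W_out = uinit(H, C, H), b_out = numeric(C)
  )
  params$b1[seq_len(H)] <- 1
  params$b2[seq_len(H)] <- 1
  structure(list(params = params, config = config, classes = NULL,
                 trained = FALSE, history = NULL,
                 val_accuracy = NA_real_),
            class = "lstm_branch")
}

# One LSTM layer over a full sequence. x: list of T matrices (N x H).
# Returns hidden states and, if keep_cache, everything BPTT needs.
lstm_layer_forward <- function(x, W, U, b, keep_cache = FALSE) {
  Tn <- length(x)
  N <- nrow(x[[1]])
  H <- ncol(W) / 4L
  h <- matrix(0, N, H)
  c_state <- matrix(0, N, H)
  hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(Tn)) {
    z <- x[[t]] %*% W + h %*% U + matrix(b, N, 4 * H, byrow = TRUE)
    f <- sigmoid(z[, i1, drop = FALSE])
    i_g <- sigmoid(z[, i2, drop = FALSE])
    g <- tanh(z[, i3, drop = FALSE])
    o <- sigmoid(z[, i4, drop = FALSE])
    c_new <- f * c_state + i_g * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(f = f, i = i_g, g = g, o = o,
                         c_prev = c_state, c = c_new, tc = tc, h_prev = h)
    h <- h_new
    c_state <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# Backward through one LSTM layer. dhs: list of T upstream gradients on the
# hidden states (may contain NULLs meaning zero). Returns input gradients
# and parameter gradients.
lstm_layer_backward <- function(x, hs, cache, dhs, W, U) {
  Tn <- length(x)
  N <- nrow(x[[1]])
  H <- ncol(W) / 4L
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, nrow(U), ncol(U))
  db <- numeric(4 * H)
  dx <- vector("list", Tn)
  dh_next <- matrix(0, N, H)
  dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(Tn))) {
    ch <- cache[[t]]
    dh <- dh_next
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    do <- dh * ch$tc
    dc <- dc_next + dh * ch$o * (1 - ch$tc^2)
    df <- dc * ch$c_prev
    di <- dc * ch$g
    dg <- dc * ch$i
    dc_next <- dc * ch$f
    dz <- cbind(df * ch$f * (1 - ch$f),
                di * ch$i * (1 - ch$i),
                dg * (1 - ch$g^2),
                do * ch$o * (1 - ch$o))
    dW <- dW + crossprod(x[[t]], dz)
    dU <- dU + crossprod(ch$h_prev, dz)
    db <- db + colSums(dz)
    dx[[t]] <- dz %*% t(W)
    dh_next <- dz %*% t(U)
  }
  list(dx = dx, dW = dW, dU = dU, db = db)
}

# Full forward pass. X: array N x T x D. Returns class probabilities and,
# when training, all layer caches. Dropout masks (training only) are applied
# between LSTM layer 1 and layer 2, inverted-dropout scaled.
branch_forward <- function(params, X, training = FALSE, dropout_rate = 0,
                           keep_cache = FALSE) {
  N <- dim(X)[1]; Tn <- dim(X)[2]
  x_in <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], nrow = N))
  a0 <- lapply(x_in, function(m)
    m %*% params$W_in + matrix(params$b_in, N, length(params$b_in),
                               byrow = TRUE))
  l1 <- lstm_layer_forward(a0, params$W1, params$U1, params$b1, keep_cache)
  h1 <- l1$hs
  masks <- NULL
  if (training && dropout_rate > 0) {
    keep <- 1 - dropout_rate
    masks <- lapply(seq_len(Tn), function(t)
      matrix(stats::rbinom(N * ncol(h1[[t]]), 1, keep) / keep,
             N, ncol(h1[[t]])))
    h1 <- lapply(seq_len(Tn), function(t) h1[[t]] * masks[[t]])
  }
  l2 <- lstm_layer_forward(h1, params$W2, params$U2, params$b2, keep_cache)
  h_last <- l2$hs[[Tn]]
  logits <- h_last %*% params$W_out +
    matrix(params$b_out, N, length(params$b_out), byrow = TRUE)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits,
       cache = if (keep_cache) list(x_in = x_in, a0 = a0, l1 = l1, h1 = h1,
                                    masks = masks, l2 = l2,
                                    h_last = h_last) else NULL)
}

# Gradient of weighted cross-entropy w.r.t. all parameters for one batch.
# y: integer class indices; w: per-sample weights (mean ~ 1).
branch_backward <- function(params, fw, y, w) {
  N <- nrow(fw$probs)
  Tn <- length(fw$cache$x_in)
  onehot <- matrix(0, N, ncol(fw$probs))
  onehot[cbind(seq_len(N), y)] <- 1
  dlogits <- (fw$probs - onehot) * (w / N)
  ch <- fw$cache
  dW_out <- crossprod(ch$h_last, dlogits)
  db_out <- colSums(dlogits)
  dh2 <- vector("list", Tn)
  dh2[[Tn]] <- dlogits %*% t(params$W_out)
  b2g <- lstm_layer_backward(ch$h1, ch$l2$hs, ch$l2$cache, dh2,
                             params$W2, params$U2)
  dh1 <- b2g$dx
  if (!is.null(ch$masks))
    dh1 <- lapply(seq_len(Tn), function(t) dh1[[t]] * ch$masks[[t]])
  b1g <- lstm_layer_backward(ch$a0, ch$l1$hs, ch$l1$cache, dh1,
                             params$W1, params$U1)
  dW_in <- matrix(0, nrow(params$W_in), ncol(params$W_in))
  db_in <- numeric(length(params$b_in))
  for (t in seq_len(Tn)) {
    dW_in <- dW_in + crossprod(ch$x_in[[t]], b1g$dx[[t]])
    db_in <- db_in + colSums(b1g$dx[[t]])
  }
  list(W_in = dW_in, b_in = db_in,
       W1 = b1g$dW, U1 = b1g$dU, b1 = b1g$db,
       W2 = b2g$dW, U2 = b2g$dU, b2 = b2g$db,
       W_out = dW_out, b_out = db_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

weighted_ce <- function(probs, y, w) {
  -sum(w * log(pmax(probs[cbind(seq_along(y), y)], 1e-12))) / length(y)
}

#' Inverse-frequency class weights
#'
#' Loss weights proportional to the inverse of per-class counts, normalised
#' to mean 1, for class-imbalanced training.
#'
#' @param counts Named or ordered non-negative per-class counts.
#' @return Numeric weight vector of the same length.
#' @export
inverse_frequency_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts <= 0)) stop("every class needs at least one sample")
  w <- 1 / counts
  w / mean(w)
}

# Per-dimension standardisation of a window array, fitted on the training
# set and stored with the model. Geometric features in particular carry
# large constant offsets (limb lengths, resting orientations) that stall
# optimisation when fed raw.
fit_scaling <- function(X) {
  mu <- apply(X, 3, mean)
  sd_ <- apply(X, 3, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
  list(mu = mu, sd = sd_)
}

apply_scaling <- function(X, scaling) {
  for (d in seq_len(dim(X)[3]))
    X[, , d] <- (X[, , d] - scaling$mu[d]) / scaling$sd[d]
  X
}

stratified_split <- function(y, fraction, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train a branch network
#'
#' Adam optimisation of the weighted cross-entropy over minibatches, with
#' the learning rate halved every `lr_halving_period_epochs` epochs,
#' inverted dropout between the LSTM layers, and a stratified validation
#' split used to track per-epoch accuracy; the returned model carries the
#' parameters of the best-validation-accuracy epoch.
#'
#' @param X Array `n x 30 x input_dim` of feature windows.
#' @param labels Factor or character vector of window labels (length n).
#' @param config A [branch_config()].
#' @param classes Optional explicit class ordering; defaults to the sorted
#'   unique labels.
#' @return A trained `lstm_branch` with `history` (per-epoch train loss and
#'   validation accuracy) and `val_accuracy` (best, in percent).
#' @export
train_branch <- function(X, labels, config, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  if (anyNA(y)) stop("labels outside the class set")
  present <- sort(unique(y))
  if (length(present) < 2) stop("need at least 2 classes present")
  missing_cl <- setdiff(seq_along(classes), present)
  if (length(missing_cl) > 0 && length(classes) == config$num_classes &&
      is.null(config$class_weights))
    stop("class absent from training split: ",
         paste(classes[missing_cl], collapse = ", "))
  stopifnot(dim(X)[3] == config$input_dim, dim(X)[1] == length(y))

  val_idx <- stratified_split(y, config$validation_fraction, config$seed)
  tr_idx <- setdiff(seq_along(y), val_idx)
  scaling <- fit_scaling(X[tr_idx, , , drop = FALSE])
  X <- apply_scaling(X, scaling)
  cw <- config$class_weights
  if (is.null(cw)) {
    counts <- tabulate(y[tr_idx], nbins = length(classes))
    counts[counts == 0] <- 1
    cw <- inverse_frequency_weights(counts)
  }

  model <- build_branch(config)   # seeds the RNG for init + training
  params <- model$params
  state <- adam_init(params)
  Xv <- X[val_idx, , , drop = FALSE]
  yv <- y[val_idx]
  best <- list(acc = -Inf, params = params)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_accuracy = numeric(0))
  n_tr <- length(tr_idx)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate_init *
      0.5^((epoch - 1) %/% config$lr_halving_period_epochs)
    ord <- tr_idx[sample.int(n_tr)]
    losses <- numeric(0)
    for (start in seq(1, n_tr, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1, n_tr)]
      Xb <- X[bi, , , drop = FALSE]
      yb <- y[bi]
      fw <- branch_forward(params, Xb, training = TRUE,
                           dropout_rate = config$dropout_rate,
                           keep_cache = TRUE)
      wb <- cw[yb]
      losses <- c(losses, weighted_ce(fw$probs, yb, wb))
      grads <- branch_backward(params, fw, yb, wb)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
    pv <- branch_forward(params, Xv)$probs
    acc <- 100 * mean(max.col(pv, ties.method = "first") == yv)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = mean(losses),
                                         val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, params = params)
  }
  model$params <- best$params
  model$classes <- classes
  model$scaling <- scaling
  model$trained <- TRUE
  model$history <- history
  model$val_accuracy <- best$acc
  model
}

#' Branch class probabilities
#'
#' @param object A trained `lstm_branch`.
#' @param X Array `n x 30 x input_dim`.
#' @param ... Unused.
#' @return `n x num_classes` matrix of class probabilities (rows sum to 1).
#' @export
predict.lstm_branch <- function(object, X, ...) {
  if (length(dim(X)) == 2) X <- array(X, c(1, dim(X)))
  if (!is.null(object$scaling)) X <- apply_scaling(X, object$scaling)
  p <- branch_forward(object$params, X)$probs
  colnames(p) <- object$classes
  p
}

#' @export
print.lstm_branch <- function(x, ...) {
  cfg <- x$config
  cat("Stacked-LSTM branch (FC -> LSTM x2 -> FC)\n")
  cat(sprintf("  input %d -> hidden %d -> %d classes\n",
              cfg$input_dim, cfg$hidden_size, cfg$num_classes))
  if (x$trained)
    cat(sprintf("  trained %d epochs, best validation accuracy %.2f%%\n",
                nrow(x$history), x$val_accuracy))
  else cat("  untrained\n")
  invisible(x)
}
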