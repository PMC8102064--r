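#' Pointwise (MLP) network configuration
#'
#' The pointwise likelihood network maps (theta, rt, choice) to a scalar
#' log-likelihood: three tanh hidden layers of sizes 100/100/120 and a
#' linear output node, trained with Adam under the Huber loss.
#'
#' @param hidden hidden layer sizes (default c(100, 100, 120)).
#' @param learning_rate Adam step size (default 1e-3, halved on validation
#'   plateau).
#' @param batch_size minibatch size (default 1024).
#' @param epochs maximum epochs.
#' @param patience early stopping: training stops once the validation loss
#'   has failed to improve for more than `patience` epochs (default 5).
#' @param huber_literal use the discontinuous printed Huber branch
#'   0.5 + d for d > 1 instead of the continuous d - 0.5 (default FALSE).
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(hidden = c(100L, 100L, 120L), learning_rate = 1e-3,
                       batch_size = 1024L, epochs = 200L, patience = 5L,
                       huber_literal = FALSE) {
  stopifnot(length(hidden) >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 huber_literal = isTRUE(huber_literal)),
            class = "mlp_config")
}

#' Histogram (CNN) network configuration
#'
#' The histogram network maps theta to a normalized likelihood histogram
#' over the (choice x time-bin) grid: fully connected upsampling layers of
#' 64 and 256 units followed by one of `choices * bins` units, a reshape to
#' `choices` channels of length `bins`, three length-5 convolutions with
#' channel counts `conv_channels`, and a final fully connected softmax
#' layer. Trained with Adam under the KL divergence to the empirical
#' histogram labels.
#'
#' @param fc_sizes sizes of the first two upsampling layers (the third is
#'   fixed to choices*bins by the training set grid).
#' @param conv_channels output channels of the three convolution layers
#'   (default c(8, 8, 1)).
#' @param kernel convolution kernel length (default 5).
#' @param learning_rate,batch_size,epochs,patience as in [mlp_config()]
#'   (defaults 1e-3, 64, 100, 5).
#' @param label_floor floor applied to zero label cells inside the KL loss
#'   (default 1e-10).
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(fc_sizes = c(64L, 256L), conv_channels = c(8L, 8L, 1L),
                       kernel = 5L, learning_rate = 1e-3, batch_size = 64L,
                       epochs = 100L, patience = 5L, label_floor = 1e-10) {
  stopifnot(length(conv_channels) == 3, kernel %% 2 == 1)
  structure(list(fc_sizes = as.integer(fc_sizes),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 label_floor = label_floor),
            class = "cnn_config")
}

#' Huber loss
#'
#' Elementwise robust regression loss on the residual d = |y - yhat|:
#' 0.5 d^2 for d <= 1 and, by default, the continuous extension d - 0.5 for
#' d > 1. `literal = TRUE` selects the 0.5 + d variant for the outer branch
#' instead; both share the same gradient.
#'
#' @param y,yhat targets and predictions (recycled).
#' @param literal use the 0.5 + d outer branch.
#' @return vector of nonnegative losses.
#' @export
huber_loss <- function(y, yhat, literal = FALSE) {
  d <- abs(y - yhat)
  ifelse(d <= 1, 0.5 * d^2, if (literal) 0.5 + d else d - 0.5)
}

#' Kullback-Leibler divergence between two likelihood histograms
#'
#' D(pred || label) = sum pred * log(pred / label), with zero label cells
#' floored at `eps`. Predictions must be strictly positive (softmax
#' output).
#'
#' @param pred,label nonnegative arrays of identical shape.
#' @param eps label floor (default 1e-10).
#' @return scalar divergence, >= 0 when both arguments are distributions.
#' @export
kl_divergence <- function(pred, label, eps = 1e-10) {
  if (!identical(dim(pred), dim(label)) || length(pred) != length(label))
    stop("pred and label must have identical shapes")
  if (any(pred <= 0)) stop("pred must be strictly positive")
  sum(pred * (log(pred) - log(pmax(label, eps))))
}

## ---- generic dense-layer machinery -------------------------------------

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- MLP ----------------------------------------------------------------

.mlp_init <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("W", l)]] <- .glorot(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  params
}

# forward pass; X already standardized. Returns yhat and (optionally) the
# per-layer activations needed for backprop.
.mlp_forward <- function(params, X, keep = FALSE) {
  L <- length(params) / 2
  h <- X
  acts <- if (keep) vector("list", L - 1) else NULL
  for (l in seq_len(L - 1)) {
    h <- tanh(sweep(h %*% params[[paste0("W", l)]], 2,
                    params[[paste0("b", l)]], `+`))
    if (keep) acts[[l]] <- h
  }
  yhat <- drop(sweep(h %*% params[[paste0("W", L)]], 2,
                     params[[paste0("b", L)]], `+`))
  if (keep) list(yhat = yhat, acts = acts) else yhat
}

.mlp_backward <- function(params, X, fw, dy) {
  L <- length(params) / 2
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  delta <- matrix(dy, ncol = 1)
  for (l in seq(L, 1)) {
    h_prev <- if (l == 1) X else fw$acts[[l - 1]]
    grads[[paste0("W", l)]] <- crossprod(h_prev, delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) *
        (1 - fw$acts[[l - 1]]^2)
    }
  }
  grads
}

## ---- training -----------------------------------------------------------

#' Train a likelihood approximation network
#'
#' Fits the pointwise MLP (Huber loss) or the histogram CNN (KL loss) on a
#' training corpus with Adam, minibatches, a 98/2 train/validation split by
#' parameter vector, learning-rate halving on validation plateau, and early
#' stopping once validation loss has failed to improve for more than
#' `patience` epochs. Aborts with a diagnostic if the loss diverges.
#'
#' @param training_set an `mlp_training_set` or `cnn_training_set`.
#' @param config an [mlp_config()] or [cnn_config()] matched to the set.
#' @param seed integer seed (weights init and batch shuffling).
#' @param verbose print per-epoch losses.
#' @return a `trained_lan` object with fields `kind` ("pointwise" or
#'   "histogram"), weights, input normalization, model metadata and
#'   `history` (train/validation loss per epoch).
#' @export
train_network <- function(training_set, config = NULL, seed = 1L,
                          verbose = FALSE) {
  if (inherits(training_set, "mlp_training_set")) {
    if (is.null(config)) config <- mlp_config()
    stopifnot(inherits(config, "mlp_config"))
    .train_mlp(training_set, config, seed, verbose)
  } else if (inherits(training_set, "cnn_training_set")) {
    if (is.null(config)) config <- cnn_config()
    stopifnot(inherits(config, "cnn_config"))
    .train_cnn(training_set, config, seed, verbose)
  } else stop("unknown training set class")
}

# split indices 98/2 by parameter vector so validation probes interpolation
# across parameters rather than across datapoints of a seen parameter
.val_split <- function(n, theta_id) {
  if (is.null(theta_id)) theta_id <- seq_len(n)
  ids <- unique(theta_id)
  nv <- max(1L, round(0.02 * length(ids)))
  val_ids <- sample(ids, nv)
  which(theta_id %in% val_ids)
}

.train_loop <- function(n_train, config, epoch_fn, val_fn, verbose) {
  lr <- config$learning_rate
  best <- Inf; best_params <- NULL; stale <- 0L; cooldown <- 0L
  hist_tr <- numeric(0); hist_va <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    tr_loss <- epoch_fn(lr)
    va_loss <- val_fn()
    if (!is.finite(tr_loss) || !is.finite(va_loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    hist_tr <- c(hist_tr, tr_loss); hist_va <- c(hist_va, va_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                      ep, tr_loss, va_loss, lr))
    if (cooldown > 0L) cooldown <- cooldown - 1L
    cur <- function() lapply(environment(epoch_fn)$params, identity)
    if (va_loss < best * (1 - 1e-4)) {
      best <- va_loss; stale <- 0L; best_params <- cur()
    } else {
      if (va_loss < best) { # tiny improvement: keep weights, count as stale
        best <- va_loss; best_params <- cur()
      }
      stale <- stale + 1L
      if (stale >= 3L && cooldown == 0L && lr > config$learning_rate / 64) {
        lr <- lr / 2 # halve on plateau, with a cooldown before the next cut
        cooldown <- 3L
      }
      if (stale > config$patience) break
    }
  }
  list(params = if (is.null(best_params)) environment(epoch_fn)$params
                else best_params,
       history = data.frame(epoch = seq_along(hist_tr), train = hist_tr,
                            validation = hist_va),
       epochs_run = length(hist_tr))
}

.train_mlp <- function(ts, config, seed, verbose) {
  set.seed(seed)
  X <- as.matrix(ts$features)
  y <- as.numeric(ts$labels)
  mu <- colMeans(X)
  sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  vi <- .val_split(nrow(Xs), ts$theta_id)
  Xv <- Xs[vi, , drop = FALSE]; yv <- y[vi]
  Xt <- Xs[-vi, , drop = FALSE]; yt <- y[-vi]
  params <- .mlp_init(ncol(Xs), config$hidden)
  # start the linear output at the label mean so early epochs need not close
  # a ~60 log-unit offset through the hidden layers
  params[[paste0("b", length(params) / 2)]] <- mean(yt)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  step <- integer(1)
  bs <- config$batch_size
  nt <- nrow(Xt)
  L <- length(params) / 2
  wi <- paste0("W", seq_len(L)); bi <- paste0("b", seq_len(L))

  # the epoch itself runs in compiled code; `params`, the Adam moments and
  # the step counter are updated in place
  epoch_fn <- function(lr) {
    ord <- sample.int(nt)
    mlp_adam_epoch_cpp(params, adam_m, adam_v, step, Xt, yt, ord, bs, lr,
                       config$huber_literal)
  }
  val_fn <- function()
    mean(huber_loss(yv, drop(mlp_forward_cpp(params[wi], params[bi], Xv)),
                    config$huber_literal))

  res <- .train_loop(nt, config, epoch_fn, val_fn, verbose)
  res$params[bi] <- lapply(res$params[bi], as.numeric) # biases as vectors
  structure(list(kind = "pointwise", params = res$params,
                 norm = list(mu = mu, sd = sdev),
                 model = ts$model, feature_names = colnames(ts$features),
                 config = config, history = res$history,
                 epochs_run = res$epochs_run,
                 labels_source = ts$labels_source),
            class = "trained_lan")
}

## ---- CNN ----------------------------------------------------------------

.cnn_init <- function(d_in, fc_sizes, n_out, conv_channels, kernel,
                      n_choices, n_bins) {
  sizes <- c(d_in, fc_sizes, n_out)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("W", l)]] <- .glorot(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  chans <- c(n_choices, conv_channels)
  for (j in 1:3) {
    fan_in <- chans[j] * kernel; fan_out <- chans[j + 1] * kernel
    lim <- sqrt(6 / (fan_in + fan_out))
    params[[paste0("K", j)]] <-
      array(stats::runif(chans[j] * kernel * chans[j + 1], -lim, lim),
            dim = c(chans[j], kernel, chans[j + 1]))
    params[[paste0("c", j)]] <- numeric(chans[j + 1])
  }
  params[["Wout"]] <- .glorot(n_bins * chans[4], n_out)
  params[["bout"]] <- numeric(n_out)
  params
}

# same-padded 1-D convolution: X (batch, L, C_in) -> (batch, L, C_out)
.conv1d <- function(X, K, bias) {
  dims <- dim(X); B <- dims[1]; L <- dims[2]; Cin <- dims[3]
  kk <- dim(K)[2]; Cout <- dim(K)[3]
  pad <- (kk - 1) / 2
  Xp <- array(0, dim = c(B, L + 2 * pad, Cin))
  Xp[, pad + seq_len(L), ] <- X
  Y <- matrix(rep(bias, each = B * L), B * L, Cout)
  for (k in seq_len(kk)) {
    S <- matrix(Xp[, k + seq_len(L) - 1, , drop = FALSE], B * L, Cin)
    Y <- Y + S %*% matrix(K[, k, ], Cin, Cout)
  }
  array(Y, dim = c(B, L, Cout))
}

# gradient of .conv1d wrt input, kernel and bias given upstream dY
.conv1d_grad <- function(X, K, dY) {
  dims <- dim(X); B <- dims[1]; L <- dims[2]; Cin <- dims[3]
  kk <- dim(K)[2]; Cout <- dim(K)[3]
  pad <- (kk - 1) / 2
  Xp <- array(0, dim = c(B, L + 2 * pad, Cin))
  Xp[, pad + seq_len(L), ] <- X
  dYm <- matrix(dY, B * L, Cout)
  dK <- array(0, dim = dim(K))
  dXp <- array(0, dim = dim(Xp))
  for (k in seq_len(kk)) {
    cols <- k + seq_len(L) - 1
    S <- matrix(Xp[, cols, , drop = FALSE], B * L, Cin)
    dK[, k, ] <- crossprod(S, dYm)
    dS <- dYm %*% t(matrix(K[, k, ], Cin, Cout))
    dXp[, cols, ] <- dXp[, cols, ] + array(dS, dim = c(B, L, Cin))
  }
  list(dX = dXp[, pad + seq_len(L), , drop = FALSE], dK = dK,
       dc = colSums(dYm))
}

.log_softmax <- function(Z) {
  m <- apply(Z, 1, max)
  Zs <- Z - m
  Zs - log(rowSums(exp(Zs)))
}

# full forward pass of the histogram network; returns log-probabilities and,
# if keep, every intermediate needed for backprop
.cnn_forward <- function(params, net, X, keep = FALSE) {
  B <- nrow(X)
  h1 <- tanh(sweep(X %*% params$W1, 2, params$b1, `+`))
  h2 <- tanh(sweep(h1 %*% params$W2, 2, params$b2, `+`))
  h3 <- tanh(sweep(h2 %*% params$W3, 2, params$b3, `+`))
  A0 <- array(h3, dim = c(B, net$n_bins, net$n_choices))
  C1 <- tanh(.conv1d(A0, params$K1, params$c1))
  C2 <- tanh(.conv1d(C1, params$K2, params$c2))
  C3 <- tanh(.conv1d(C2, params$K3, params$c3))
  H <- matrix(C3, B, net$n_bins * dim(params$K3)[3])
  Z <- sweep(H %*% params$Wout, 2, params$bout, `+`)
  logp <- .log_softmax(Z)
  if (!keep) return(logp)
  list(logp = logp, h1 = h1, h2 = h2, h3 = h3, A0 = A0, C1 = C1, C2 = C2,
       C3 = C3, H = H)
}

.train_cnn <- function(ts, config, seed, verbose) {
  set.seed(seed)
  X <- as.matrix(ts$features)
  Yl <- log(pmax(ts$labels, config$label_floor)) # floored label log-mass
  mu <- colMeans(X)
  sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  net <- list(n_bins = ts$n_bins, n_choices = length(ts$choices))
  n_out <- net$n_bins * net$n_choices
  stopifnot(ncol(Yl) == n_out)
  vi <- .val_split(nrow(Xs), seq_len(nrow(Xs)))
  Xv <- Xs[vi, , drop = FALSE]; Yv <- Yl[vi, , drop = FALSE]
  Xt <- Xs[-vi, , drop = FALSE]; Yt <- Yl[-vi, , drop = FALSE]
  params <- .cnn_init(ncol(Xs), config$fc_sizes, n_out,
                      config$conv_channels, config$kernel,
                      net$n_choices, net$n_bins)
  adam <- .adam_new(params)
  bs <- config$batch_size
  nt <- nrow(Xt)

  kl_rows <- function(logp, Ylog) { # mean KL(pred || label) over rows
    p <- exp(logp)
    mean(rowSums(p * (logp - Ylog)))
  }

  epoch_fn <- function(lr) {
    ord <- sample.int(nt)
    tot <- 0
    for (start in seq(1, nt, by = bs)) {
      idx <- ord[start:min(start + bs - 1, nt)]
      Xb <- Xt[idx, , drop = FALSE]; Yb <- Yt[idx, , drop = FALSE]
      B <- nrow(Xb)
      fw <- .cnn_forward(params, net, Xb, keep = TRUE)
      p <- exp(fw$logp)
      s <- fw$logp - Yb
      tot <- tot + sum(p * s)
      # d KL / d logits for softmax output
      dZ <- p * (s - rowSums(p * s)) / B
      g <- list()
      dH <- dZ %*% t(params$Wout)
      g$Wout <- crossprod(fw$H, dZ); g$bout <- colSums(dZ)
      dC3 <- array(dH, dim = dim(fw$C3)) * (1 - fw$C3^2)
      cg3 <- .conv1d_grad(fw$C2, params$K3, dC3)
      g$K3 <- cg3$dK; g$c3 <- cg3$dc
      dC2 <- cg3$dX * (1 - fw$C2^2)
      cg2 <- .conv1d_grad(fw$C1, params$K2, dC2)
      g$K2 <- cg2$dK; g$c2 <- cg2$dc
      dC1 <- cg2$dX * (1 - fw$C1^2)
      cg1 <- .conv1d_grad(fw$A0, params$K1, dC1)
      g$K1 <- cg1$dK; g$c1 <- cg1$dc
      dh3 <- matrix(cg1$dX, B, net$n_bins * net$n_choices) * (1 - fw$h3^2)
      g$W3 <- crossprod(fw$h2, dh3); g$b3 <- colSums(dh3)
      dh2 <- (dh3 %*% t(params$W3)) * (1 - fw$h2^2)
      g$W2 <- crossprod(fw$h1, dh2); g$b2 <- colSums(dh2)
      dh1 <- (dh2 %*% t(params$W2)) * (1 - fw$h1^2)
      g$W1 <- crossprod(Xb, dh1); g$b1 <- colSums(dh1)
      g <- g[names(params)]
      st <- .adam_step(params, g, adam, lr)
      params <<- st$params; adam <<- st$state
    }
    tot / nt
  }
  val_fn <- function() kl_rows(.cnn_forward(params, net, Xv), Yv)

  res <- .train_loop(nt, config, epoch_fn, val_fn, verbose)
  structure(list(kind = "histogram", params = res$params, net = net,
                 norm = list(mu = mu, sd = sdev),
                 model = ts$model, feature_names = colnames(ts$features),
                 choices = ts$choices, n_bins = ts$n_bins, t_max = ts$t_max,
                 config = config, history = res$history,
                 epochs_run = res$epochs_run),
            class = "trained_lan")
}
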