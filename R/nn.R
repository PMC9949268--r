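# Fully connected network internals: initialization, forward pass, binary
# cross-entropy, backpropagation, Adam, and the early-stopping training loop.
# Everything is plain (BLAS-backed) matrix algebra; gradient correctness is
# pinned by a finite-difference test.

#' Network architecture configuration
#'
#' The default is a 14-layer fully connected network: the input layer (width
#' `input_width`), 12 hidden rectified-linear layers, and a single logistic
#' output unit. Widths, activation and dropout are configuration; the layer
#' count follows from `hidden_widths`.
#'
#' @param input_width number of input features (default 33).
#' @param hidden_widths integer vector of hidden-layer widths (default 12
#'   layers, 256 down to 8).
#' @param activation `"relu"` or `"tanh"` (default `"relu"`).
#' @param dropout_rate dropout probability in `[0, 1)`, applied to hidden
#'   activations during training only (default 0.1).
#' @return object of class `nn_config`.
#' @export
nn_config <- function(input_width = 33,
                      hidden_widths = c(256, 256, 128, 128, 128, 64, 64, 64,
                                        32, 32, 16, 8),
                      activation = c("relu", "tanh"),
                      dropout_rate = 0.1) {
  activation <- match.arg(activation)
  stopifnot(input_width >= 1, all(hidden_widths >= 1),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 activation = activation,
                 dropout_rate = dropout_rate),
            class = "nn_config")
}

#' Training hyperparameters
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 512).
#' @param max_epochs maximum training epochs (default 200).
#' @param patience early-stopping patience in epochs without validation-loss
#'   improvement (default 20).
#' @param seed integer seed governing initialization, shuffling, dropout and
#'   the validation split.
#' @param split_fraction validation fraction for early stopping (default 0.1).
#' @return object of class `nn_hyper`.
#' @export
nn_hyper <- function(learning_rate = 1e-3, batch_size = 512, max_epochs = 200,
                     patience = 20, seed = 1L, split_fraction = 0.1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed), split_fraction = split_fraction),
            class = "nn_hyper")
}

#' Initialize network weights
#'
#' Variance-scaled uniform initialization matched to the activation, with
#' zero biases; deterministic given `seed`. Rectifier networks use the He
#' scaling `U(+/- sqrt(6/fan_in))`, which preserves activation variance
#' through deep ReLU stacks; `tanh` networks use the Glorot scaling
#' `U(+/- sqrt(6/(fan_in+fan_out)))`.
#'
#' @param config an [nn_config()].
#' @param seed integer seed.
#' @return list with elements `config`, `W` (list of weight matrices, one per
#'   non-input layer: 12 hidden + 1 output) and `b` (bias vectors).
#' @export
nn_init <- function(config, seed = 1L) {
  widths <- c(config$input_width, config$hidden_widths, 1L)
  n_mat <- length(widths) - 1L
  W <- vector("list", n_mat); b <- vector("list", n_mat)
  withr::with_seed(seed, {
    for (l in seq_len(n_mat)) {
      fan_in <- widths[l]; fan_out <- widths[l + 1L]
      lim <- if (config$activation == "relu") sqrt(6 / fan_in)
             else sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[l]] <- numeric(fan_out)
    }
  })
  list(config = config, W = W, b = b)
}

act_fun <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), tanh = tanh(z))
}
act_grad <- function(a, z, activation) {
  switch(activation, relu = (z > 0) * 1, tanh = 1 - a * a)
}

#' Forward pass
#'
#' Computes per-row probabilities `sigmoid(f(X))`. In inference mode
#' (`train = FALSE`, the default) dropout is off and the pass is
#' deterministic; in training mode inverted dropout is applied to hidden
#' activations.
#'
#' @param net network from [nn_init()].
#' @param X numeric matrix (rows = observations), already standardized.
#' @param train logical; apply dropout and keep caches for backprop.
#' @return in inference mode, a numeric probability vector in (0, 1); in
#'   training mode a list with `p` and the layer caches.
#' @export
nn_forward <- function(net, X, train = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$config$input_width)
    stop("input width ", ncol(X), " does not match network input width ",
         net$config$input_width)
  if (any(!is.finite(X)))
    stop("non-finite feature values in row(s) ",
         paste(head(which(rowSums(!is.finite(X)) > 0), 5), collapse = ", "))
  L <- length(net$W)
  a <- X
  caches <- if (train) vector("list", L) else NULL
  p_drop <- if (train) net$config$dropout_rate else 0
  for (l in seq_len(L - 1L)) {
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    h <- act_fun(z, net$config$activation)
    mask <- NULL
    if (p_drop > 0) {
      mask <- matrix(rbinom(length(h), 1, 1 - p_drop), nrow(h), ncol(h)) / (1 - p_drop)
      h <- h * mask
    }
    if (train) caches[[l]] <- list(a_in = a, z = z, h = h, mask = mask)
    a <- h
  }
  z_out <- drop(a %*% net$W[[L]] + net$b[[L]])
  p <- plogis(z_out)
  # keep probabilities in the open interval
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  if (!train) return(unname(p))
  list(p = unname(p), a_last = a, caches = caches)
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y*log(p) + (1-y)*log(1-p))`, with `p` clipped to
#' `[eps, 1-eps]` to avoid `log(0)`.
#'
#' @param p probability vector.
#' @param y binary labels of the same length.
#' @param eps clipping constant (default 1e-12).
#' @return non-negative scalar.
#' @export
bce_loss <- function(p, y, eps = 1e-12) {
  if (length(p) != length(y)) stop("length mismatch between p and y")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradients of mean BCE w.r.t. all weights/biases, given a training-mode
# forward pass; dL/dz_out = (p - y)/n for the logistic output + BCE.
nn_backward <- function(net, fwd, X, y) {
  L <- length(net$W)
  n <- length(y)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- matrix((fwd$p - y) / n, ncol = 1)
  dW[[L]] <- crossprod(fwd$a_last, delta)
  db[[L]] <- colSums(delta)
  for (l in rev(seq_len(L - 1L))) {
    delta <- delta %*% t(net$W[[l + 1L]])
    cache <- fwd$caches[[l]]
    if (!is.null(cache$mask)) delta <- delta * cache$mask
    delta <- delta * act_grad(cache$h, cache$z, net$config$activation)
    dW[[l]] <- crossprod(cache$a_in, delta)
    db[[l]] <- colSums(delta)
  }
  list(dW = dW, db = db)
}

#' Train the network with Adam and early stopping
#'
#' Mini-batch gradient descent with the Adam adaptive-moment optimizer on the
#' binary cross-entropy. A label-stratified validation split monitors
#' generalization; training stops when the validation loss has not improved
#' for `patience` epochs and the best-validation weights are returned.
#' Fully reproducible given `hyper$seed`.
#'
#' @param net network from [nn_init()].
#' @param X standardized feature matrix.
#' @param y binary label vector.
#' @param hyper an [nn_hyper()].
#' @return the trained network, with element `history` (a `data.frame` of
#'   per-epoch training and validation loss) and `epochs_run`.
#' @export
nn_train <- function(net, X, y, hyper = nn_hyper()) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("both classes required for training")
  val <- stratified_split(y, hyper$split_fraction, seed = hyper$seed + 1L)
  Xtr <- X[!val, , drop = FALSE]; ytr <- y[!val]
  Xva <- X[val, , drop = FALSE]; yva <- y[val]

  L <- length(net$W)
  m_W <- lapply(net$W, function(w) w * 0); v_W <- m_W
  m_b <- lapply(net$b, function(b) b * 0); v_b <- m_b
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L
  best <- list(loss = Inf, W = net$W, b = net$b, epoch = 0L)
  hist_tr <- numeric(0); hist_va <- numeric(0)
  wait <- 0L

  withr::with_seed(hyper$seed, {
    for (epoch in seq_len(hyper$max_epochs)) {
      ord <- sample(nrow(Xtr))
      nb <- ceiling(length(ord) / hyper$batch_size)
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * hyper$batch_size + 1L):min(bi * hyper$batch_size, length(ord))]
        fwd <- nn_forward(net, Xtr[rows, , drop = FALSE], train = TRUE)
        gr <- nn_backward(net, fwd, Xtr[rows, , drop = FALSE], ytr[rows])
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in seq_len(L)) {
          m_W[[l]] <- beta1 * m_W[[l]] + (1 - beta1) * gr$dW[[l]]
          v_W[[l]] <- beta2 * v_W[[l]] + (1 - beta2) * gr$dW[[l]]^2
          net$W[[l]] <- net$W[[l]] - hyper$learning_rate *
            (m_W[[l]] / corr1) / (sqrt(v_W[[l]] / corr2) + adam_eps)
          m_b[[l]] <- beta1 * m_b[[l]] + (1 - beta1) * gr$db[[l]]
          v_b[[l]] <- beta2 * v_b[[l]] + (1 - beta2) * gr$db[[l]]^2
          net$b[[l]] <- net$b[[l]] - hyper$learning_rate *
            (m_b[[l]] / corr1) / (sqrt(v_b[[l]] / corr2) + adam_eps)
        }
      }
      tr_loss <- bce_loss(nn_forward(net, Xtr), ytr)
      va_loss <- bce_loss(nn_forward(net, Xva), yva)
      if (!is.finite(tr_loss) || !is.finite(va_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      hist_tr <- c(hist_tr, tr_loss); hist_va <- c(hist_va, va_loss)
      if (va_loss < best$loss - 1e-9) {
        best <- list(loss = va_loss, W = net$W, b = net$b, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hyper$patience) break
      }
    }
  })
  net$W <- best$W; net$b <- best$b
  net$history <- data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_va)
  net$epochs_run <- length(hist_tr)
  net$best_epoch <- best$epoch
  net$best_val_loss <- best$loss
  net
}
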