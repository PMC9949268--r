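# The user-facing model object: fit, predict, transfer, checkpoint, methods.

#' Fit the GWAS-enhancement neural network
#'
#' Trains the 14-layer fully connected network on a per-variant feature
#' matrix (typically from [assemble_features()]) against binary labels from a
#' larger study of the same trait. Features are standardized internally
#' (mean/sd fit on the training rows only) and the scaler is stored in the
#' model, so `predict()` takes raw features.
#'
#' @param x numeric feature matrix, rows = variants, columns = named features.
#' @param y binary label vector (1 = associated in the label study).
#' @param config an [nn_config()]; the input width defaults to `ncol(x)`.
#' @param hyper an [nn_hyper()].
#' @param standardize logical; z-score features on the training rows
#'   (default `TRUE`).
#' @return an object of class `gwasdnn` with components `network`, `scaler`,
#'   `schema` (feature names), `history`, `hyper` and `call`. Methods:
#'   [predict.gwasdnn()], `print`, `summary`, `plot` (loss curves), `fitted`,
#'   `residuals`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- rbinom(200, 1, plogis(2 * x[, 1]))
#' fit <- gwasdnn(x, y, config = nn_config(3, c(8, 4), dropout_rate = 0),
#'                hyper = nn_hyper(max_epochs = 20, batch_size = 64))
#' summary(fit)
#' @export
gwasdnn <- function(x, y, config = NULL, hyper = nn_hyper(), standardize = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(config)) config <- nn_config(input_width = ncol(x))
  if (config$input_width != ncol(x))
    stop("config input_width (", config$input_width,
         ") does not match feature count (", ncol(x), ")")
  y <- as.integer(y)
  scaler <- NULL
  if (standardize) {
    std <- suppressMessages(standardize(x))
    x <- std$train
    scaler <- std$scaler
  }
  net <- nn_init(config, seed = hyper$seed)
  net <- nn_train(net, x, y, hyper)
  structure(list(network = net, scaler = scaler, schema = colnames(x),
                 history = net$history, hyper = hyper,
                 n_train = length(y), n_pos = sum(y),
                 fitted_values = nn_forward(net, x), y = y,
                 call = match.call()),
            class = "gwasdnn")
}

scale_for_model <- function(object, newdata) {
  if (!is.matrix(newdata)) stop("newdata must be a matrix")
  if (!is.null(colnames(newdata))) {
    diff <- setdiff(object$schema, colnames(newdata))
    extra <- setdiff(colnames(newdata), object$schema)
    if (length(diff) || length(extra))
      stop("feature schema mismatch; missing: [",
           paste(diff, collapse = ", "), "], unexpected: [",
           paste(extra, collapse = ", "), "]")
    newdata <- newdata[, object$schema, drop = FALSE]
  } else if (ncol(newdata) != length(object$schema)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$schema))
  }
  if (!is.null(object$scaler)) newdata <- apply_scaler(newdata, object$scaler)
  newdata
}

#' Predict per-variant association probabilities
#'
#' Applies the stored standardization and a deterministic forward pass
#' (dropout off). Probabilities lie strictly inside (0, 1).
#'
#' @param object a fitted [gwasdnn()] model.
#' @param newdata raw (unstandardized) feature matrix with the model's schema.
#' @param ... unused.
#' @return numeric probability vector, named by `rownames(newdata)`.
#' @export
predict.gwasdnn <- function(object, newdata, ...) {
  X <- scale_for_model(object, newdata)
  p <- nn_forward(object$network, X)
  names(p) <- rownames(newdata)
  p
}

#' Apply a trained model to another trait with frozen weights
#'
#' Transfer application: the model's parameters are not updated; the new
#' trait's feature matrix must use the identical feature schema and is
#' standardized with the parameters stored at training time.
#'
#' @param object a fitted [gwasdnn()] model.
#' @param x_new raw feature matrix for the target trait.
#' @return probability vector, as [predict.gwasdnn()].
#' @export
transfer_apply <- function(object, x_new) {
  before <- serialize(list(object$network$W, object$network$b), NULL)
  p <- predict(object, x_new)
  after <- serialize(list(object$network$W, object$network$b), NULL)
  stopifnot(identical(before, after))   # frozen-weight contract
  p
}

#' @export
print.gwasdnn <- function(x, ...) {
  widths <- c(x$network$config$input_width, x$network$config$hidden_widths, 1L)
  cat("GWAS-enhancement neural network (", length(widths), "-layer fully connected)\n",
      sep = "")
  cat("  architecture:", paste(widths, collapse = "-"), "\n")
  cat("  trained on", x$n_train, "variants (", x$n_pos, "positive );",
      x$network$epochs_run, "epochs, best validation loss",
      format(x$network$best_val_loss, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.gwasdnn <- function(object, ...) {
  n_par <- sum(vapply(object$network$W, length, numeric(1))) +
    sum(vapply(object$network$b, length, numeric(1)))
  out <- list(layers = length(object$network$W) + 1L,
              widths = c(object$network$config$input_width,
                         object$network$config$hidden_widths, 1L),
              n_parameters = n_par,
              activation = object$network$config$activation,
              dropout_rate = object$network$config$dropout_rate,
              n_train = object$n_train, n_pos = object$n_pos,
              epochs_run = object$network$epochs_run,
              best_epoch = object$network$best_epoch,
              best_val_loss = object$network$best_val_loss)
  class(out) <- "summary.gwasdnn"
  out
}

#' @export
print.summary.gwasdnn <- function(x, ...) {
  cat("Fully connected network:", paste(x$widths, collapse = "-"),
      "(", x$layers, "layers,", x$n_parameters, "parameters )\n")
  cat("Activation:", x$activation, " dropout:", x$dropout_rate, "\n")
  cat("Training: n =", x$n_train, "(", x$n_pos, "positives );",
      x$epochs_run, "epochs run, best epoch", x$best_epoch,
      "validation BCE", format(x$best_val_loss, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.gwasdnn <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "binary cross-entropy",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::abline(v = x$network$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing file containing the network
#' configuration, weights, standardization parameters and training metadata;
#' `load_gwasdnn(save_gwasdnn(m, f))` reproduces predictions bit-identically.
#'
#' @param object a fitted [gwasdnn()] model.
#' @param path checkpoint path.
#' @return `save_gwasdnn`: `path` invisibly; `load_gwasdnn`: the model.
#' @export
save_gwasdnn <- function(object, path) {
  stopifnot(inherits(object, "gwasdnn"))
  payload <- list(format = "gwasdnn-checkpoint", version = 1L, model = object)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_gwasdnn
#' @export
load_gwasdnn <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint ", path, ": ", conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "gwasdnn-checkpoint"))
    stop("not a model checkpoint: ", path)
  if (!identical(payload$version, 1L))
    stop("unsupported checkpoint version: ", payload$version)
  payload$model
}

#' @export
fitted.gwasdnn <- function(object, ...) object$fitted_values

#' @export
residuals.gwasdnn <- function(object, ...) object$y - object$fitted_values
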