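# Labeled, class-rebalanced, standardized training data.
#
# Labels come from a larger "teacher" study of the same trait: Y = 1 iff that
# study's p-value is strictly below genome-wide significance (5e-8). GWAS
# tables are extremely imbalanced, so non-significant variants are
# under-sampled to a fixed negative:positive ratio before training.

#' Binary labels from a label study
#'
#' @param label_stats summary statistics of the (larger) label study,
#'   harmonized to the feature study's variant set.
#' @param alpha significance threshold, strict (default `5e-8`).
#' @return named integer vector (1 = `p < alpha`), names = variant ids.
#' @export
label_variants <- function(label_stats, alpha = GWS_ALPHA) {
  setNames(as.integer(label_stats$p_value < alpha), label_stats$variant_id)
}

#' Bundle features, labels and input-study significance
#'
#' @param X feature matrix from [assemble_features()].
#' @param y binary labels aligned to the rows of `X` (variants without a
#'   label-study record must be dropped before this call).
#' @param input_significant logical vector: significant in the *input* study.
#' @return object of class `labeled_set`.
#' @export
labeled_set <- function(X, y, input_significant = rep(FALSE, nrow(X))) {
  stopifnot(nrow(X) == length(y), all(y %in% 0:1),
            length(input_significant) == nrow(X))
  structure(list(X = X, y = as.integer(y),
                 input_significant = as.logical(input_significant),
                 scaler = NULL),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat("labeled set:", nrow(x$X), "variants x", ncol(x$X), "features;",
      sum(x$y), "positive label(s)",
      if (!is.null(x$scaler)) "(standardized)" else "", "\n")
  invisible(x)
}

#' Under-sample non-significant variants
#'
#' Keeps every positive-label variant and a uniform random subset of
#' negatives of size `ceiling(ratio * n_positives)` (all of them when fewer
#' exist), without replacement. Deterministic given `seed`.
#'
#' @param set a [labeled_set()].
#' @param ratio negatives retained per positive (default 10).
#' @param seed integer seed.
#' @return the subset `labeled_set`, with attribute `mask` (the retained row
#'   indices, in original order).
#' @export
undersample <- function(set, ratio = 10, seed = 1L) {
  pos <- which(set$y == 1L)
  neg <- which(set$y == 0L)
  if (length(pos) == 0L) stop("undersample: no positive labels; model untrainable")
  n_neg <- min(length(neg), ceiling(ratio * length(pos)))
  keep_neg <- if (n_neg == length(neg)) neg else
    withr::with_seed(seed, sample(neg, n_neg))
  mask <- sort(c(pos, keep_neg))
  out <- labeled_set(set$X[mask, , drop = FALSE], set$y[mask],
                     set$input_significant[mask])
  attr(out, "mask") <- mask
  out
}

#' Fit and apply feature standardization
#'
#' Per-feature z-scoring with mean and standard deviation fit on the training
#' set only; the same transform is applied unchanged to any other matrix, so
#' no test-set statistics leak into the model. Constant columns are passed
#' through unchanged and flagged.
#'
#' @param train a [labeled_set()] (or plain matrix) to fit on.
#' @param others optional list of feature matrices to transform with the
#'   training parameters.
#' @return list with `train` (standardized `labeled_set`/matrix), `others`
#'   (transformed list) and `scaler` (list of `center`, `scale`,
#'   `constant` flags).
#' @export
standardize <- function(train, others = list()) {
  X <- if (inherits(train, "labeled_set")) train$X else train
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  const <- !is.finite(scl) | scl <= 0
  ctr[const] <- 0
  scl[const] <- 1
  scaler <- list(center = ctr, scale = scl, constant = const)
  if (any(const))
    message(sum(const), " constant feature column(s) passed through unscaled: ",
            paste(names(ctr)[const], collapse = ", "))
  tX <- apply_scaler(X, scaler)
  if (inherits(train, "labeled_set")) {
    train$X <- tX
    train$scaler <- scaler
  } else train <- tX
  list(train = train,
       others = lapply(others, apply_scaler, scaler = scaler),
       scaler = scaler)
}

#' @rdname standardize
#' @param X feature matrix to transform.
#' @param scaler scaler list from [standardize()].
#' @export
apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @rdname standardize
#' @export
invert_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$scale, "*"), 2, scaler$center, "+")
}

#' Stratified train/validation split
#'
#' Random split stratified by label, used for early stopping.
#'
#' @param y binary labels.
#' @param fraction validation fraction (default 0.1).
#' @param seed integer seed.
#' @return logical vector, `TRUE` for validation rows.
#' @export
stratified_split <- function(y, fraction = 0.1, seed = 1L) {
  val <- logical(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_val <- max(1L, round(fraction * length(idx)))
      if (length(idx) > 1L) val[sample(idx, n_val)] <- TRUE
    }
  })
  val
}
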