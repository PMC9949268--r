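# Comparator models on the same 33 features: logistic regression (full and
# under-sampled) and gradient-boosted trees (full and under-sampled).

#' Fit the logistic-regression baseline
#'
#' Maximum-likelihood logistic regression
#' `logit(P) = beta0 + sum_i beta_i X_i` via IRLS (`stats::glm`). Under
#' (quasi-)perfect separation the MLE diverges; the fit is then
#' ridge-stabilized with a tiny penalty (`glmnet`, alpha = 0,
#' lambda = 1e-6) and flagged with a warning, so comparisons always return
#' finite coefficients.
#'
#' @param X feature matrix (standardized upstream for comparability).
#' @param y binary labels (both classes present).
#' @return object of class `gwas_logistic` with `intercept`, `beta` (named),
#'   `separation` flag. Methods: `coef`, `predict`, `print`.
#' @export
fit_logistic <- function(X, y) {
  stopifnot(length(unique(y)) == 2)
  df <- data.frame(y = y, X, check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial(), control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || any(!is.finite(coef(fit)))) {
    warning("separation detected; returning ridge-stabilized estimates (lambda = 1e-6)")
    Xr <- X
    if (ncol(Xr) < 2) Xr <- cbind(Xr, `.pad` = 0)  # glmnet needs >= 2 columns
    rf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0, lambda = 1e-6,
                         standardize = FALSE)
    beta <- as.numeric(rf$beta)
    names(beta) <- rownames(rf$beta)
    beta <- beta[colnames(X)]
    intercept <- as.numeric(rf$a0)
  } else {
    cf <- coef(fit)
    intercept <- unname(cf[1])
    beta <- cf[-1]
    names(beta) <- colnames(X)
  }
  structure(list(intercept = intercept, beta = beta, separation = sep,
                 deviance = if (!sep) fit$deviance else NA_real_,
                 null_deviance = if (!sep) fit$null.deviance else NA_real_),
            class = "gwas_logistic")
}

#' @export
coef.gwas_logistic <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
print.gwas_logistic <- function(x, ...) {
  cat("logistic baseline:", length(x$beta), "features",
      if (x$separation) "(ridge-stabilized)" else "", "\n")
  invisible(x)
}

#' Predict from the logistic baseline
#'
#' @param object a `gwas_logistic` fit.
#' @param newdata feature matrix with the model's columns.
#' @param ... unused.
#' @return probability vector `plogis(beta0 + X beta)`.
#' @export
predict.gwas_logistic <- function(object, newdata, ...) {
  nd <- newdata[, names(object$beta), drop = FALSE]
  unname(plogis(object$intercept + drop(nd %*% object$beta)))
}

#' @rdname predict.gwas_logistic
#' @param model a `gwas_logistic` fit.
#' @param X feature matrix.
#' @export
predict_logistic <- function(model, X) predict(model, X)

#' Fit the gradient-boosted-tree baseline
#'
#' Thin adapter over xgboost with the comparator's pinned settings: logistic
#' objective, at most `rounds` boosting iterations (default 50), RMSLE as the
#' evaluation metric, and `scale_pos_weight` defaulting to
#' `#negatives / #positives` to counter class imbalance.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param rounds maximum boosting iterations (default 50).
#' @param imbalance_weight positive-class weight; `NULL` (default) uses
#'   `#negatives / #positives`.
#' @param seed integer seed.
#' @return object of class `gwas_gbt` wrapping the booster.
#' @export
fit_gbt <- function(X, y, rounds = 50, imbalance_weight = NULL, seed = 1L) {
  stopifnot(length(unique(y)) == 2)
  if (is.null(imbalance_weight)) imbalance_weight <- sum(y == 0) / sum(y == 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  booster <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "rmsle",
                  scale_pos_weight = imbalance_weight, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = rounds))
  structure(list(booster = booster, rounds = rounds,
                 imbalance_weight = imbalance_weight,
                 schema = colnames(X)),
            class = "gwas_gbt")
}

#' @export
print.gwas_gbt <- function(x, ...) {
  cat("gradient-boosted-tree baseline:",
      xgboost::xgb.get.num.boosted.rounds(x$booster), "trees, scale_pos_weight =",
      format(x$imbalance_weight, digits = 3), "\n")
  invisible(x)
}

#' @export
predict.gwas_gbt <- function(object, newdata, ...) {
  nd <- xgboost::xgb.DMatrix(newdata[, object$schema, drop = FALSE])
  unname(predict(object$booster, nd))
}

#' Run the five-way method comparison
#'
#' Trains the network plus four baselines — logistic and gradient boosting on
#' the full variant set, and their `_subset` variants on exactly the
#' under-sampling mask used by the network — and evaluates each at variant
#' and locus level against a truth study.
#'
#' @param X raw feature matrix of the feature study.
#' @param y binary labels from the label study.
#' @param stats input-study summary statistics (for locus calling on
#'   predictions), aligned to the rows of `X`.
#' @param truth binary variant-level truth vector.
#' @param truth_loci truth `locus_set` for locus-level metrics.
#' @param methods subset of
#'   `c("dnn", "logistic", "logistic_subset", "gbt", "gbt_subset")`.
#' @param undersample_ratio negatives per positive in the training subset.
#' @param hyper [nn_hyper()] for the network.
#' @param threshold probability threshold for calling (default 0.5).
#' @param merge_bp locus merge distance (default 250 kb).
#' @param seed integer seed.
#' @return `data.frame`, one row per method: variant TPR/F1/AUROC and locus
#'   TPR/F1; attribute `predictions` holds each method's probability vector
#'   and `mask` the shared under-sampling mask.
#' @export
run_comparison <- function(X, y, stats, truth, truth_loci,
                           methods = c("dnn", "logistic", "logistic_subset",
                                       "gbt", "gbt_subset"),
                           undersample_ratio = 10, hyper = nn_hyper(),
                           threshold = 0.5, merge_bp = 250000, seed = 1L) {
  full <- labeled_set(X, y, stats$p_value < GWS_ALPHA)
  sub <- undersample(full, ratio = undersample_ratio, seed = seed)
  mask <- attr(sub, "mask")
  std <- suppressMessages(standardize(sub$X, others = list(X)))
  Xs_sub <- std$train
  Xs_full <- std$others[[1]]

  preds <- list()
  rows <- list()
  for (m in methods) {
    p <- tryCatch(switch(m,
      dnn = {
        fit <- gwasdnn(sub$X, sub$y, config = nn_config(ncol(X)), hyper = hyper)
        predict(fit, X)
      },
      logistic = predict(fit_logistic(Xs_full, y), Xs_full),
      logistic_subset = predict(fit_logistic(Xs_sub, sub$y), Xs_full),
      gbt = predict(fit_gbt(Xs_full, y, seed = seed), Xs_full),
      gbt_subset = predict(fit_gbt(Xs_sub, sub$y, seed = seed), Xs_full),
      stop("unknown method: ", m)
    ), error = function(e) {
      warning("method '", m, "' failed: ", conditionMessage(e))
      NULL
    })
    preds[[m]] <- p
    if (is.null(p)) {
      rows[[m]] <- data.frame(method = m, variant_tpr = NA, variant_f1 = NA,
                              variant_auroc = NA, locus_tpr = NA, locus_f1 = NA)
      next
    }
    vm <- variant_metrics(p, truth, threshold = threshold)
    called <- data.frame(variant_id = stats$variant_id, chrom = stats$chrom,
                         pos = stats$pos, score = p,
                         stringsAsFactors = FALSE)[p >= threshold, , drop = FALSE]
    pl <- call_loci(called, merge_bp = merge_bp)
    lm <- locus_metrics(pl, truth_loci, slack_bp = merge_bp)
    rows[[m]] <- data.frame(method = m, variant_tpr = vm$tpr, variant_f1 = vm$f1,
                            variant_auroc = vm$auroc, locus_tpr = lm$tpr,
                            locus_f1 = lm$f1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictions") <- preds
  attr(out, "mask") <- mask
  out
}
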