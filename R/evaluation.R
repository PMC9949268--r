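# Locus calling, enhanced-variant/locus identification, variant- and
# locus-level metrics, ROC/PRC, threshold sweeps, and validation binning.
#
# A locus is a single-linkage merge of significant variants: consecutive
# called variants at most `merge_bp` apart (default 250 kb) on one chromosome
# join the same locus. The index variant is the member with the highest
# score (input -log10 p for input loci, predicted probability for enhanced
# loci). Locus matching extends a locus span by `slack_bp` on each side and
# asks for any overlap.

#' Merge significant variants into loci
#'
#' @param significant `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `score` (the ranking used to pick the index variant).
#' @param merge_bp merge distance in bp; variants exactly `merge_bp` apart
#'   join one locus (default 250000).
#' @return a `locus_set`: `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive span of members), `n_variants`, `index_variant`, `index_score`,
#'   and attribute `members` (list of variant-id vectors).
#' @export
call_loci <- function(significant, merge_bp = 250000) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_variants = integer(), index_variant = character(),
                      index_score = numeric(), stringsAsFactors = FALSE)
  if (is.null(significant) || nrow(significant) == 0L) {
    attr(empty, "members") <- list()
    class(empty) <- c("locus_set", "data.frame")
    return(empty)
  }
  s <- significant[order(significant$chrom, significant$pos), , drop = FALSE]
  new_locus <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                   diff(s$pos) > merge_bp)
  id <- cumsum(new_locus)
  rows <- lapply(split(seq_len(nrow(s)), id), function(ix) {
    sc <- s$score[ix]
    top <- ix[which.max(sc)]
    data.frame(chrom = s$chrom[ix[1]], start = min(s$pos[ix]),
               end = max(s$pos[ix]), n_variants = length(ix),
               index_variant = s$variant_id[top], index_score = max(sc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- lapply(split(s$variant_id, id), identity)
  attr(out, "merge_bp") <- merge_bp
  class(out) <- c("locus_set", "data.frame")
  out
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus set:", nrow(x), "loci\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Match loci between two locus sets
#'
#' A locus in `a` matches if its span, extended by `slack_bp` on each side,
#' overlaps any locus span in `b` on the same chromosome.
#'
#' @param a,b `locus_set` objects (same genome build).
#' @param slack_bp span extension in bp (default 250000).
#' @return logical vector over the rows of `a`.
#' @export
match_loci <- function(a, b, slack_bp = 250000) {
  if (nrow(a) == 0L) return(logical(0))
  out <- logical(nrow(a))
  if (nrow(b) == 0L) return(out)
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    out[i] <- any(same & b$start <= a$end[i] + slack_bp &
                    b$end >= a$start[i] - slack_bp)
  }
  out
}

#' Identify enhanced variants and loci
#'
#' Enhanced variants are predicted significant (`P >= prob_threshold`) but
#' not genome-wide significant in the input study (`input p >= alpha`).
#' Enhanced loci are loci over all predicted-significant variants that
#' contain no input-significant member. Anti-enhanced loci — input-significant
#' loci whose members all fall below the probability threshold — are also
#' reported, capturing the model's removal of likely false positives.
#'
#' @param predictions named probability vector (names = variant ids) aligned
#'   with `input_stats`.
#' @param input_stats input-study summary statistics.
#' @param prob_threshold probability call threshold, inclusive (default 0.5).
#' @param alpha genome-wide significance threshold (default 5e-8).
#' @param merge_bp locus merge distance (default 250000).
#' @return list with `enhanced_variants` (a `data.frame`), `enhanced_loci`,
#'   `predicted_loci` (all predicted-significant loci), `input_loci` and
#'   `anti_enhanced_loci` (`locus_set`s), and the per-variant `table` with
#'   columns `variant_id, chrom, pos, input_p, pred_prob, input_significant,
#'   enhanced`.
#' @export
find_enhanced <- function(predictions, input_stats, prob_threshold = 0.5,
                          alpha = GWS_ALPHA, merge_bp = 250000) {
  stopifnot(length(predictions) == nrow(input_stats))
  p <- unname(predictions)
  pred_sig <- p >= prob_threshold
  input_sig <- input_stats$p_value < alpha
  enhanced <- pred_sig & !input_sig

  tab <- data.frame(variant_id = input_stats$variant_id,
                    chrom = input_stats$chrom, pos = input_stats$pos,
                    input_p = input_stats$p_value, pred_prob = p,
                    input_significant = input_sig, enhanced = enhanced,
                    stringsAsFactors = FALSE)

  score_df <- function(rows, score)
    data.frame(variant_id = tab$variant_id[rows], chrom = tab$chrom[rows],
               pos = tab$pos[rows], score = score[rows],
               stringsAsFactors = FALSE)

  predicted_loci <- call_loci(score_df(which(pred_sig), p), merge_bp)
  input_loci <- call_loci(score_df(which(input_sig), -log10(tab$input_p)), merge_bp)

  # enhanced loci: predicted loci with no input-significant member and no
  # overlap with any input-study locus (novelty is relative to the input
  # study's loci, which do not depend on the probability threshold)
  members <- attr(predicted_loci, "members")
  input_sig_ids <- tab$variant_id[input_sig]
  keep <- !vapply(members, function(m) any(m %in% input_sig_ids), logical(1)) &
    !match_loci(predicted_loci, input_loci, slack_bp = 0)
  enhanced_loci <- predicted_loci[keep, , drop = FALSE]
  attr(enhanced_loci, "members") <- members[keep]
  class(enhanced_loci) <- c("locus_set", "data.frame")

  # anti-enhanced: input loci whose members all fall below the threshold
  imembers <- attr(input_loci, "members")
  pred_sig_ids <- tab$variant_id[pred_sig]
  anti <- vapply(imembers, function(m) !any(m %in% pred_sig_ids), logical(1))
  anti_enhanced <- input_loci[anti, , drop = FALSE]
  attr(anti_enhanced, "members") <- imembers[anti]
  class(anti_enhanced) <- c("locus_set", "data.frame")

  list(enhanced_variants = tab[enhanced, , drop = FALSE],
       enhanced_loci = enhanced_loci,
       predicted_loci = predicted_loci,
       input_loci = input_loci,
       anti_enhanced_loci = anti_enhanced,
       table = tab)
}

#' Variant-level classification metrics
#'
#' Confusion counts at a threshold, TPR, precision, and
#' `F1 = TP / (TP + (FP + FN)/2)`, plus full ROC and precision-recall curves
#' obtained by sweeping every distinct prediction value; AUROC and AUPRC by
#' trapezoid integration.
#'
#' @param predictions probability/score vector.
#' @param truth binary truth vector.
#' @param threshold call threshold, inclusive (default 0.5).
#' @return list with `tp fp fn tn tpr fpr precision f1 auroc auprc`, `roc`
#'   (`data.frame` fpr/tpr) and `prc` (`data.frame` recall/precision). With a
#'   single-class truth the curves and areas are `NA` (reported missing).
#' @export
variant_metrics <- function(predictions, truth, threshold = 0.5) {
  stopifnot(length(predictions) == length(truth))
  truth <- as.integer(truth)
  tp <- sum(predictions >= threshold & truth == 1)
  fp <- sum(predictions >= threshold & truth == 0)
  fn <- sum(predictions < threshold & truth == 1)
  tn <- sum(predictions < threshold & truth == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (tp + (fp + fn) / 2 > 0) tp / (tp + (fp + fn) / 2) else NA_real_

  if (length(unique(truth)) < 2) {
    roc <- prc <- NULL; auroc <- auprc <- NA_real_
  } else {
    cuts <- c(Inf, sort(unique(predictions), decreasing = TRUE))
    n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
    tps <- fps <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
      tps[i] <- sum(predictions >= cuts[i] & truth == 1)
      fps[i] <- sum(predictions >= cuts[i] & truth == 0)
    }
    roc <- data.frame(fpr = fps / n_neg, tpr = tps / n_pos)
    auroc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
    rec <- tps / n_pos
    pr <- ifelse(tps + fps > 0, tps / (tps + fps), 1)
    prc <- data.frame(recall = rec, precision = pr)
    auprc <- sum(diff(rec) * (pr[-1] + pr[-length(pr)]) / 2)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, tpr = tpr, fpr = fpr,
       precision = prec, f1 = f1, auroc = auroc, auprc = auprc,
       roc = roc, prc = prc)
}

#' Locus-level metrics
#'
#' A truth locus is a true positive if matched by any predicted locus
#' ([match_loci()]); unmatched predicted loci are false positives; unmatched
#' truth loci are false negatives. TPR and F1 as at variant level.
#'
#' @param predicted,truth `locus_set` objects called with the same `merge_bp`.
#' @param slack_bp matching slack (default 250000).
#' @return list with `tp fp fn tpr precision f1`.
#' @export
locus_metrics <- function(predicted, truth, slack_bp = 250000) {
  truth_hit <- match_loci(truth, predicted, slack_bp)
  pred_hit <- match_loci(predicted, truth, slack_bp)
  tp <- sum(truth_hit); fn <- sum(!truth_hit); fp <- sum(!pred_hit)
  tpr <- if (nrow(truth)) tp / nrow(truth) else NA_real_
  prec <- if (nrow(predicted)) sum(pred_hit) / nrow(predicted) else NA_real_
  f1 <- if (tp + (fp + fn) / 2 > 0) tp / (tp + (fp + fn) / 2) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tpr = tpr, precision = prec, f1 = f1)
}

#' Sweep the probability threshold
#'
#' Tightens the call threshold from 0.50 to 0.95 in steps of 0.05 (by
#' default). Locus boundaries are fixed at the lowest threshold; at each
#' stricter threshold a locus survives iff its index variant's probability
#' reaches it, so the enhanced-variant and enhanced-locus counts are nested
#' and non-increasing. Per threshold the surviving loci are matched against
#' an optional independent validation study.
#'
#' @param predictions named probability vector aligned with `input_stats`.
#' @param input_stats input-study summary statistics.
#' @param validation_loci optional `locus_set` used to flag validated loci.
#' @param thresholds numeric vector (default `seq(0.5, 0.95, 0.05)`).
#' @param merge_bp locus merge distance.
#' @param slack_bp matching slack for validation.
#' @return `data.frame` with `threshold`, `n_enhanced_variants`,
#'   `n_enhanced_loci`, `n_validated`.
#' @export
threshold_sweep <- function(predictions, input_stats, validation_loci = NULL,
                            thresholds = seq(0.5, 0.95, by = 0.05),
                            merge_bp = 250000, slack_bp = 250000) {
  thresholds <- sort(thresholds)
  base <- find_enhanced(predictions, input_stats,
                        prob_threshold = thresholds[1], merge_bp = merge_bp)
  loci <- base$enhanced_loci
  validated <- if (is.null(validation_loci) || nrow(loci) == 0L) {
    rep(NA, max(1L, nrow(loci)))
  } else match_loci(loci, validation_loci, slack_bp)
  p <- base$table$pred_prob
  not_input_sig <- !base$table$input_significant
  rows <- lapply(thresholds, function(th) {
    alive <- loci$index_score >= th
    nv <- if (is.null(validation_loci)) NA_integer_ else
      sum(validated[alive], na.rm = TRUE)
    data.frame(threshold = th,
               n_enhanced_variants = sum(p >= th & not_input_sig),
               n_enhanced_loci = sum(alive),
               n_validated = nv)
  })
  do.call(rbind, rows)
}

#' Bin enhanced loci by predicted probability and assess validation
#'
#' Bins enhanced loci by the predicted probability of their index variant
#' (bins of width 0.05 over \[0.5, 1\]) and reports, per bin, the number of
#' loci, the proportion validated by at least one independent study, and the
#' distribution of how many studies validate each locus.
#'
#' @param enhanced_loci `locus_set` with `index_score` = index-variant
#'   probability.
#' @param validation_loci_list list of `locus_set`s from independent studies.
#' @param slack_bp matching slack (default 250000).
#' @param bin_width probability bin width (default 0.05).
#' @return list with `bins` (`data.frame`: `bin_lo`, `bin_hi`, `n_loci`,
#'   `prop_validated`) and `n_studies_validating` (integer per locus).
#' @export
validation_binning <- function(enhanced_loci, validation_loci_list,
                               slack_bp = 250000, bin_width = 0.05) {
  stopifnot(length(validation_loci_list) >= 1)
  n <- nrow(enhanced_loci)
  n_val <- integer(n)
  for (v in validation_loci_list)
    n_val <- n_val + as.integer(match_loci(enhanced_loci, v, slack_bp))
  breaks <- seq(0.5, 1, by = bin_width)
  bin <- cut(pmin(pmax(enhanced_loci$index_score, 0.5), 1 - 1e-12),
             breaks = breaks, right = FALSE, include.lowest = TRUE)
  bins <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  bins$n_loci <- as.integer(table(bin))
  prop <- tapply(n_val > 0, bin, mean)
  bins$prop_validated <- as.numeric(prop)
  list(bins = bins, n_studies_validating = n_val)
}
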