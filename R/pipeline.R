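# High-level orchestration: feature building for a study and the full
# enhancement run (train on study A features / study B labels, apply to
# study B features, evaluate against study C).

#' Build the feature matrix for one study
#'
#' Computes MAF and both LD scores from the panel (the known-variant LD score
#' uses *this* study's genome-wide-significant variants) and assembles the
#' full feature matrix with the given annotations.
#'
#' @param stats summary statistics of the study (harmonized to the panel).
#' @param panel a [genotype_panel()].
#' @param annotations list with `indicator_tracks`, `score_tracks`, `eqtl`
#'   (as produced by [simulate_annotations()] or read from files).
#' @param alpha significance threshold defining the known set (default 5e-8).
#' @param window_bp LD window (default 1 Mb).
#' @param include_self self term in the overall LD score (default TRUE).
#' @param eqtl_p_max strict eQTL p threshold (default 1e-6).
#' @return feature matrix (rows = variants in `stats` order).
#' @export
build_features <- function(stats, panel, annotations, alpha = GWS_ALPHA,
                           window_bp = 1e6, include_self = TRUE,
                           eqtl_p_max = 1e-6) {
  known <- stats$variant_id[stats$p_value < alpha]
  ld <- ld_features(panel, known = known, window_bp = window_bp,
                    include_self = include_self)
  assemble_features(stats, ld,
                    indicator_tracks = annotations$indicator_tracks,
                    score_tracks = annotations$score_tracks,
                    eqtl_set = filter_eqtls(annotations$eqtl, eqtl_p_max))
}

#' Hyperparameters used by the benchmark harness
#'
#' A slightly faster schedule than the [nn_hyper()] defaults, sized for the
#' desk-scale benchmark (a few thousand training rows).
#'
#' @param seed integer seed.
#' @return an [nn_hyper()].
#' @export
benchmark_hyper <- function(seed = 1L) {
  nn_hyper(learning_rate = 2e-3, batch_size = 512, max_epochs = 60,
           patience = 8, seed = seed)
}

#' Run the full enhancement benchmark on simulated data
#'
#' Mirrors the three-study design: study A (small) contributes input
#' features, study B (large) contributes labels; the trained model is applied
#' to study B's features and its predictions are evaluated against study C
#' significance and the planted ground truth. If the label study contains no
#' genome-wide-significant variant (e.g. a null simulation) no model can be
#' trained and the run reports zero predicted/enhanced loci.
#'
#' @param bench a benchmark from [make_benchmark()].
#' @param undersample_ratio negatives per positive for training (default 10).
#' @param hyper an [nn_hyper()] (default [benchmark_hyper()]).
#' @param prob_threshold call threshold (default 0.5).
#' @param merge_bp locus merge distance (default 250 kb).
#' @return list of class `enhancement_run`: the fitted `model` (or `NULL`),
#'   `predictions`, `enhancement` (from [find_enhanced()] on study B),
#'   `metrics` (variant AUROC vs ground truth, locus TPR/F1 for enhanced
#'   calls and for the input baseline vs study-C loci), plus the feature
#'   matrices and locus sets used.
#' @export
run_enhancement <- function(bench, undersample_ratio = 10,
                            hyper = benchmark_hyper(bench$config$seed),
                            prob_threshold = 0.5, merge_bp = 250000) {
  X_a <- build_features(bench$study_small, bench$panel, bench$annotations)
  X_b <- build_features(bench$study_large, bench$panel, bench$annotations)
  y <- label_variants(bench$study_large)
  stopifnot(identical(rownames(X_a), names(y)))

  causal_truth <- as.integer(bench$study_small$variant_id %in% bench$truth$causal_ids)
  input_sig <- bench$study_large$p_value < GWS_ALPHA

  model <- NULL
  if (sum(y) > 0) {
    full <- labeled_set(X_a, y, bench$study_small$p_value < GWS_ALPHA)
    sub <- undersample(full, ratio = undersample_ratio, seed = hyper$seed)
    model <- gwasdnn(sub$X, sub$y, config = nn_config(ncol(X_a)), hyper = hyper)
    predictions <- predict(model, X_b)
  } else {
    predictions <- setNames(rep(0, nrow(X_b)), rownames(X_b))
  }

  enh <- find_enhanced(predictions, bench$study_large,
                       prob_threshold = prob_threshold, merge_bp = merge_bp)

  sC <- bench$study_validation
  truth_loci <- call_loci(
    data.frame(variant_id = sC$variant_id, chrom = sC$chrom, pos = sC$pos,
               score = -log10(sC$p_value),
               stringsAsFactors = FALSE)[sC$p_value < GWS_ALPHA, , drop = FALSE],
    merge_bp = merge_bp)

  vm <- if (sum(y) > 0)
    variant_metrics(predictions, causal_truth, threshold = prob_threshold)
  else NULL
  locus_model <- locus_metrics(enh$predicted_loci, truth_loci, slack_bp = merge_bp)
  locus_input <- locus_metrics(enh$input_loci, truth_loci, slack_bp = merge_bp)

  # enhanced loci containing a true causal variant not significant in study B
  members <- attr(enh$enhanced_loci, "members")
  novel_causal <- vapply(members, function(m)
    any(m %in% bench$truth$causal_ids & !(m %in% bench$study_large$variant_id[input_sig])),
    logical(1))

  structure(list(model = model, predictions = predictions,
                 enhancement = enh, features_a = X_a, features_b = X_b,
                 labels = y, truth_loci = truth_loci,
                 metrics = list(
                   variant = vm,
                   auroc_vs_causal = if (is.null(vm)) NA_real_ else vm$auroc,
                   locus_model = locus_model,
                   locus_input = locus_input,
                   n_enhanced_loci = nrow(enh$enhanced_loci),
                   n_enhanced_causal_novel = sum(novel_causal))),
            class = "enhancement_run")
}

#' @export
print.enhancement_run <- function(x, ...) {
  m <- x$metrics
  cat("enhancement run:", length(x$predictions), "variants\n")
  cat("  enhanced loci:", m$n_enhanced_loci,
      "(", m$n_enhanced_causal_novel, "containing a novel causal variant )\n")
  cat("  variant AUROC vs causal truth:",
      if (is.na(m$auroc_vs_causal)) "NA" else format(m$auroc_vs_causal, digits = 3), "\n")
  cat("  locus TPR vs validation-study truth: model",
      format(m$locus_model$tpr, digits = 3), "/ input baseline",
      format(m$locus_input$tpr, digits = 3), "\n")
  invisible(x)
}

#' Simulate a second trait sharing the causal-annotation architecture
#'
#' Draws a fresh set of causal variants *preferentially from the first
#' trait's annotated regions* (so the annotation-to-causality structure is
#' shared while the causal variants themselves differ), simulates a study of
#' the given size over the same panel, and returns its feature matrix and
#' ground truth. Used to test frozen-weight transfer across traits.
#'
#' @param bench the original benchmark from [make_benchmark()].
#' @param n_samples sample size of the second trait's study (default: the
#'   label study's).
#' @param seed integer seed.
#' @return list with `stats`, `features`, `truth` (causal ids), `study_truth`
#'   binary vector aligned with `features` rows.
#' @export
simulate_related_trait <- function(bench, n_samples = bench$config$n_large,
                                   seed = bench$config$seed + 101L) {
  config <- bench$config
  lay <- attr(bench$panel, "layout")
  # annotation propensity: how many binary tracks cover each variant
  cover <- Reduce(`+`, lapply(bench$annotations$indicator_tracks, function(t)
    overlap_indicator(lay, t)))
  withr::with_seed(seed, {
    w <- (1 + cover)^2
    blocks <- sample(config$n_blocks, config$n_causal_loci)
    picks <- integer(0)
    for (b in blocks) {
      ix <- which(lay$block == b)
      k <- max(1L, round(config$n_causal / config$n_causal_loci))
      picks <- c(picks, sample(ix, min(k, length(ix)), prob = w[ix]))
    }
    a <- numeric(config$n_variants)
    a[picks] <- rnorm(length(picks), 0, config$effect_sd)
  })
  names(a) <- lay$variant_id
  truth2 <- structure(list(causal_ids = lay$variant_id[sort(picks)],
                           effects = a, causal_blocks = sort(blocks),
                           true_loci = NULL),
                      class = "ground_truth")
  stats <- simulate_study(bench$panel, truth2, n_samples, seed = seed + 1L,
                          block_R = bench$block_R)
  features <- build_features(stats, bench$panel, bench$annotations)
  list(stats = stats, features = features, truth = truth2,
       study_truth = as.integer(lay$variant_id %in% truth2$causal_ids))
}
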