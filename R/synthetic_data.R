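# Synthetic benchmark generator: block-LD reference panels, a sparse set of
# causal variants clustered into loci, paired GWA studies of differing power
# sharing those causal variants, and annotations enriched at causal variants.
#
# Summary statistics are simulated directly with the standard multivariate-
# normal model for marginal z-scores: within an LD block with correlation
# matrix R and standardized causal effects a, z ~ N(sqrt(n) R a, R). This is
# faster than individual-level phenotype simulation and exercises every
# pipeline stage; individual-level genotypes exist only in the panel.

#' Simulation configuration
#'
#' Defaults define a desk-scale benchmark: 20,000 variants in 40 blocks of
#' 500 (positions ~5 kb apart, blocks separated by >1 Mb so LD windows never
#' straddle blocks), exchangeable latent correlation 0.5 within blocks, a
#' 200-individual panel, MAF in \[0.05, 0.5\], 36 causal variants clustered
#' in 12 causal loci, per-causal standardized effect sd 0.03, studies of
#' 20k/60k/120k samples, and annotation enrichment 5 at base rate 0.05.
#'
#' @param n_variants total variant count.
#' @param n_blocks number of LD blocks.
#' @param block_correlation exchangeable latent correlation within a block,
#'   in `[0, 1)`.
#' @param maf_range range the per-variant MAFs are drawn from, inside (0, 0.5].
#' @param n_individuals_panel panel size.
#' @param causal_fraction fraction of variants that are causal, in (0, 1).
#' @param n_causal_loci number of causal loci the causal variants cluster
#'   into (`NULL`: `ceiling(n_causal / 3)`).
#' @param effect_sd sd of the per-causal standardized effect.
#' @param n_small,n_large,n_validation sample sizes of the feature, label and
#'   validation studies.
#' @param annotation_enrichment relative rate `e >= 1` of annotation
#'   membership at causal vs non-causal variants.
#' @param annotation_base_rate non-causal membership rate `q` (`e * q <= 1`).
#' @param n_annotation_tracks number of binary interval tracks.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 20000, n_blocks = 40,
                       block_correlation = 0.5, maf_range = c(0.05, 0.5),
                       n_individuals_panel = 200, causal_fraction = 0.0018,
                       n_causal_loci = NULL, effect_sd = 0.03,
                       n_small = 20000, n_large = 60000, n_validation = 120000,
                       annotation_enrichment = 5, annotation_base_rate = 0.05,
                       n_annotation_tracks = 24, seed = 1L) {
  stopifnot(n_variants > 0, n_blocks > 0, n_variants %% n_blocks == 0,
            block_correlation >= 0, block_correlation < 1,
            causal_fraction > 0, causal_fraction < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            n_individuals_panel >= 2, effect_sd >= 0,
            annotation_enrichment >= 1)
  if (annotation_enrichment * annotation_base_rate > 1)
    stop("annotation_enrichment * annotation_base_rate exceeds 1")
  n_causal <- max(1L, round(causal_fraction * n_variants))
  if (is.null(n_causal_loci)) n_causal_loci <- min(n_blocks, ceiling(n_causal / 3))
  if (n_causal_loci > n_blocks)
    stop("n_causal_loci cannot exceed n_blocks")
  if (n_causal_loci > n_causal) n_causal_loci <- n_causal
  structure(list(n_variants = as.integer(n_variants),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(n_variants / n_blocks),
                 block_correlation = block_correlation,
                 maf_range = maf_range,
                 n_individuals_panel = as.integer(n_individuals_panel),
                 causal_fraction = causal_fraction,
                 n_causal = as.integer(n_causal),
                 n_causal_loci = as.integer(n_causal_loci),
                 effect_sd = effect_sd,
                 n_small = as.integer(n_small), n_large = as.integer(n_large),
                 n_validation = as.integer(n_validation),
                 annotation_enrichment = annotation_enrichment,
                 annotation_base_rate = annotation_base_rate,
                 n_annotation_tracks = as.integer(n_annotation_tracks),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# variant layout: blocks placed on one chromosome with 2 Mb gaps between
# them so a 1 Mb LD window never spans two blocks; ~5 kb spacing inside.
sim_layout <- function(config) {
  bs <- config$block_size
  block <- rep(seq_len(config$n_blocks), each = bs)
  within <- rep(seq_len(bs), config$n_blocks)
  pos <- (block - 1L) * (bs * 5000L + 2000000L) + within * 5000L
  data.frame(variant_id = sprintf("var%06d", seq_len(config$n_variants)),
             chrom = "1", pos = as.integer(pos), block = block,
             stringsAsFactors = FALSE)
}

#' Simulate a block-LD genotype reference panel
#'
#' Within each block, latent exchangeable Gaussians with correlation
#' `block_correlation` are thresholded to Hardy-Weinberg genotypes at MAFs
#' drawn from `maf_range`; blocks are independent. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return a [genotype_panel()] with attribute `layout`.
#' @export
simulate_panel <- function(config) {
  lay <- sim_layout(config)
  n_ind <- config$n_individuals_panel
  rho <- config$block_correlation
  geno <- matrix(0L, n_ind, config$n_variants)
  mafs <- numeric(config$n_variants)
  withr::with_seed(config$seed, {
    mafs[] <- runif(config$n_variants, config$maf_range[1], config$maf_range[2])
    for (b in seq_len(config$n_blocks)) {
      ix <- which(lay$block == b)
      m <- length(ix)
      # two latent haplotype draws per individual, exchangeable correlation
      for (h in 1:2) {
        shared <- rnorm(n_ind)
        lat <- sqrt(rho) * matrix(shared, n_ind, m) +
          sqrt(1 - rho) * matrix(rnorm(n_ind * m), n_ind, m)
        thr <- qnorm(mafs[ix])
        carrier <- sweep(lat, 2, thr, "<")
        geno[, ix] <- geno[, ix] + carrier
      }
    }
  })
  map <- data.frame(variant_id = lay$variant_id, chrom = lay$chrom,
                    pos = lay$pos, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, map)
  attr(panel, "layout") <- lay
  attr(panel, "target_maf") <- mafs
  panel
}

#' Plant causal variants and effects
#'
#' Draws `n_causal` causal variants clustered into `n_causal_loci` blocks
#' (each chosen block holds at least one causal variant) with standardized
#' effects `a ~ N(0, effect_sd^2)`; returns the ground truth used by the
#' evaluation.
#'
#' @param config a [sim_config()].
#' @param panel the panel from [simulate_panel()].
#' @return list of class `ground_truth`: `causal_ids`, `effects` (named,
#'   full-length, zero off the causal set), `causal_blocks`, `true_loci`
#'   (a `locus_set` of causal-locus spans).
#' @export
simulate_effects <- function(config, panel) {
  lay <- attr(panel, "layout")
  withr::with_seed(config$seed + 1L, {
    blocks <- sample(config$n_blocks, config$n_causal_loci)
    # each causal locus gets one causal variant, remainder spread uniformly
    picks <- vapply(blocks, function(b) sample(which(lay$block == b), 1L), integer(1))
    remainder <- config$n_causal - length(picks)
    if (remainder > 0) {
      pool <- setdiff(which(lay$block %in% blocks), picks)
      picks <- c(picks, sample(pool, remainder))
    }
    picks <- sort(picks[seq_len(min(length(picks), config$n_causal))])
    a <- numeric(config$n_variants)
    a[picks] <- rnorm(length(picks), 0, config$effect_sd)
  })
  names(a) <- lay$variant_id
  spans <- do.call(rbind, lapply(sort(blocks), function(b) {
    ix <- intersect(picks, which(lay$block == b))
    data.frame(chrom = "1", start = min(lay$pos[ix]), end = max(lay$pos[ix]),
               n_variants = length(ix),
               index_variant = lay$variant_id[ix[1]], index_score = NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(spans) <- NULL
  attr(spans, "members") <- lapply(sort(blocks), function(b)
    lay$variant_id[intersect(picks, which(lay$block == b))])
  class(spans) <- c("locus_set", "data.frame")
  structure(list(causal_ids = lay$variant_id[picks], effects = a,
                 causal_blocks = sort(blocks), true_loci = spans),
            class = "ground_truth")
}

# per-block panel correlation matrices with ridge repair, cached on the panel
block_correlations <- function(panel, ridge = 1e-6) {
  lay <- attr(panel, "layout")
  lapply(seq_len(max(lay$block)), function(b) {
    ix <- which(lay$block == b)
    R <- suppressWarnings(cor(panel$geno[, ix, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      R <- R + diag(ridge, nrow(R))
      R <- R / (1 + ridge)
      diag(R) <- 1 + ridge
      ch <- chol(R)
    }
    list(R = R, chol = ch, ix = ix)
  })
}

#' Simulate a GWA study's summary statistics
#'
#' Marginal z-scores per block: `z ~ N(sqrt(n) R a, R)` with `R` the block's
#' panel correlation (ridge-repaired if not positive definite) and `a` the
#' standardized causal effects. Then `p = 2 Phi(-|z|)`, `se = 1/sqrt(n)` and
#' `OR = exp(z * se)` on the standardized scale. Two studies with the same
#' truth differ only in `n` and the noise seed.
#'
#' @param panel panel from [simulate_panel()].
#' @param truth ground truth from [simulate_effects()].
#' @param n_samples study sample size.
#' @param seed noise seed for this study.
#' @param block_R optional precomputed [block_correlations()] (cached reuse).
#' @return a summary-statistics `data.frame` as from [read_summary_stats()].
#' @export
simulate_study <- function(panel, truth, n_samples, seed,
                           block_R = block_correlations(panel)) {
  lay <- attr(panel, "layout")
  z <- numeric(nrow(lay))
  withr::with_seed(seed, {
    for (blk in block_R) {
      mu <- sqrt(n_samples) * drop(blk$R %*% truth$effects[blk$ix])
      noise <- drop(crossprod(blk$chol, rnorm(length(blk$ix))))
      z[blk$ix] <- mu + noise
    }
  })
  p <- 2 * pnorm(-abs(z))
  p <- pmax(p, 1e-320)
  se <- 1 / sqrt(n_samples)
  out <- data.frame(variant_id = lay$variant_id, chrom = lay$chrom,
                    pos = lay$pos, allele_effect = "G", allele_other = "A",
                    odds_ratio = exp(z * se), p_value = p, se = se,
                    stringsAsFactors = FALSE)
  attr(out, "key") <- variant_key(out$chrom, out$pos, out$allele_effect,
                                  out$allele_other)
  attr(out, "z") <- z
  out
}

#' Simulate enriched annotations
#'
#' Binary interval tracks cover causal variants at rate `e * q` and
#' non-causal variants at rate `q`; score tracks are standard-normal noise
#' with a +1 shift at causal variants; the eQTL table contains causal
#' variants with `p < 1e-6` at an elevated rate (0.4 vs 0.02). Intervals are
#' 500 bp windows centred on member variants. Deterministic given seed.
#'
#' @param truth ground truth from [simulate_effects()].
#' @param config a [sim_config()].
#' @param panel the panel (supplies the variant layout).
#' @return list with `indicator_tracks` (named list of
#'   [interval_annotation()]), `score_tracks` (named list of named numeric
#'   vectors) and `eqtl` (`data.frame` variant_id/gene/p).
#' @export
simulate_annotations <- function(truth, config, panel) {
  lay <- attr(panel, "layout")
  causal <- lay$variant_id %in% truth$causal_ids
  q <- config$annotation_base_rate
  e <- config$annotation_enrichment
  rate <- ifelse(causal, pmin(e * q, 1), q)
  track_names <- c("open_chromatin_adult", "open_chromatin_fetal",
                   "fire_adult", "fire_fetal", "super_fire_adult",
                   "super_fire_fetal", "selective_sweep",
                   "ccre_dhs", "ccre_h3k27ac", "ccre_h3k4me3", "ccre_ctcf",
                   "ccre_tf",
                   sprintf("meta%02d", seq_len(11)), "user_slot")
  track_names <- track_names[seq_len(config$n_annotation_tracks)]
  withr::with_seed(config$seed + 2L, {
    indicator_tracks <- lapply(track_names, function(nm) {
      member <- runif(nrow(lay)) < rate
      interval_annotation(nm, lay$chrom[member], lay$pos[member] - 250,
                          lay$pos[member] + 250)
    })
    names(indicator_tracks) <- track_names
    score_tracks <- lapply(c("phylop", "fathmm_xf", "cadd_phred"), function(nm)
      setNames(rnorm(nrow(lay)) + causal * 1.0, lay$variant_id))
    names(score_tracks) <- c("phylop", "fathmm_xf", "cadd_phred")
    has_eqtl <- runif(nrow(lay)) < ifelse(causal, 0.4, 0.02)
    eqtl <- data.frame(
      variant_id = lay$variant_id[has_eqtl],
      gene = sprintf("GENE%04d", lay$block[has_eqtl]),
      p = 10^-runif(sum(has_eqtl), 6.05, 12),
      stringsAsFactors = FALSE)
    # plus sub-threshold associations that the strict p < 1e-6 filter drops
    weak <- runif(nrow(lay)) < 0.02
    eqtl <- rbind(eqtl, data.frame(
      variant_id = lay$variant_id[weak],
      gene = sprintf("GENE%04dw", lay$block[weak]),
      p = 10^-runif(sum(weak), 0, 5.9), stringsAsFactors = FALSE))
  })
  list(indicator_tracks = indicator_tracks, score_tracks = score_tracks,
       eqtl = eqtl)
}

#' Generate a complete benchmark
#'
#' One panel and ground truth, three studies of increasing size over the same
#' truth (the feature study A, the label study B, and the validation study
#' C), and enriched annotations. With `dir` set, everything is also written
#' to disk in the package's standard formats (gzipped VCF panel, TSV summary
#' statistics, BED tracks, TSV score tracks and eQTL table, TSV ground
#' truth), re-readable by the data-io layer.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list with `config`, `panel`, `truth`, `study_small`,
#'   `study_large`, `study_validation`, `annotations`, `block_R`.
#' @export
make_benchmark <- function(config = sim_config(), dir = NULL) {
  panel <- simulate_panel(config)
  truth <- simulate_effects(config, panel)
  block_R <- block_correlations(panel)
  study_small <- simulate_study(panel, truth, config$n_small,
                                seed = config$seed + 11L, block_R = block_R)
  study_large <- simulate_study(panel, truth, config$n_large,
                                seed = config$seed + 12L, block_R = block_R)
  study_validation <- simulate_study(panel, truth, config$n_validation,
                                     seed = config$seed + 13L, block_R = block_R)
  ann <- simulate_annotations(truth, config, panel)
  bench <- list(config = config, panel = panel, truth = truth,
                study_small = study_small, study_large = study_large,
                study_validation = study_validation, annotations = ann,
                block_R = block_R)
  if (!is.null(dir)) write_benchmark(bench, dir)
  bench
}

write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel_vcf(bench$panel, file.path(dir, "panel.vcf.gz"))
  wr <- function(stats, name) {
    out <- data.frame(CHR = stats$chrom, BP = stats$pos, SNP = stats$variant_id,
                      A1 = stats$allele_effect, A2 = stats$allele_other,
                      OR = stats$odds_ratio, P = stats$p_value, SE = stats$se)
    write.table(out, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(bench$study_small, "study_A.tsv")
  wr(bench$study_large, "study_B.tsv")
  wr(bench$study_validation, "study_C.tsv")
  for (nm in names(bench$annotations$indicator_tracks)) {
    iv <- bench$annotations$indicator_tracks[[nm]]$intervals
    write.table(iv, file.path(dir, paste0(nm, ".bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  for (nm in names(bench$annotations$score_tracks)) {
    sc <- bench$annotations$score_tracks[[nm]]
    write.table(data.frame(variant_id = names(sc), score = as.numeric(sc)),
                file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(bench$annotations$eqtl, file.path(dir, "eqtl.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(variant_id = bench$truth$causal_ids,
                         effect = bench$truth$effects[bench$truth$causal_ids]),
              file.path(dir, "ground_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
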