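# The generator: panel structure, effects, study calibration, annotations.
# Small configurations here; the full-size benchmark is exercised by the
# acceptance tests.

small_cfg <- function(...) {
  args <- modifyList(list(n_variants = 1000, n_blocks = 5,
                          n_individuals_panel = 150, causal_fraction = 0.012,
                          seed = 17), list(...))
  do.call(sim_config, args)
}

test_that("panels are deterministic with planted within-block correlation", {
  cfg <- small_cfg(block_correlation = 0.9, n_individuals_panel = 500)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$geno, p2$geno)

  lay <- attr(p1, "layout")
  within <- c(); between <- c()
  set.seed(1)
  for (k in 1:300) {
    ij <- sample(cfg$n_variants, 2)
    r2 <- suppressMessages(pairwise_r2(p1, lay$variant_id[ij[1]],
                                       lay$variant_id[ij[2]]))
    if (lay$block[ij[1]] == lay$block[ij[2]]) within <- c(within, r2)
    else between <- c(between, r2)
  }
  expect_gt(mean(within), mean(between))

  # rho = 0: within-block r2 is at the independence null, ~1/n
  r2s <- c()
  for (s in 1:20) {
    p0 <- simulate_panel(small_cfg(block_correlation = 0, n_variants = 50,
                                   n_blocks = 1, n_individuals_panel = 100,
                                   seed = s))
    R <- cor(p0$geno)
    r2s <- c(r2s, mean(R[upper.tri(R)]^2))
  }
  expect_lt(mean(r2s), 3 / 100)
})

test_that("effects: deterministic count, clustered placement, moment check", {
  cfg <- small_cfg(causal_fraction = 12 / 1000)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  expect_equal(length(truth$causal_ids), 12)
  expect_equal(nrow(truth$true_loci), cfg$n_causal_loci)
  # each causal locus holds at least one causal variant
  expect_true(all(vapply(attr(truth$true_loci, "members"), length,
                         integer(1)) >= 1))

  cfg2 <- small_cfg(n_variants = 5000, n_blocks = 10, causal_fraction = 0.2,
                    effect_sd = 0.05, n_causal_loci = 10)
  t2 <- simulate_effects(cfg2, simulate_panel(cfg2))
  a <- t2$effects[t2$causal_ids]
  expect_equal(length(a), 1000)
  expect_lt(abs(sd(a) - 0.05) / 0.05, 0.1)
})

test_that("null studies are calibrated and zero effects give null z-scores", {
  cfg <- small_cfg(n_variants = 10000, n_blocks = 10, effect_sd = 0,
                   block_correlation = 0.3)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  s <- simulate_study(panel, truth, 50000, seed = 5)
  frac <- mean(s$p_value < 0.05)
  # binomial Monte-Carlo band (correlated variants widen it; 3 blocks-worth)
  expect_lt(abs(frac - 0.05), 0.02)
  expect_lt(abs(mean(attr(s, "z"))), 0.1)
})

test_that("power: strong causal detected, monotone in sample size", {
  # n chosen so sqrt(n) * a = 8 at the causal variant
  cfg <- small_cfg(n_variants = 100, n_blocks = 1, causal_fraction = 0.01,
                   block_correlation = 0.2)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  a <- 0.04
  truth$effects[] <- 0
  truth$effects[truth$causal_ids[1]] <- a
  n <- (8 / a)^2
  hits <- 0
  for (s in 1:25) {
    st <- simulate_study(panel, truth, n, seed = 1000 + s)
    if (st$p_value[st$variant_id == truth$causal_ids[1]] < 5e-8) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.9)   # theoretical power ~0.995

  # larger studies detect at least as much (median over 5 seeds)
  cfgp <- small_cfg(effect_sd = 0.05)
  pp <- simulate_panel(cfgp); tt <- simulate_effects(cfgp, pp)
  diffs <- vapply(1:5, function(s) {
    small <- simulate_study(pp, tt, 20000, seed = 2000 + s)
    large <- simulate_study(pp, tt, 80000, seed = 3000 + s)
    sum(large$p_value < 5e-8) - sum(small$p_value < 5e-8)
  }, numeric(1))
  expect_gte(median(diffs), 0)
  expect_gt(sum(diffs), 0)
})

test_that("annotations are enriched at causal variants as configured", {
  cfg <- small_cfg(n_variants = 10000, n_blocks = 10, causal_fraction = 0.05,
                   annotation_enrichment = 5, annotation_base_rate = 0.05)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  ann <- simulate_annotations(truth, cfg, panel)
  lay <- attr(panel, "layout")
  causal <- lay$variant_id %in% truth$causal_ids

  # contingency-table odds ratio of membership vs causality
  member <- overlap_indicator(lay, ann$indicator_tracks[[1]]) == 1
  or <- (sum(member & causal) / sum(!member & causal)) /
    (sum(member & !causal) / sum(!member & !causal))
  expect_gt(or, 1)

  # e = 1: no enrichment beyond binomial noise
  cfg1 <- small_cfg(n_variants = 10000, n_blocks = 10, causal_fraction = 0.05,
                    annotation_enrichment = 1)
  ann1 <- simulate_annotations(truth, cfg1, panel)
  m1 <- overlap_indicator(lay, ann1$indicator_tracks[[1]]) == 1
  r_causal <- mean(m1[causal]); r_bg <- mean(m1[!causal])
  expect_lt(abs(r_causal - r_bg),
            3 * sqrt(0.05 * 0.95 / sum(causal)) + 3 * sqrt(0.05 * 0.95 / sum(!causal)))

  # eQTL table: causal variants below 1e-6 at elevated rate; determinism
  eq_set <- filter_eqtls(ann$eqtl)
  expect_gt(mean(truth$causal_ids %in% eq_set),
            mean(lay$variant_id[!causal] %in% eq_set))
  ann_b <- simulate_annotations(truth, cfg, panel)
  expect_identical(ann_b$eqtl, ann$eqtl)
  expect_error(simulate_annotations(truth, small_cfg(annotation_enrichment = 30,
                                                     annotation_base_rate = 0.05),
                                    panel),
               "exceeds")
})

test_that("benchmark files round-trip through the data-io layer", {
  cfg <- small_cfg(n_variants = 400, n_blocks = 2, n_individuals_panel = 60)
  dir <- tempfile()
  bench <- make_benchmark(cfg, dir = dir)
  sA <- read_summary_stats(file.path(dir, "study_A.tsv"))
  expect_equal(nrow(sA), 400)
  expect_equal(sum(attr(sA, "skip_report")), 0)
  expect_equal(sA$p_value, bench$study_small$p_value, tolerance = 1e-6)
  panel <- read_panel_vcf(file.path(dir, "panel.vcf.gz"))
  expect_equal(unname(panel$geno), unname(bench$panel$geno))
  bed <- read_bed_annotation(file.path(dir, "open_chromatin_adult.bed"))
  expect_equal(nrow(bed$intervals),
               nrow(bench$annotations$indicator_tracks[[1]]$intervals))
  gt <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_setequal(gt$variant_id, bench$truth$causal_ids)

  # whole benchmark deterministic given the master seed
  bench2 <- make_benchmark(cfg)
  expect_identical(bench2$study_large$p_value, bench$study_large$p_value)
  expect_identical(bench2$truth$causal_ids, bench$truth$causal_ids)
})

test_that("study files re-read losslessly at full float precision", {
  cfg <- small_cfg(n_variants = 200, n_blocks = 1, n_individuals_panel = 50)
  bench <- make_benchmark(cfg)
  # power ordering across the three studies (significant-locus counts)
  counts <- vapply(list(bench$study_small, bench$study_large,
                        bench$study_validation), function(s)
    nrow(call_loci(data.frame(variant_id = s$variant_id, chrom = s$chrom,
                              pos = s$pos, score = -log10(s$p_value))[
                                s$p_value < 5e-8, , drop = FALSE])),
    numeric(1))
  expect_true(counts[1] <= counts[2] + 1e-9)
  expect_true(counts[2] <= counts[3] + 1e-9)
})
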