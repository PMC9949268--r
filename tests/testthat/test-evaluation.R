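mk_sig <- function(pos, chrom = "1", score = seq_along(pos))
  data.frame(variant_id = sprintf("s%d", seq_along(pos)),
             chrom = rep(chrom, length.out = length(pos)),
             pos = as.integer(pos), score = score, stringsAsFactors = FALSE)

test_that("locus calling merges at the boundary and matches transitive closure", {
  one <- call_loci(mk_sig(500))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 500); expect_equal(one$end, 500)

  # exactly merge_bp apart joins; one bp more splits
  expect_equal(nrow(call_loci(mk_sig(c(1000, 251000)))), 1)
  expect_equal(nrow(call_loci(mk_sig(c(1000, 251001)))), 2)

  # 200 random positions vs brute-force transitive closure
  set.seed(7)
  pos <- sort(sample.int(3e7, 200))
  got <- call_loci(mk_sig(pos))
  # union-find oracle
  grp <- seq_along(pos)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (abs(pos[i] - pos[j]) <= 250000) grp[find(i)] <- find(j)
  }
  roots <- vapply(seq_along(pos), find, integer(1))
  oracle <- t(vapply(split(pos, roots), range, numeric(2)))
  oracle <- oracle[order(oracle[, 1]), , drop = FALSE]
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, unname(oracle[, 1]))
  expect_equal(got$end, unname(oracle[, 2]))

  # index variant is the top-scoring member
  l <- call_loci(mk_sig(c(100, 200, 300), score = c(1, 9, 2)))
  expect_equal(l$index_variant, "s2")
  expect_equal(nrow(call_loci(mk_sig(integer(0)))), 0)
})

test_that("locus matching follows the all-pairs overlap oracle", {
  a <- call_loci(mk_sig(c(1e6, 5e6, 9e6)))
  expect_true(all(match_loci(a, a)))
  b <- a; b$chrom <- "2"
  expect_false(any(match_loci(a, b)))

  set.seed(8)
  la <- call_loci(mk_sig(sort(sample.int(2e7, 40))))
  lb <- call_loci(mk_sig(sort(sample.int(2e7, 25))))
  got <- match_loci(la, lb, slack_bp = 250000)
  brute <- vapply(seq_len(nrow(la)), function(i)
    any(vapply(seq_len(nrow(lb)), function(j)
      la$chrom[i] == lb$chrom[j] &&
        la$start[i] - 250000 <= lb$end[j] &&
        la$end[i] + 250000 >= lb$start[j], logical(1))), logical(1))
  expect_equal(got, brute)
})

test_that("enhanced variants are predicted-significant but input-missed", {
  set.seed(9)
  n <- 50
  stats <- toy_stats(10^-runif(n, 0, 10), pos = seq_len(n) * 1e6,
                     id = sprintf("v%02d", 1:n))
  pred <- setNames(runif(n), stats$variant_id)
  pred[1] <- 0.9; stats$p_value[1] <- 1e-9   # already significant
  pred[2] <- 0.6; stats$p_value[2] <- 1e-5   # enhanced at 0.5
  enh <- find_enhanced(pred, stats)
  expect_false("v01" %in% enh$enhanced_variants$variant_id)
  expect_true("v02" %in% enh$enhanced_variants$variant_id)
  # manual two-condition filter
  manual <- stats$variant_id[pred >= 0.5 & stats$p_value >= 5e-8]
  expect_setequal(enh$enhanced_variants$variant_id, manual)
  # disjoint from the input-significant set by construction
  expect_length(intersect(enh$enhanced_variants$variant_id,
                          stats$variant_id[stats$p_value < 5e-8]), 0)
  # enhanced loci contain no input-significant member
  isig <- stats$variant_id[stats$p_value < 5e-8]
  for (m in attr(enh$enhanced_loci, "members"))
    expect_length(intersect(m, isig), 0)
  # anti-enhanced loci: input-significant, all members below threshold
  for (m in attr(enh$anti_enhanced_loci, "members"))
    expect_true(all(pred[m] < 0.5))
})

test_that("variant metrics: printed F1 formula, perfect and random predictors", {
  # TP=1, FP=1, FN=1 -> F1 = 1/(1+1) = 0.5
  vm <- variant_metrics(c(0.9, 0.8, 0.1), c(1, 0, 1))
  expect_equal(vm$tp, 1); expect_equal(vm$fp, 1); expect_equal(vm$fn, 1)
  expect_equal(vm$f1, 0.5)
  expect_equal(vm$tpr, 0.5)

  perfect <- variant_metrics(c(0.99, 0.95, 0.01, 0.02), c(1, 1, 0, 0))
  expect_equal(perfect$tpr, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$auroc, 1)

  set.seed(10)
  scores <- runif(500); truth <- rbinom(500, 1, 0.3)
  vm2 <- variant_metrics(scores, truth)
  expect_equal(vm2$auroc, auroc_concordance(scores, truth), tolerance = 1e-12)
  # ROC is monotone non-decreasing
  expect_true(all(diff(vm2$roc$tpr) >= 0))
  expect_true(all(diff(vm2$roc$fpr) >= 0))
  # one-class truth: curves reported missing
  expect_true(is.na(variant_metrics(scores, rep(1, 500))$auroc))
})

test_that("variant AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- runif(300); truth <- rbinom(300, 1, 0.4)
  vm <- variant_metrics(scores, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(vm$auroc, ref, tolerance = 1e-10)
})

test_that("locus metrics count matched/unmatched loci correctly", {
  truth <- call_loci(mk_sig(c(1e6, 5e6, 9e6, 13e6, 17e6)))
  same <- locus_metrics(truth, truth)
  expect_equal(same$tpr, 1); expect_equal(same$f1, 1)
  none <- locus_metrics(call_loci(mk_sig(integer(0))), truth)
  expect_equal(none$tpr, 0)
  # toy with known overlaps: predicted hits loci 1 and 3 only, plus 1 FP
  pred <- call_loci(mk_sig(c(1e6 + 1e5, 9e6 - 2e5, 25e6)))
  lm <- locus_metrics(pred, truth)
  expect_equal(lm$tp, 2); expect_equal(lm$fn, 3); expect_equal(lm$fp, 1)
  expect_equal(lm$tpr, 2 / 5)
  expect_equal(lm$f1, 2 / (2 + 0.5 * (1 + 3)))
  # counts partition the truth set
  expect_equal(lm$tp + lm$fn, nrow(truth))
})

test_that("threshold sweep is the prescribed grid and non-increasing", {
  set.seed(12)
  n <- 200
  stats <- toy_stats(10^-runif(n, 0, 12), pos = seq_len(n) * 4e5,
                     id = sprintf("t%03d", 1:n))
  pred <- setNames(runif(n), stats$variant_id)
  sw <- threshold_sweep(pred, stats)
  expect_equal(sw$threshold, seq(0.5, 0.95, by = 0.05))
  expect_equal(nrow(sw), 10)
  expect_true(all(diff(sw$n_enhanced_loci) <= 0))
  expect_true(all(diff(sw$n_enhanced_variants) <= 0))
  # per-threshold counts match independent recomputation
  for (th in c(0.5, 0.7, 0.95)) {
    manual <- sum(pred >= th & stats$p_value >= 5e-8)
    expect_equal(sw$n_enhanced_variants[sw$threshold == th], manual)
  }
})

test_that("validation binning reports per-bin validated proportions", {
  loci <- call_loci(mk_sig(c(1e6, 5e6, 9e6, 13e6),
                           score = c(0.55, 0.62, 0.78, 0.97)))
  # all validated
  vb <- validation_binning(loci, list(loci))
  nz <- vb$bins$n_loci > 0
  expect_true(all(vb$bins$prop_validated[nz] == 1))
  expect_equal(sum(vb$bins$n_loci), 4)
  # no validation overlap
  far <- call_loci(mk_sig(5e7, chrom = "9"))
  vb0 <- validation_binning(loci, list(far))
  expect_true(all(vb0$bins$prop_validated[vb0$bins$n_loci > 0] == 0))
  expect_equal(vb0$n_studies_validating, rep(0L, 4))
})

test_that("higher-probability loci validate more often in a planted simulation", {
  rhos <- numeric(5)
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 60
    prob <- runif(n, 0.5, 1)
    pos <- seq_len(n) * 2e6
    loci <- call_loci(mk_sig(pos, score = prob))
    # a locus is truly causal with probability increasing in prob
    causal <- rbinom(n, 1, (prob - 0.5) * 2 * 0.9 + 0.05) == 1
    val <- call_loci(mk_sig(pos[causal][order(pos[causal])]))
    vb <- validation_binning(loci, list(val))
    ok <- vb$bins$n_loci > 0
    rhos[s] <- suppressWarnings(
      cor(vb$bins$bin_lo[ok], vb$bins$prop_validated[ok], method = "spearman"))
  }
  expect_gt(median(rhos, na.rm = TRUE), 0)
})
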