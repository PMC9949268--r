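test_that("interval overlap uses BED half-open convention", {
  variants <- data.frame(chrom = "1", pos = c(99L, 100L, 101L, 150L, 200L, 201L))
  track <- interval_annotation("t", "1", c(99, 100), c(100, 200))
  # [99,100) holds 1-based pos 100; [100,200) holds 101..200
  expect_equal(overlap_indicator(variants, track), c(0L, 1L, 1L, 1L, 1L, 0L))
  # unknown chromosome: indicator 0 with one aggregated warning
  v2 <- data.frame(chrom = c("1", "chr9"), pos = c(100L, 5L))
  expect_warning(ind <- overlap_indicator(v2, track), "chr9")
  expect_equal(ind, c(1L, 0L))
})

test_that("overlap indicator matches a brute-force all-pairs scan", {
  set.seed(21)
  n <- 1000; m <- 50
  variants <- data.frame(chrom = sample(c("1", "2"), n, TRUE),
                         pos = sample.int(100000, n))
  st <- sample.int(100000, m)
  track <- interval_annotation("r", sample(c("1", "2"), m, TRUE), st - 1,
                               st - 1 + sample.int(3000, m))
  got <- overlap_indicator(variants, track)
  brute <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (variants$chrom[i] == track$intervals$chrom[j] &&
        track$intervals$start[j] < variants$pos[i] &&
        variants$pos[i] <= track$intervals$end[j]) brute[i] <- 1L
  }
  expect_equal(got, brute)
})

test_that("score lookup honours fill policies", {
  track <- setNames(c(3.2, -1, 0.5, 2, 7), paste0("v", 1:5))
  v <- data.frame(variant_id = c("v1", "vX"), chrom = "1", pos = c(1L, 2L))
  expect_equal(as.numeric(score_lookup(v, track, fill = "zero")), c(3.2, 0))
  med <- score_lookup(v, track, fill = "median")
  expect_equal(as.numeric(med), c(3.2, median(track)))
  expect_equal(attr(med, "n_filled"), 1L)

  set.seed(3)
  big <- setNames(rnorm(80), paste0("s", 1:80))
  vv <- data.frame(variant_id = c(paste0("s", 1:80), paste0("x", 1:20)),
                   chrom = "1", pos = 1:100)
  filled <- score_lookup(vv, big, fill = "median")
  expect_equal(as.numeric(filled)[81:100], rep(median(big), 20))
})

test_that("eQTL filter is a strict-threshold union with set semantics", {
  eqtl <- data.frame(
    variant_id = c("a", "a", "b", "c", "d", "e", "e", "f"),
    gene = paste0("g", 1:8),
    p = c(1e-7, 1e-3, 1e-6, 9.99e-7, 1e-8, 5e-7, 2e-9, 0.2),
    stringsAsFactors = FALSE)
  got <- filter_eqtls(eqtl)
  # p = 1e-6 exactly is excluded (strict <); duplicates appear once
  expect_false("b" %in% got)
  expect_setequal(got, c("a", "c", "d", "e"))
  expect_equal(length(filter_eqtls(eqtl)), 4)
})

test_that("Jaccard index: closed forms, symmetry, fragmentation invariance", {
  a <- interval_annotation("a", "1", 0, 100)
  b <- interval_annotation("b", "1", 50, 150)
  dis <- interval_annotation("d", "1", 1000, 1100)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, dis), 0)
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(b, a), jaccard_index(a, b))
  # splitting an interval changes nothing
  a_frag <- interval_annotation("a2", "1", c(0, 40), c(40, 100))
  expect_equal(jaccard_index(a_frag, b), 1 / 3)
  expect_equal(jaccard_index(a_frag, a), 1)
  # empty union
  e <- interval_annotation("e", character(), numeric(), numeric())
  expect_equal(jaccard_index(e, e), 0)
})

test_that("annotation clustering recovers planted structure deterministically", {
  mk <- function(name, starts) interval_annotation(name, "1", starts, starts + 100)
  # identity cut: every track its own meta-annotation
  tr <- list(mk("x", 0), mk("y", 5000), mk("z", 10000))
  out <- cluster_annotations(tr, n_groups = 3)
  expect_equal(length(out), 3)
  got_spans <- lapply(out, function(t) t$intervals$start)
  expect_setequal(unlist(got_spans), c(0, 5000, 10000))

  # two identical + one disjoint, k = 2: the identical pair merges
  tr2 <- list(mk("a", 0), mk("b", 0), mk("c", 99000))
  out2 <- cluster_annotations(tr2, n_groups = 2)
  members <- lapply(out2, attr, "members")
  expect_true(any(vapply(members, function(m) setequal(m, c("a", "b")), logical(1))))

  # planted 2-block structure vs exhaustive best-2-partition oracle
  blockA <- lapply(1:3, function(i) mk(paste0("A", i), c(0, 300) + (i - 1) * 10))
  blockB <- lapply(1:3, function(i) mk(paste0("B", i), c(50000, 60000) + (i - 1) * 10))
  tracks <- c(blockA, blockB)
  out3 <- cluster_annotations(tracks, n_groups = 2)
  got <- lapply(out3, attr, "members")

  nms <- vapply(tracks, `[[`, character(1), "name")
  J <- outer(seq_along(tracks), seq_along(tracks),
             Vectorize(function(i, j) jaccard_index(tracks[[i]], tracks[[j]])))
  best <- NULL; best_score <- -Inf
  for (code in 1:(2^(length(tracks) - 1) - 1)) {
    side <- c(0, as.integer(intToBits(code))[1:(length(tracks) - 1)])
    if (length(unique(side)) < 2) next
    score <- mean(c(J[side == 0, side == 0][upper.tri(diag(sum(side == 0)))],
                    J[side == 1, side == 1][upper.tri(diag(sum(side == 1)))]))
    if (score > best_score) { best_score <- score; best <- side }
  }
  oracle <- list(nms[best == 0], nms[best == 1])
  expect_true(setequal(got[[1]], oracle[[1]]) || setequal(got[[1]], oracle[[2]]))

  # invariant to input order
  out4 <- cluster_annotations(rev(tracks), n_groups = 2)
  expect_equal(lapply(out4, attr, "members"), got)

  expect_error(cluster_annotations(tr, n_groups = 5), "exceeds")
})

test_that("feature assembly is cell-wise consistent with single operations", {
  stats <- toy_stats(c(5e-8, 1e-12, 0.5, 1e-300, 0.03,
                       0.2, 1e-9, 0.9, 0.04, 0.6))
  panel <- toy_panel(n_ind = 40, m = 10, seed = 13)
  ld <- ld_features(panel, known = stats$variant_id[stats$p_value < 5e-8])
  tracks <- list(t1 = interval_annotation("t1", "1", 15000, 45000),
                 t2 = interval_annotation("t2", "1", 0, 5000))
  scores <- list(sc = setNames(seq(0.1, 1, by = 0.1), stats$variant_id))
  eq <- c("v2", "v7")
  X <- assemble_features(stats, ld, tracks, scores, eq)

  expect_equal(colnames(X), c("neglog10_p", "odds_ratio", "maf",
                              "ld_score_overall", "ld_score_known",
                              "eqtl", "sc", "t1", "t2"))
  expect_equal(X["v1", "neglog10_p"], -log10(5e-8))
  expect_equal(unname(X[, "odds_ratio"]), stats$odds_ratio)
  for (v in c("v1", "v4", "v9")) {
    expect_equal(X[v, "maf"], compute_maf(panel, v))
    expect_equal(X[v, "ld_score_overall"], ld$ld_score_overall[ld$variant_id == v])
    expect_equal(X[v, "t1"],
                 as.numeric(overlap_indicator(stats[stats$variant_id == v, ],
                                              tracks$t1)))
  }
  expect_equal(unname(X[, "eqtl"]), as.numeric(stats$variant_id %in% eq))
  expect_equal(unname(X[, "sc"]), as.numeric(scores$sc))
  expect_true(all(is.finite(X)))
})

test_that("-log10 p is capped so underflowed p-values stay finite", {
  stats <- toy_stats(c(1e-330, 0.5))
  stats$p_value[1] <- 1e-330   # would be -Inf after log10 without the cap
  panel <- toy_panel(n_ind = 10, m = 2)
  ld <- ld_features(panel)
  X <- assemble_features(stats, ld)
  expect_equal(X["v1", "neglog10_p"], 320)
  expect_error(assemble_features(stats, ld, schema = c("neglog10_p", "nope")),
               "not resolvable")
})
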