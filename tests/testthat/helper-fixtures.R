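# Shared fixtures: tiny panels, toy summary statistics, and a lazily built
# cache of full-size benchmark runs reused across test files.

# deterministic toy panel: m variants, n individuals, positions 10kb apart
toy_panel <- function(n_ind = 10, m = 3, seed = 42, chrom = "1",
                      spacing = 10000L, maf = 0.3) {
  geno <- withr::with_seed(seed,
    matrix(rbinom(n_ind * m, 2, maf), n_ind, m))
  map <- data.frame(variant_id = paste0("v", seq_len(m)), chrom = chrom,
                    pos = seq_len(m) * spacing, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  genotype_panel(geno, map)
}

toy_stats <- function(p, chrom = "1", pos = seq_along(p) * 10000L,
                      or = rep(1.1, length(p)),
                      id = paste0("v", seq_along(p))) {
  out <- data.frame(variant_id = id, chrom = chrom, pos = as.integer(pos),
                    allele_effect = "G", allele_other = "A",
                    odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  attr(out, "key") <- variant_key(out$chrom, out$pos, out$allele_effect,
                                  out$allele_other)
  out
}

write_tsv_text <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# --- cached full-size benchmark runs (built once, reused by the acceptance
# tests for enhancement, threshold sweep, null safety and transfer) ---------
.bench_cache <- new.env(parent = emptyenv())

acc_run <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.bench_cache[[key]])) {
    bench <- make_benchmark(sim_config(seed = seed))
    .bench_cache[[paste0("bench", seed)]] <- bench
    .bench_cache[[key]] <- run_enhancement(bench)
  }
  .bench_cache[[key]]
}

acc_bench <- function(seed) {
  invisible(acc_run(seed))
  .bench_cache[[paste0("bench", seed)]]
}

acc_null_run <- function(seed) {
  key <- paste0("null", seed)
  if (is.null(.bench_cache[[key]])) {
    bench <- make_benchmark(sim_config(effect_sd = 0, seed = seed))
    .bench_cache[[key]] <- run_enhancement(bench)
  }
  .bench_cache[[key]]
}

# independent AUROC oracle: concordance over all positive/negative pairs
auroc_concordance <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (s in pos) tot <- tot + sum(s > neg) + 0.5 * sum(s == neg)
  tot / (length(pos) * length(neg))
}
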