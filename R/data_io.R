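# Reading and harmonizing GWAS summary statistics, reference panels and
# results tables. Internal conventions: positions are 1-based; odds ratios are
# stored (beta = log(OR) on demand); a variant is keyed by chromosome,
# position and its unordered allele pair.

#' Canonical variant key
#'
#' Builds a strand-naive but allele-aware key: chromosome, position and the
#' *unordered* allele pair. Two records with swapped allele labels receive the
#' same key; A/T and C/G (palindromic) variants are matched by position and
#' allele pair without any strand flipping.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param a1,a2 character vectors, the two alleles (order irrelevant).
#' @return character vector of keys, `"chrom:pos:min(a1,a2):max(a1,a2)"`.
#' @export
variant_key <- function(chrom, pos, a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  lo <- ifelse(a1 <= a2, a1, a2)
  hi <- ifelse(a1 <= a2, a2, a1)
  paste(chrom, pos, lo, hi, sep = ":")
}

#' Default column dialect for summary-statistics files
#'
#' Maps the logical fields of a summary-statistics table to the column names
#' used in a file. The default matches the common PLINK-style header
#' (`CHR BP SNP A1 A2 OR P [SE]`). A file may provide `beta` instead of
#' `odds_ratio`; the odds ratio is then `exp(beta)`.
#'
#' @param ... named overrides, e.g. `p_value = "PVAL"`.
#' @return named list mapping logical names to file column names.
#' @export
sumstats_dialect <- function(...) {
  d <- list(chrom = "CHR", pos = "BP", variant_id = "SNP",
            allele_effect = "A1", allele_other = "A2",
            odds_ratio = "OR", beta = "BETA", p_value = "P", se = "SE")
  modifyList(d, list(...))
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-separated summary-statistics file with a header into
#' the package's internal table. Rows with unparsable or out-of-range p-values
#' or odds ratios are dropped and counted in the attached skip report;
#' duplicated variant keys are dropped (first kept) with a warning.
#'
#' @param path file path.
#' @param dialect a column-name map from [sumstats_dialect()], or the path of a
#'   YAML file holding one.
#' @return a `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, `odds_ratio`, `p_value` (and `se` when
#'   present), plus attributes `skip_report` (named counts of dropped rows)
#'   and `key` (the variant keys).
#' @export
read_summary_stats <- function(path, dialect = sumstats_dialect()) {
  if (is.character(dialect) && length(dialect) == 1L)
    dialect <- modifyList(sumstats_dialect(), yaml::read_yaml(dialect))
  if (!file.exists(path)) stop("summary statistics file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("summary statistics file is empty: ", path)

  need <- c("chrom", "pos", "variant_id", "allele_effect", "allele_other", "p_value")
  for (f in need) {
    col <- dialect[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop("required column '", f, "' (file column '", col,
           "') missing from ", path)
  }
  has_or   <- !is.null(dialect$odds_ratio) && dialect$odds_ratio %in% names(raw)
  has_beta <- !is.null(dialect$beta) && dialect$beta %in% names(raw)
  if (!has_or && !has_beta)
    stop("need an effect-size column: '", dialect$odds_ratio, "' (odds ratio) or '",
         dialect$beta, "' (beta) in ", path)

  out <- data.frame(
    variant_id    = raw[[dialect$variant_id]],
    chrom         = as.character(raw[[dialect$chrom]]),
    pos           = suppressWarnings(as.integer(raw[[dialect$pos]])),
    allele_effect = toupper(raw[[dialect$allele_effect]]),
    allele_other  = toupper(raw[[dialect$allele_other]]),
    stringsAsFactors = FALSE
  )
  if (has_or) {
    out$odds_ratio <- suppressWarnings(as.numeric(raw[[dialect$odds_ratio]]))
  } else {
    out$odds_ratio <- exp(suppressWarnings(as.numeric(raw[[dialect$beta]])))
  }
  out$p_value <- suppressWarnings(as.numeric(raw[[dialect$p_value]]))
  if (!is.null(dialect$se) && dialect$se %in% names(raw))
    out$se <- suppressWarnings(as.numeric(raw[[dialect$se]]))

  bad_p  <- !is.finite(out$p_value) | out$p_value <= 0 | out$p_value > 1
  bad_or <- !is.finite(out$odds_ratio) | out$odds_ratio <= 0
  bad_pos <- is.na(out$pos) | out$pos < 1
  keep <- !(bad_p | bad_or | bad_pos)
  skip <- c(bad_p = sum(bad_p), bad_effect = sum(bad_or & !bad_p),
            bad_pos = sum(bad_pos & !bad_p & !bad_or))
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no parsable variants in ", path)

  key <- variant_key(out$chrom, out$pos, out$allele_effect, out$allele_other)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicated variant key(s) dropped (first occurrence kept)")
    out <- out[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  skip <- c(skip, duplicated = sum(dup))
  rownames(out) <- NULL
  attr(out, "skip_report") <- skip
  attr(out, "key") <- key
  out
}

sumstats_key <- function(stats) {
  k <- attr(stats, "key", exact = TRUE)
  if (is.null(k) || length(k) != nrow(stats))
    k <- variant_key(stats$chrom, stats$pos, stats$allele_effect, stats$allele_other)
  k
}

#' Harmonize summary statistics against a reference panel
#'
#' Intersects a summary-statistics table with a genotype panel by variant key.
#' Variants absent from the panel or whose allele pair disagrees with the
#' panel's are dropped (reported). When the effect allele equals the panel's
#' reference (non-ALT) allele, the odds ratio is inverted (`OR -> 1/OR`) and
#' the allele columns swapped, so all retained effects refer to the panel's
#' alternate allele. The operation is idempotent.
#'
#' @param stats table from [read_summary_stats()].
#' @param panel a [genotype_panel()].
#' @return the harmonized subset of `stats`, with attribute `harmonize_report`
#'   (a `data.frame` of dropped variants and reasons) and refreshed keys.
#' @export
harmonize <- function(stats, panel) {
  key_s <- sumstats_key(stats)
  key_p <- variant_key(panel$map$chrom, panel$map$pos, panel$map$ref, panel$map$alt)
  idx <- match(key_s, key_p)
  absent <- is.na(idx)

  # allele-pair agreement is implied by key match; orient effects to ALT
  flip <- rep(FALSE, nrow(stats))
  ok <- which(!absent)
  flip[ok] <- stats$allele_effect[ok] != panel$map$alt[idx[ok]]

  dropped <- data.frame(variant_id = stats$variant_id[absent],
                        reason = rep("absent_or_allele_mismatch", sum(absent)),
                        stringsAsFactors = FALSE)
  out <- stats[!absent, , drop = FALSE]
  fl <- flip[!absent]
  if (any(fl)) {
    out$odds_ratio[fl] <- 1 / out$odds_ratio[fl]
    tmp <- out$allele_effect[fl]
    out$allele_effect[fl] <- out$allele_other[fl]
    out$allele_other[fl] <- tmp
  }
  if (nrow(out) == 0L)
    stop("harmonize: zero overlapping variants between summary statistics and panel ",
         "(check genome build / chromosome naming)")
  rownames(out) <- NULL
  attr(out, "key") <- key_s[!absent]
  attr(out, "skip_report") <- attr(stats, "skip_report", exact = TRUE)
  attr(out, "harmonize_report") <- dropped
  out
}

#' Write (and read back) an enhanced-results table
#'
#' Writes the per-variant output of an enhancement run as TSV with a stable
#' column order: `variant_id`, `chrom`, `pos`, `input_p`, `pred_prob`,
#' `input_significant`, `enhanced`. The file round-trips losslessly through
#' [read_enhanced_results()].
#'
#' @param table `data.frame` holding (at least) the columns above;
#'   `pred_prob` must lie in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enhanced_results <- function(table, path) {
  cols <- c("variant_id", "chrom", "pos", "input_p", "pred_prob",
            "input_significant", "enhanced")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(table) && (any(table$pred_prob < 0) || any(table$pred_prob > 1)))
    stop("pred_prob outside [0, 1]")
  out <- table[, cols, drop = FALSE]
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_enhanced_results
#' @export
read_enhanced_results <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(variant_id = "character", chrom = "character",
                            pos = "integer", input_p = "numeric",
                            pred_prob = "numeric", input_significant = "logical",
                            enhanced = "logical"))
}
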