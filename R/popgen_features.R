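# MAF and windowed LD scores from a reference panel.
#
# LD score conventions: r^2 is the squared Pearson correlation of allele
# counts across individuals (pairwise-complete when genotypes are missing).
# The overall LD score sums r^2 with every panel variant within `window_bp`
# on the same chromosome and, by the usual LD-score convention, includes the
# self term (so its floor is 1); `include_self = FALSE` drops it. The
# known-variant LD score restricts the sum to a supplied set of variants
# (the input study's genome-wide-significant ones), the self term counting
# only when the target itself belongs to the set. Monomorphic variants have
# undefined r^2 and contribute 0.

panel_index <- function(panel, id) {
  i <- match(id, panel$map$variant_id)
  if (any(is.na(i))) stop("variant(s) not in panel: ",
                          paste(id[is.na(i)], collapse = ", "))
  i
}

#' Minor allele frequency of a panel variant
#'
#' `min(f, 1 - f)` where `f` is the alternate-allele frequency over
#' non-missing allele counts.
#'
#' @param panel a [genotype_panel()].
#' @param id variant id(s) present in the panel.
#' @return numeric vector in `[0, 0.5]`.
#' @export
compute_maf <- function(panel, id = panel$map$variant_id) {
  g <- panel$geno[, panel_index(panel, id), drop = FALSE]
  n_ok <- colSums(!is.na(g))
  if (any(n_ok == 0)) stop("MAF undefined: all genotypes missing for ",
                           paste(id[n_ok == 0], collapse = ", "))
  f <- colSums(g, na.rm = TRUE) / (2 * n_ok)
  unname(pmin(f, 1 - f))
}

#' Pairwise LD r-squared between two panel variants
#'
#' Squared Pearson correlation of the two allele-count vectors over
#' individuals with both genotypes observed. Undefined (monomorphic) pairs
#' return 0 with a message, matching their zero contribution to LD scores.
#'
#' @param panel a [genotype_panel()].
#' @param i,j variant ids.
#' @return numeric in `[0, 1]`.
#' @export
pairwise_r2 <- function(panel, i, j) {
  gi <- panel$geno[, panel_index(panel, i)]
  gj <- panel$geno[, panel_index(panel, j)]
  ok <- !is.na(gi) & !is.na(gj)
  if (sd(gi[ok]) == 0 || sd(gj[ok]) == 0) {
    message("pairwise_r2: monomorphic variant, r^2 undefined; using 0")
    return(0)
  }
  unname(cor(gi[ok], gj[ok])^2)
}

window_ids <- function(panel, target, window_bp) {
  ti <- panel_index(panel, target)
  same <- panel$map$chrom == panel$map$chrom[ti] &
    abs(panel$map$pos - panel$map$pos[ti]) <= window_bp
  panel$map$variant_id[same]
}

#' Overall LD score of a target variant
#'
#' Sum of r-squared between the target and every panel variant within
#' `window_bp` on the same chromosome; with `include_self = TRUE` (default)
#' the self term contributes 1, so the score's floor is 1.
#'
#' @param panel a [genotype_panel()].
#' @param target variant id.
#' @param window_bp window half-width in bp (default 1 Mb).
#' @param include_self logical; include the target's own r^2 = 1 term.
#' @return numeric LD score.
#' @export
ld_score_overall <- function(panel, target, window_bp = 1e6, include_self = TRUE) {
  ids <- setdiff(window_ids(panel, target, window_bp), target)
  s <- if (include_self) 1 else 0
  for (v in ids) s <- s + suppressMessages(pairwise_r2(panel, target, v))
  s
}

#' LD score with known (input-significant) variants
#'
#' Like [ld_score_overall()] but summing only over pairs whose partner lies
#' in `known` — the set of variants genome-wide significant in the input
#' study — within the same window. The self term counts iff the target is
#' itself in `known`.
#'
#' @inheritParams ld_score_overall
#' @param known character vector of variant ids (intersected with the panel).
#' @return numeric LD score (possibly 0).
#' @export
ld_score_known <- function(panel, target, known, window_bp = 1e6,
                           include_self = TRUE) {
  known <- intersect(known, panel$map$variant_id)
  ids <- intersect(setdiff(window_ids(panel, target, window_bp), target), known)
  s <- if (include_self && target %in% known) 1 else 0
  for (v in ids) s <- s + suppressMessages(pairwise_r2(panel, target, v))
  s
}

#' MAF and both LD scores for every panel variant
#'
#' Vectorized equivalent of [compute_maf()], [ld_score_overall()] and
#' [ld_score_known()] over the whole panel. Variants are processed per
#' chromosome in maximal runs separated by gaps larger than `window_bp`
#' (no cross-run pair can fall inside a window); within a run the full
#' correlation matrix over individuals is formed with BLAS and masked by the
#' window.
#'
#' @param panel a [genotype_panel()].
#' @param known character vector of input-significant variant ids.
#' @param window_bp window half-width in bp (default 1 Mb).
#' @param include_self logical, self term in the overall score (default TRUE).
#' @return `data.frame` with columns `variant_id`, `maf`, `ld_score_overall`,
#'   `ld_score_known`, in panel order.
#' @export
ld_features <- function(panel, known = character(), window_bp = 1e6,
                        include_self = TRUE) {
  m <- ncol(panel$geno)
  maf <- compute_maf(panel)
  ov <- numeric(m); kn <- numeric(m)
  is_known <- panel$map$variant_id %in% known
  has_na <- anyNA(panel$geno)

  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch)
    pos <- panel$map$pos[idx]
    runs <- cumsum(c(1L, as.integer(diff(pos) > window_bp)))
    for (r in unique(runs)) {
      ri <- idx[runs == r]
      g <- panel$geno[, ri, drop = FALSE]
      if (has_na) {
        R <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
      } else {
        R <- suppressWarnings(cor(g))
      }
      R[!is.finite(R)] <- 0                        # monomorphic contribute 0
      r2 <- R * R
      p <- panel$map$pos[ri]
      mask <- abs(outer(p, p, "-")) <= window_bp
      r2m <- r2 * mask
      diag(r2m) <- 0
      ov[ri] <- rowSums(r2m) + if (include_self) 1 else 0
      kset <- is_known[ri]
      kn[ri] <- as.numeric(r2m %*% kset) + if (include_self) as.numeric(kset) else 0
    }
  }
  data.frame(variant_id = panel$map$variant_id, maf = maf,
             ld_score_overall = ov, ld_score_known = kn,
             stringsAsFactors = FALSE)
}
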