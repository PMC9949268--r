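# Interval annotations, per-variant score tracks, eQTL filtering, Jaccard
# clustering into meta-annotations, and assembly of the feature matrix.
#
# Interval tracks use BED conventions: 0-based half-open [start, end).
# A variant at 1-based position p falls in [start, end) iff start < p <= end.

#' Construct an interval annotation track
#'
#' @param name track name.
#' @param chrom,start,end vectors defining 0-based half-open intervals.
#' @return object of class `interval_annotation`.
#' @export
interval_annotation <- function(name, chrom, start, end) {
  if (length(start) && length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(start >= end)) stop("intervals must have start < end")
  structure(list(name = name,
                 intervals = data.frame(chrom = as.character(chrom),
                                        start = as.numeric(start),
                                        end = as.numeric(end),
                                        stringsAsFactors = FALSE)),
            class = "interval_annotation")
}

#' Read a BED file as an interval annotation
#'
#' @param path BED path (3+ columns, no header).
#' @param name track name (default: file name without extension).
#' @return an [interval_annotation()].
#' @export
read_bed_annotation <- function(path, name = sub("\\.bed(\\.gz)?$", "", basename(path))) {
  b <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  interval_annotation(name, b[[1]], as.numeric(b[[2]]), as.numeric(b[[3]]))
}

# per-chromosome IRanges in 1-based closed coordinates
ann_ranges <- function(track) {
  iv <- track$intervals
  split(IRanges::IRanges(start = iv$start + 1, end = iv$end), iv$chrom)
}

#' Merge a track to disjoint intervals
#'
#' Collapses overlapping or adjacent intervals; membership of any position is
#' unchanged.
#'
#' @param track an [interval_annotation()].
#' @return an [interval_annotation()] with disjoint intervals.
#' @export
merge_annotation <- function(track) {
  rl <- lapply(ann_ranges(track), IRanges::reduce)
  chrom <- rep(names(rl), vapply(rl, length, integer(1)))
  if (!length(chrom)) return(interval_annotation(track$name, character(), numeric(), numeric()))
  st <- unlist(lapply(rl, IRanges::start), use.names = FALSE) - 1
  en <- unlist(lapply(rl, IRanges::end), use.names = FALSE)
  interval_annotation(track$name, chrom, st, en)
}

#' Binary overlap indicator for variants against a track
#'
#' @param variants `data.frame` with columns `chrom` and `pos` (1-based).
#' @param track an [interval_annotation()].
#' @return integer vector of 0/1, one per variant row.
#' @export
overlap_indicator <- function(variants, track) {
  out <- integer(nrow(variants))
  rl <- ann_ranges(track)
  unknown <- setdiff(unique(variants$chrom), c(names(rl), unique(track$intervals$chrom)))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    if (is.null(rl[[ch]])) next
    q <- IRanges::IRanges(start = variants$pos[vi], width = 1)
    out[vi] <- as.integer(IRanges::countOverlaps(q, rl[[ch]]) > 0)
  }
  if (length(unknown) && nrow(track$intervals))
    warning("chromosome(s) absent from track '", track$name, "': ",
            paste(unknown, collapse = ", "), " (indicator 0)")
  out
}

#' Look up per-variant scores with a missing-value policy
#'
#' @param variants `data.frame` with `variant_id` (and `chrom`, `pos`).
#' @param track named numeric vector keyed by variant id or `"chrom:pos"`.
#' @param fill `"zero"` or `"median"` — value substituted for variants absent
#'   from the track; `"median"` uses the median of the track itself.
#' @return numeric vector with attribute `n_filled`.
#' @export
score_lookup <- function(variants, track, fill = c("zero", "median")) {
  fill <- match.arg(fill)
  v <- track[variants$variant_id]
  if (all(is.na(v)) && all(c("chrom", "pos") %in% names(variants)))
    v <- track[paste0(variants$chrom, ":", variants$pos)]
  miss <- is.na(v)
  v[miss] <- if (fill == "zero") 0 else median(track, na.rm = TRUE)
  out <- unname(as.numeric(v))
  attr(out, "n_filled") <- sum(miss)
  out
}

#' Filter an eQTL table to the significant-variant set
#'
#' Takes the union, over rows, of variants with any eQTL association at
#' nominal `p < p_max` (strict). The default threshold is 1e-6; membership in
#' the returned set becomes a binary feature.
#'
#' @param eqtl `data.frame` with columns `variant_id`, `gene`, `p`.
#' @param p_max strict upper bound on nominal p (default `1e-6`).
#' @return character vector of unique variant ids.
#' @export
filter_eqtls <- function(eqtl, p_max = 1e-6) {
  stopifnot(all(c("variant_id", "p") %in% names(eqtl)))
  unique(eqtl$variant_id[eqtl$p < p_max])
}

#' Jaccard similarity of two interval tracks
#'
#' Base-pair intersection over base-pair union after merging each track to
#' disjoint intervals; 0 when the union is empty.
#'
#' @param a,b [interval_annotation()] objects.
#' @return numeric in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  ra <- lapply(ann_ranges(merge_annotation(a)), identity)
  rb <- lapply(ann_ranges(merge_annotation(b)), identity)
  chroms <- union(names(ra), names(rb))
  inter <- 0; uni <- 0
  for (ch in chroms) {
    x <- if (is.null(ra[[ch]])) IRanges::IRanges() else ra[[ch]]
    y <- if (is.null(rb[[ch]])) IRanges::IRanges() else rb[[ch]]
    inter <- inter + sum(IRanges::width(IRanges::intersect(x, y)))
    uni <- uni + sum(IRanges::width(IRanges::union(x, y)))
  }
  if (uni == 0) 0 else inter / uni
}

#' Cluster interval tracks into meta-annotations
#'
#' Average-linkage hierarchical clustering on distance 1 − Jaccard, cut to
#' `n_groups` clusters; each meta-annotation is the base-pair union of its
#' members. Tracks are ordered lexicographically by name before clustering so
#' the result does not depend on input order.
#'
#' @param tracks list of [interval_annotation()] objects (length ≥ `n_groups`).
#' @param n_groups number of meta-annotations (default 11).
#' @return list of merged [interval_annotation()] objects named
#'   `meta01 ... metaNN` (members recorded in attribute `members`).
#' @export
cluster_annotations <- function(tracks, n_groups = 11) {
  if (length(tracks) < n_groups)
    stop("n_groups (", n_groups, ") exceeds number of tracks (", length(tracks), ")")
  nms <- vapply(tracks, `[[`, character(1), "name")
  tracks <- tracks[order(nms)]
  nms <- sort(nms)
  k <- length(tracks)
  D <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    d <- 1 - jaccard_index(tracks[[i]], tracks[[j]])
    D[i, j] <- d; D[j, i] <- d
  }
  grp <- if (n_groups == k) seq_len(k) else
    cutree(hclust(as.dist(D), method = "average"), k = n_groups)
  out <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    members <- which(grp == g)
    iv <- do.call(rbind, lapply(tracks[members], function(t) t$intervals))
    meta <- merge_annotation(interval_annotation(sprintf("meta%02d", g),
                                                 iv$chrom, iv$start, iv$end))
    attr(meta, "members") <- nms[members]
    out[[g]] <- meta
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Default 33-column feature schema
#'
#' Five statistics (−log10 p, OR, MAF, overall LD score, known-variant LD
#' score) followed by 28 annotation slots: 1 eQTL indicator, 3 pathogenic
#' scores, and 24 binary interval tracks (named by the supplied tracks).
#'
#' @param score_names names of the score tracks (default the three pathogenic
#'   scores).
#' @param indicator_names names of the binary interval tracks.
#' @return character vector of feature names.
#' @export
default_feature_schema <- function(score_names = c("phylop", "fathmm_xf", "cadd_phred"),
                                   indicator_names = character()) {
  c("neglog10_p", "odds_ratio", "maf", "ld_score_overall", "ld_score_known",
    "eqtl", score_names, indicator_names)
}

#' Assemble the per-variant feature matrix
#'
#' Builds the n x p model input in schema order: `neglog10_p` (capped),
#' `odds_ratio`, `maf`, `ld_score_overall`, `ld_score_known`, `eqtl`
#' membership, score-track columns, and one binary column per interval track.
#'
#' @param stats harmonized summary statistics ([read_summary_stats()]).
#' @param ld `data.frame` from [ld_features()] (matched by `variant_id`).
#' @param indicator_tracks named list of [interval_annotation()] objects.
#' @param score_tracks named list of score vectors (see [score_lookup()]).
#' @param eqtl_set character vector from [filter_eqtls()].
#' @param schema ordered feature names; defaults to the 33-column layout.
#' @param neglog10_cap cap on −log10 p so underflowing p-values stay finite
#'   (default 320).
#' @param score_fill fill policy for score tracks (see [score_lookup()]).
#' @return numeric matrix, rownames = variant ids, colnames = schema.
#' @export
assemble_features <- function(stats, ld, indicator_tracks = list(),
                              score_tracks = list(), eqtl_set = character(),
                              schema = NULL, neglog10_cap = 320,
                              score_fill = "zero") {
  n <- nrow(stats)
  if (is.null(schema))
    schema <- default_feature_schema(names(score_tracks), names(indicator_tracks))
  li <- match(stats$variant_id, ld$variant_id)
  if (anyNA(li)) stop("LD features missing for ",
                      sum(is.na(li)), " variant(s)")
  sources <- list(
    neglog10_p = function() pmin(-log10(stats$p_value), neglog10_cap),
    odds_ratio = function() stats$odds_ratio,
    maf = function() ld$maf[li],
    ld_score_overall = function() ld$ld_score_overall[li],
    ld_score_known = function() ld$ld_score_known[li],
    eqtl = function() as.numeric(stats$variant_id %in% eqtl_set)
  )
  X <- matrix(NA_real_, n, length(schema),
              dimnames = list(stats$variant_id, schema))
  for (f in schema) {
    col <- if (!is.null(sources[[f]])) {
      sources[[f]]()
    } else if (f %in% names(score_tracks)) {
      score_lookup(stats, score_tracks[[f]], fill = score_fill)
    } else if (f %in% names(indicator_tracks)) {
      overlap_indicator(stats, indicator_tracks[[f]])
    } else {
      stop("feature '", f, "' not resolvable; candidates: ",
           paste(c(names(sources), names(score_tracks), names(indicator_tracks)),
                 collapse = ", "))
    }
    X[, f] <- as.numeric(col)
  }
  if (any(!is.finite(X))) stop("non-finite entries in feature matrix")
  X
}
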