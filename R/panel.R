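# Genotype reference panel: the substrate for MAF and LD r^2.

#' Construct a genotype panel
#'
#' A panel holds an individuals x variants allele-count matrix (entries 0/1/2,
#' dosages in \[0,2\] permitted, `NA` for missing) and a variant map. Used to
#' compute minor allele frequencies and pairwise LD r-squared.
#'
#' @param geno numeric matrix, individuals in rows, variants in columns.
#' @param map `data.frame` with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per column of `geno`, positions non-decreasing within each
#'   chromosome.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, map) {
  stopifnot(is.matrix(geno), nrow(geno) >= 2, ncol(geno) == nrow(map))
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map)))
    stop("panel map must have columns: ", paste(need, collapse = ", "))
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop("panel positions must be non-decreasing within chromosome ", ch)
  }
  colnames(geno) <- map$variant_id
  structure(list(geno = geno, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype panel:", nrow(x$geno), "individuals x", ncol(x$geno), "variants on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read a genotype panel from a VCF file
#'
#' Parses GT fields into allele counts (phase ignored). Variants with more
#' than `max_missing` missing genotypes are excluded from the panel at load
#' and reported via a message.
#'
#' @param path VCF path (optionally bgzipped).
#' @param max_missing maximum tolerated per-variant missingness (default 0.1).
#' @return a [genotype_panel()].
#' @export
read_panel_vcf <- function(path, max_missing = 0.1) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles in GT strings like 0/1, 1|1, ./.
  alt_count <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(a, function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (all(is.na(x))) NA_real_ else sum(x > 0, na.rm = TRUE)
    }, numeric(1))
  }
  geno <- t(apply(gt, 1, alt_count))          # variants x individuals
  geno <- t(geno)                             # individuals x variants
  map <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  miss <- colMeans(is.na(geno))
  drop <- miss > max_missing
  if (any(drop)) {
    message(sum(drop), " variant(s) with >", max_missing * 100,
            "% missing genotypes excluded from panel")
    geno <- geno[, !drop, drop = FALSE]
    map <- map[!drop, , drop = FALSE]
  }
  ord <- order(map$chrom, map$pos)
  genotype_panel(geno[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

#' Write a genotype panel to VCF
#'
#' @param panel a [genotype_panel()]; entries must be hard calls (0/1/2).
#' @param path output path; vcfR writes gzip-compressed VCF.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  n_ind <- nrow(panel$geno)
  fix <- cbind(CHROM = panel$map$chrom, POS = as.character(panel$map$pos),
               ID = panel$map$variant_id, REF = panel$map$ref,
               ALT = panel$map$alt, QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gmat <- matrix(gt_code[as.character(t(panel$geno))],
                 nrow = ncol(panel$geno), ncol = n_ind)
  gmat[is.na(gmat)] <- "./."
  gt <- cbind(FORMAT = "GT", gmat)
  colnames(gt) <- c("FORMAT", sprintf("I%04d", seq_len(n_ind)))
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
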