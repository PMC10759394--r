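#' Build a binary per-SNP annotation from an element set
#'
#' A SNP is annotated (`a(j) = 1`) when its position falls inside at least
#' one element. Positions are 1-based; an element stored as the half-open
#' interval \[start, end) on disk covers positions `start + 1` to `end`
#' once loaded, so a SNP exactly at an element's (half-open) end coordinate
#' is outside.
#'
#' @param snps SNP table: data frame with `chrom` and `pos` (1-based), or a
#'   `GRanges` of width-1 sites.
#' @param elements `GRanges` of elements.
#' @return Integer 0/1 vector, one value per SNP.
#' @export
annotate_snps <- function(snps, elements) {
  stopifnot(is(elements, "GRanges"))
  gr <- if (is(snps, "GRanges")) snps
        else GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
  as.integer(overlapsAny(gr, elements, ignore.strand = TRUE))
}

#' Summary statistics of an annotation
#'
#' For a binary annotation over `p` SNPs: the annotated count `|a|`, the
#' annotated proportion `q = |a| / p`, and the population standard
#' deviation `SD_a = sqrt(q (1 - q))` (divide-by-n convention, as used to
#' standardize per-annotation effect sizes). Quantitative covariates get
#' their population SD.
#'
#' @param a Annotation vector (binary 0/1 or quantitative).
#' @return List with `n_annotated` (`NA` for quantitative), `p`, `prop`,
#'   and `sd`.
#' @export
annotation_summary <- function(a) {
  a <- as.numeric(a)
  p <- length(a)
  binary <- all(a %in% c(0, 1))
  list(n_annotated = if (binary) sum(a) else NA_real_,
       p = p,
       prop = if (binary) mean(a) else NA_real_,
       sd = sqrt(mean((a - mean(a))^2)))
}

#' Correlation between SNP annotations
#'
#' Two binary annotations are compared with Cramér's V, the square root of
#' `chi-squared / n` from their 2x2 contingency table (no continuity or
#' bias correction), ranging 0 (no correlation) to 1 (complete
#' correlation). A binary versus quantitative pair is compared with
#' Pearson's R.
#'
#' @param x Binary 0/1 annotation.
#' @param y Second annotation: binary (Cramér's V) or quantitative
#'   (Pearson's R).
#' @return List with `value` and `type` (`"cramer_v"` or `"pearson_r"`).
#' @export
correlate_annotations <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) .err("annotations must have equal length")
  if (any(!x %in% c(0, 1))) .err("x must be a binary 0/1 annotation")
  if (var(x) == 0) .err("correlation undefined: x is constant")
  if (var(y) == 0) .err("correlation undefined: y is constant")
  if (all(y %in% c(0, 1))) {
    chi2 <- suppressWarnings(
      chisq.test(table(factor(x, 0:1), factor(y, 0:1)),
                 correct = FALSE)$statistic)
    list(value = sqrt(as.numeric(chi2) / length(x)), type = "cramer_v")
  } else {
    list(value = cor(x, y), type = "pearson_r")
  }
}
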