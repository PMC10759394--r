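#' Overlap of fine-mapped variants with an annotation across PIP thresholds
#'
#' For each threshold `t`, compares the fraction of annotated fine-mapped
#' variants with `PIP >= t` (`f_in`) against the fraction among all
#' fine-mapped variants (`f_all`), reporting both the difference and the
#' ratio, plus a one-sided binomial enrichment P-value when `f_all` lies
#' strictly inside (0, 1). Thresholding is inclusive (`>=`). When the table
#' carries a `method` column with several fine-mapping methods, results are
#' computed per method and never merged.
#'
#' @param pips Fine-mapping table: data frame with `pip` in \[0, 1\] and
#'   optionally `method`.
#' @param annotation Binary 0/1 vector aligned to `pips` rows.
#' @param thresholds PIP thresholds in \[0, 1\].
#' @return Data frame with `method`, `threshold`, `f_in`, `f_all`, `diff`,
#'   `ratio`, and `p`.
#' @export
pip_overlap_fractions <- function(pips, annotation,
                                  thresholds = c(0, 0.1, 0.25, 0.5)) {
  a <- as.integer(annotation)
  if (length(a) != nrow(pips)) .err("annotation must align with the table")
  if (any(!a %in% c(0L, 1L))) .err("annotation must be binary 0/1")
  if (any(thresholds < 0 | thresholds > 1)) .err("thresholds must lie in [0, 1]")
  method <- if (!is.null(pips$method)) as.character(pips$method)
            else rep("all", nrow(pips))
  out <- lapply(unique(method), function(m) {
    i <- method == m
    pip <- pips$pip[i]; ai <- a[i]
    n_in <- sum(ai == 1L)
    if (n_in == 0L) .err("no annotated variants for method '%s'", m)
    do.call(rbind, lapply(thresholds, function(t) {
      k <- sum(pip[ai == 1L] >= t)
      f_in <- k / n_in
      f_all <- mean(pip >= t)
      data.frame(method = m, threshold = t, f_in = f_in, f_all = f_all,
                 diff = f_in - f_all,
                 ratio = if (f_all > 0) f_in / f_all else NA_real_,
                 p = if (f_all > 0 && f_all < 1)
                   binomial_enrichment_test(k, n_in, f_all) else NA_real_)
    }))
  })
  do.call(rbind, out)
}

#' One-sided binomial enrichment test
#'
#' Exact upper-tail probability `P(X >= k)` for
#' `X ~ Binomial(n, p0)`: the chance of observing at least `k` annotated
#' variants passing the PIP threshold if they passed at the genome-wide
#' rate `p0`.
#'
#' @param k Number of passing annotated variants (0 <= k <= n).
#' @param n Number of annotated variants.
#' @param p0 Genome-wide passing fraction, strictly inside (0, 1).
#' @return One-sided P-value.
#' @export
binomial_enrichment_test <- function(k, n, p0) {
  if (!(k >= 0 && k <= n)) .err("need 0 <= k <= n")
  if (!(p0 > 0 && p0 < 1)) .err("p0 must lie strictly inside (0, 1)")
  if (k == 0) return(1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}
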