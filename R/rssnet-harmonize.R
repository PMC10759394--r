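.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize GWAS summary statistics with a reference SNP table
#'
#' Matches GWAS rows to the reference by `snp_id` and reconciles alleles:
#' effect signs are flipped when the effect/other alleles are swapped
#' relative to the reference; alleles reported on the opposite strand are
#' complemented (and flipped if also swapped); strand-ambiguous (A/T, C/G)
#' SNPs, SNPs absent from the reference, and SNPs whose alleles cannot be
#' reconciled are dropped. The exclusion report counts each reason.
#'
#' @param gwas Data frame with `snp_id`, `a1` (effect allele), `a2`,
#'   `beta`, `se`, and optionally `z`.
#' @param reference Reference SNP table with `snp_id`, `a1`, `a2`.
#' @return List with `gwas` (aligned to the reference row order of the
#'   retained SNPs) and `report` (named integer vector of counts).
#' @export
harmonize_gwas <- function(gwas, reference) {
  for (df in list(gwas, reference))
    if (!all(c("snp_id", "a1", "a2") %in% names(df)))
      .err("both tables need snp_id, a1, a2 columns")
  g1 <- toupper(gwas$a1); g2 <- toupper(gwas$a2)
  m <- match(gwas$snp_id, reference$snp_id)
  unmatched <- is.na(m)
  ambiguous <- !unmatched & g1 == unname(.COMPLEMENT[g2])
  r1 <- toupper(reference$a1[m]); r2 <- toupper(reference$a2[m])
  c1 <- unname(.COMPLEMENT[g1]); c2 <- unname(.COMPLEMENT[g2])
  same <- !unmatched & !ambiguous & g1 == r1 & g2 == r2
  swap <- !unmatched & !ambiguous & g1 == r2 & g2 == r1
  comp <- !unmatched & !ambiguous & !same & !swap & c1 == r1 & c2 == r2
  comp_swap <- !unmatched & !ambiguous & !same & !swap & c1 == r2 & c2 == r1
  mismatch <- !unmatched & !ambiguous & !(same | swap | comp | comp_swap)
  keep <- same | swap | comp | comp_swap
  if (!any(keep)) .err("no GWAS SNPs could be matched to the reference")
  flip <- swap | comp_swap
  out <- gwas[keep, , drop = FALSE]
  sign <- ifelse(flip[keep], -1, 1)
  out$beta <- out$beta * sign
  if (!is.null(out$z)) out$z <- out$z * sign
  out$a1 <- r1[keep]; out$a2 <- r2[keep]
  # order as in the reference
  out <- out[order(m[keep]), , drop = FALSE]
  rownames(out) <- NULL
  report <- c(matched = sum(same), flipped = sum(swap),
              complemented = sum(comp), complement_flipped = sum(comp_swap),
              strand_ambiguous = sum(ambiguous),
              allele_mismatch = sum(mismatch), unmatched = sum(unmatched))
  list(gwas = out, report = report)
}
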