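#' Compute annotation-stratified LD scores from reference genotypes
#'
#' For SNP `j` and annotation `a`, the LD score is
#' `l(j, a) = sum_k r2(j, k) a(k)` over reference SNPs `k` within
#' `window_bases` of `j` on the same chromosome, with `r2` the squared
#' sample correlation of genotype columns (no small-sample adjustment).
#' Monomorphic reference SNPs are excluded with a warning. An all-ones
#' `base` annotation is appended when not supplied, so the background
#' per-SNP contribution is always estimable downstream.
#'
#' @param genotypes A [simulate_genotypes()]-style `genotypes` object used
#'   as the LD reference.
#' @param annotations Matrix (SNPs x annotations) with column names, a
#'   named list of vectors, or a single vector (labelled `"annot"`).
#' @param window_bases Window half-width in bases.
#' @return Object of class `ld_scores`: list with the score matrix
#'   `scores`, `snp_id`, the aligned annotation matrix `annot`, and the
#'   indices `kept` of retained SNPs.
#' @export
compute_ld_scores <- function(genotypes, annotations, window_bases = 1e6) {
  stopifnot(inherits(genotypes, "genotypes"))
  A <- .as_annot_matrix(annotations, ncol(genotypes$X))
  sds <- apply(genotypes$X, 2, sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sprintf("excluding %d monomorphic reference SNPs", sum(!keep)))
  X <- genotypes$X[, keep, drop = FALSE]
  pos <- genotypes$pos[keep]
  chr <- genotypes$chrom[keep]
  A <- A[keep, , drop = FALSE]
  if (!any(apply(A, 2, function(a) all(a == 1))))
    A <- cbind(A, base = 1)
  R2 <- cor(X)^2
  win <- abs(outer(pos, pos, "-")) <= window_bases &
    outer(chr, chr, "==")
  R2[!win] <- 0
  scores <- R2 %*% A
  colnames(scores) <- colnames(A)
  structure(list(scores = scores, snp_id = genotypes$snp_id[keep],
                 annot = A, kept = which(keep), window_bases = window_bases),
            class = "ld_scores")
}

.as_annot_matrix <- function(annotations, p) {
  if (is.list(annotations) && !is.data.frame(annotations))
    annotations <- do.call(cbind, annotations)
  if (is.null(dim(annotations)))
    annotations <- matrix(annotations, ncol = 1,
                          dimnames = list(NULL, "annot"))
  annotations <- as.matrix(annotations)
  if (is.null(colnames(annotations)))
    colnames(annotations) <- paste0("annot", seq_len(ncol(annotations)))
  if (nrow(annotations) != p)
    .err("annotation rows (%d) must match SNP count (%d)",
         nrow(annotations), p)
  annotations
}

#' Stratified heritability regression on GWAS summary statistics
#'
#' Regresses per-SNP chi-squared statistics `z^2` on `n * l(j, a)` across
#' annotations with a free intercept, by weighted least squares with
#' heteroskedasticity-aware weights `1 / (2 (1 + n l_base(j) / p)^2)`. The
#' coefficients are the per-SNP heritability contributions `tau` of each
#' annotation; standard errors come from a delete-block jackknife over
#' contiguous SNP blocks. Conditional analyses (a conserved-subset
#' annotation fitted jointly with the full element annotation and any
#' covariates) are expressed by the columns supplied to
#' [compute_ld_scores()].
#'
#' @param gwas GWAS summary data frame with `snp_id`, `z`, and `n`.
#' @param ld An [compute_ld_scores()] result.
#' @param n Sample size; defaults to the median of `gwas$n`.
#' @param n_blocks Number of jackknife blocks; defaults to 200, scaled down
#'   proportionally when fewer than 2,000 SNPs are available.
#' @param min_maf SNPs with a `maf` column below this are dropped
#'   (common-SNP filter); ignored when `gwas` has no `maf` column.
#' @return Object of class `sldsc_fit` with elements `tau`, `tau_se`,
#'   `intercept`, `intercept_se`, `h2`, `h2_se`, per-annotation `h2_a`,
#'   annotation summaries, and the jackknife replicate matrix.
#' @export
fit_sldsc <- function(gwas, ld, n = NULL, n_blocks = NULL, min_maf = 0.05) {
  stopifnot(inherits(ld, "ld_scores"))
  m <- match(ld$snp_id, gwas$snp_id)
  if (anyNA(m)) .err("%d LD-score SNPs missing from the GWAS", sum(is.na(m)))
  gwas <- gwas[m, , drop = FALSE]
  keep <- rep(TRUE, nrow(gwas))
  if (!is.null(gwas$maf)) keep <- gwas$maf >= min_maf
  gwas <- gwas[keep, , drop = FALSE]
  L <- ld$scores[keep, , drop = FALSE]
  A <- ld$annot[keep, , drop = FALSE]
  p <- nrow(L); K <- ncol(L)
  if (p < 2 * (K + 1)) .err("need at least twice as many SNPs as annotations")
  if (is.null(n)) n <- median(gwas$n)
  nj <- if (!is.null(gwas$n)) gwas$n else rep(n, p)
  chi2 <- gwas$z^2
  base_col <- which(apply(A, 2, function(a) all(a == 1)))[1]
  w <- 1 / (2 * (1 + nj * L[, base_col] / p)^2)
  X <- cbind(`(Intercept)` = 1, L * nj)
  qx <- qr(X * sqrt(w))
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    .err("rank-deficient design; collinear annotations: %s",
         paste(bad, collapse = ", "))
  }
  if (is.null(n_blocks))
    n_blocks <- max(2L, round(200 * min(1, p / 2000)))
  n_blocks <- min(n_blocks, p)
  blk <- as.integer(cut(seq_len(p), breaks = n_blocks, labels = FALSE))
  # accumulate weighted cross-products per jackknife block
  K1 <- ncol(X)
  xtx_b <- array(0, c(K1, K1, n_blocks))
  xty_b <- matrix(0, K1, n_blocks)
  for (b in seq_len(n_blocks)) {
    i <- which(blk == b)
    Xw <- X[i, , drop = FALSE] * w[i]
    xtx_b[, , b] <- crossprod(X[i, , drop = FALSE], Xw)
    xty_b[, b] <- crossprod(Xw, chi2[i])
  }
  xtx <- apply(xtx_b, c(1, 2), sum)
  xty <- rowSums(xty_b)
  coef_full <- solve(xtx, xty)
  jack <- matrix(NA_real_, n_blocks, K1)
  for (b in seq_len(n_blocks))
    jack[b, ] <- solve(xtx - xtx_b[, , b], xty - xty_b[, b])
  colnames(jack) <- colnames(X)
  se <- sqrt((n_blocks - 1) / n_blocks *
               colSums(sweep(jack, 2, colMeans(jack))^2))
  tau <- coef_full[-1]
  names(tau) <- colnames(L)
  csA <- colSums(A)
  crossA <- crossprod(A)  # K x K; row k gives h2_(annot k) = crossA[k,] %*% tau
  h2_rep <- jack[, -1, drop = FALSE] %*% csA
  h2 <- sum(csA * tau)
  structure(list(
    tau = tau, tau_se = setNames(se[-1], names(tau)),
    intercept = coef_full[1], intercept_se = se[1],
    h2 = h2,
    h2_se = sqrt((n_blocks - 1) / n_blocks * sum((h2_rep - mean(h2_rep))^2)),
    h2_a = setNames(as.numeric(crossA %*% tau), names(tau)),
    p = p, n = n,
    n_a = setNames(csA, names(tau)),
    sd_a = setNames(apply(A, 2, function(a) sqrt(mean((a - mean(a))^2))),
                    names(tau)),
    binary_a = setNames(apply(A, 2, function(a) all(a %in% c(0, 1))),
                        names(tau)),
    jack = jack, crossA = crossA, csA = csA, n_blocks = n_blocks
  ), class = "sldsc_fit")
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("sldsc_fit: %d SNPs, %d annotations, %d jackknife blocks\n",
              x$p, length(x$tau), x$n_blocks))
  cat(sprintf("  intercept %.3f (SE %.3f), h2 %.4f (SE %.4f)\n",
              x$intercept, x$intercept_se, x$h2, x$h2_se))
  print(data.frame(tau = x$tau, se = x$tau_se))
  invisible(x)
}

#' Heritability enrichment and standardized effect size of an annotation
#'
#' From a fitted stratified regression: the heritability enrichment
#' `(h2_a / h2) / (|a| / p)` and the standardized per-SNP effect
#' `tau* = p SD_a tau_a / h2`, each with jackknife-propagated standard
#' errors. The one-sided enrichment P-value tests whether the per-SNP
#' heritability difference `h2_a / |a| - (h2 - h2_a) / (p - |a|)` exceeds
#' zero; the one-sided `tau*` P-value tests `tau* > 0`, both by normal
#' approximation on the jackknife SE. The all-SNPs annotation has
#' enrichment exactly 1 with a zero-width difference contrast (P-value
#' `NA`).
#'
#' @param fit An [fit_sldsc()] result.
#' @param annotation Column name of the focal annotation.
#' @return List with `enrichment`, `enrichment_se`, `enrichment_p`,
#'   `tau_star`, `tau_star_se`, `tau_star_p`, `h2_a`, `h2`, `prop_snps`,
#'   `prop_h2`.
#' @export
summarize_fit <- function(fit, annotation) {
  stopifnot(inherits(fit, "sldsc_fit"))
  k <- match(annotation, names(fit$tau))
  if (is.na(k)) .err("annotation '%s' not in the fit", annotation)
  if (!fit$binary_a[k])
    .err("enrichment is defined for binary annotations only")
  na <- fit$n_a[[k]]; p <- fit$p
  if (na == 0) .err("enrichment undefined: annotation covers no SNPs")
  # per-replicate derived quantities, all linear in the tau replicates
  tau_rep <- fit$jack[, -1, drop = FALSE]
  h2_rep <- as.numeric(tau_rep %*% fit$csA)
  h2a_rep <- as.numeric(tau_rep %*% fit$crossA[k, ])
  jse <- function(x) sqrt((fit$n_blocks - 1) / fit$n_blocks *
                            sum((x - mean(x))^2))
  h2a <- fit$h2_a[[k]]
  ts <- p * fit$sd_a[[k]] / fit$h2 * fit$tau[[k]]
  ts_rep <- p * fit$sd_a[[k]] / h2_rep * tau_rep[, k]
  ts_se <- jse(ts_rep)
  if (na == p) {
    return(list(enrichment = 1, enrichment_se = 0, enrichment_p = NA_real_,
                tau_star = unname(ts), tau_star_se = ts_se,
                tau_star_p = pnorm(ts / ts_se, lower.tail = FALSE),
                h2_a = unname(h2a), h2 = fit$h2, prop_snps = 1,
                prop_h2 = 1))
  }
  enr <- (h2a / fit$h2) / (na / p)
  enr_rep <- (h2a_rep / h2_rep) / (na / p)
  diff <- h2a / na - (fit$h2 - h2a) / (p - na)
  diff_rep <- h2a_rep / na - (h2_rep - h2a_rep) / (p - na)
  diff_se <- jse(diff_rep)
  list(enrichment = unname(enr), enrichment_se = jse(enr_rep),
       enrichment_p = pnorm(diff / diff_se, lower.tail = FALSE),
       tau_star = unname(ts), tau_star_se = ts_se,
       tau_star_p = pnorm(ts / ts_se, lower.tail = FALSE),
       h2_a = unname(h2a), h2 = fit$h2,
       prop_snps = unname(na / p), prop_h2 = unname(h2a / fit$h2))
}
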