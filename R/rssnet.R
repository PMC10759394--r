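#' Annotation-informed spike-and-slab effect prior
#'
#' Each SNP effect is zero with probability `1 - pi_j` and otherwise
#' normal with variance `sigma_j^2`, where the association probability
#' `pi_j = (1 + 10^-(theta0 + a_j theta))^-1` and the slab variance
#' `sigma_j^2 = sigma0_sq + a_j sigma_sq` both increase for annotated SNPs
#' (`a_j = 1`).
#'
#' @param theta0 Baseline log10-odds (typically negative).
#' @param theta Enrichment log10-odds (>= 0).
#' @param sigma0_sq Baseline slab variance (> 0).
#' @param sigma_sq Enrichment slab variance (>= 0).
#' @param annotation Binary 0/1 vector `a_j`.
#' @return Object of class `effect_prior`: list with `pi`, `sigma2`, and
#'   the four parameters.
#' @export
effect_prior <- function(theta0, theta, sigma0_sq, sigma_sq, annotation) {
  a <- as.numeric(annotation)
  if (any(!a %in% c(0, 1))) .err("annotation must be binary 0/1")
  if (sigma0_sq <= 0) .err("sigma0_sq must be positive")
  if (sigma_sq < 0) .err("sigma_sq must be non-negative")
  if (theta < 0) .err("theta must be non-negative")
  structure(list(pi = 1 / (1 + 10^(-(theta0 + a * theta))),
                 sigma2 = sigma0_sq + a * sigma_sq,
                 theta0 = theta0, theta = theta,
                 sigma0_sq = sigma0_sq, sigma_sq = sigma_sq),
            class = "effect_prior")
}

#' Block LD structure from reference genotypes
#'
#' Computes the per-block SNP correlation matrix from a reference genotype
#' panel, shrinks it toward the identity (weight `shrink`), and floors its
#' eigenvalues at `eigen_floor` before rescaling to unit diagonal, so every
#' block matrix is positive definite.
#'
#' @param genotypes A [simulate_genotypes()]-style `genotypes` object.
#' @param shrink Shrinkage weight toward the identity in \[0, 1).
#' @param eigen_floor Eigenvalue floor applied after shrinkage.
#' @return Object of class `ld_structure`: list with `blocks` (correlation
#'   matrices), `block` assignment, and `snp_id`.
#' @export
ld_from_genotypes <- function(genotypes, shrink = 0.1, eigen_floor = 1e-8) {
  stopifnot(inherits(genotypes, "genotypes"))
  if (shrink < 0 || shrink >= 1) .err("shrink must lie in [0, 1)")
  ids <- unique(genotypes$block)
  blocks <- lapply(ids, function(b) {
    X <- genotypes$X[, genotypes$block == b, drop = FALSE]
    R <- (1 - shrink) * cor(X) + shrink * diag(ncol(X))
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < eigen_floor) {
      R <- e$vectors %*% (pmax(e$values, eigen_floor) * t(e$vectors))
      R <- stats::cov2cor(R)
    }
    R
  })
  structure(list(blocks = blocks, block = genotypes$block,
                 snp_id = genotypes$snp_id),
            class = "ld_structure")
}

#' Variational inference for one prior configuration
#'
#' Fits the fully factorized spike-and-slab variational family to the
#' summary-statistic likelihood (marginal effect estimates jointly normal
#' with mean `S R S^-1 beta` and covariance `S R S`) by coordinate ascent,
#' independently per LD block, with SNPs updated in order of decreasing
#' `|z|`. The evidence lower bound (ELBO) is non-decreasing over
#' iterations and is reported including the data-dependent constant, so it
#' approximates the log marginal likelihood of the configuration.
#'
#' @param gwas Harmonized GWAS data frame (`snp_id`, `beta`, `se`, `z`)
#'   aligned to `ld$snp_id`.
#' @param ld An [ld_from_genotypes()] result (or compatible
#'   `ld_structure`).
#' @param prior An [effect_prior()].
#' @param tol Convergence tolerance on the relative ELBO change.
#' @param max_iter Iteration cap per block; non-convergence is flagged in
#'   the result, not an error.
#' @param init Optional list with `alpha` and `mu` starting values
#'   (defaults to `alpha = pi`, `mu = 0`).
#' @param precomputed Cached result of the internal LD pre-computation;
#'   used by [fit_model()] to share work across grid points.
#' @return List with `alpha`, `mu`, `s2`, total `elbo`, per-block
#'   `elbo_trace`, and `converged` flags.
#' @export
variational_fit <- function(gwas, ld, prior, tol = 1e-8, max_iter = 500L,
                            init = NULL, precomputed = NULL) {
  stopifnot(inherits(ld, "ld_structure"), inherits(prior, "effect_prior"))
  if (!identical(as.character(gwas$snp_id), as.character(ld$snp_id)))
    .err("gwas rows must align with ld$snp_id (harmonize first)")
  p <- nrow(gwas)
  if (length(prior$pi) != p) .err("prior length must match SNP count")
  pre <- if (is.null(precomputed)) .ld_precompute(gwas, ld) else precomputed
  log_odds <- log(prior$pi) - log1p(-prior$pi)
  alpha <- if (!is.null(init$alpha)) init$alpha else prior$pi
  mu <- if (!is.null(init$mu)) init$mu else numeric(p)
  out_alpha <- numeric(p); out_mu <- numeric(p); out_s2 <- numeric(p)
  elbo <- 0; traces <- vector("list", length(pre$idx))
  converged <- logical(length(pre$idx))
  for (b in seq_along(pre$idx)) {
    i <- pre$idx[[b]]
    fit <- .vb_block(pre$Omega[[b]], pre$y[[b]],
                     prior$sigma2[i], log_odds[i],
                     order(-abs(gwas$z[i])) - 1L,
                     alpha[i], mu[i], tol, as.integer(max_iter))
    out_alpha[i] <- fit$alpha; out_mu[i] <- fit$mu; out_s2[i] <- fit$s2
    elbo <- elbo + fit$elbo + pre$const[b]
    traces[[b]] <- fit$elbo_trace + pre$const[b]
    converged[b] <- fit$converged
  }
  list(alpha = out_alpha, mu = out_mu, s2 = out_s2, elbo = elbo,
       elbo_trace = traces, converged = converged)
}

# per-block Omega = S^-1 R S^-1, y = betahat / se^2, and the ELBO constant
# -0.5 (p log 2pi + log|SRS| + betahat' (SRS)^-1 betahat); cached on the
# ld_structure so repeated grid fits reuse it
.ld_precompute <- function(gwas, ld) {
  idx <- split(seq_len(nrow(gwas)), ld$block)
  Omega <- vector("list", length(idx))
  y <- vector("list", length(idx))
  const <- numeric(length(idx))
  for (b in seq_along(idx)) {
    i <- idx[[b]]
    R <- ld$blocks[[b]]
    se <- gwas$se[i]
    Omega[[b]] <- R / tcrossprod(se)
    y[[b]] <- gwas$beta[i] / se^2
    v <- gwas$beta[i] / se
    ch <- tryCatch(chol(R), error = function(e)
      .err("LD block %d is not positive definite after regularization", b))
    u <- backsolve(ch, v, transpose = TRUE)
    logdet <- 2 * sum(log(diag(ch))) + 2 * sum(log(se))
    const[b] <- -0.5 * (length(i) * log(2 * pi) + logdet + sum(u^2))
  }
  list(idx = idx, Omega = Omega, y = y, const = const)
}

#' Hyper-parameter grid for the enrichment model
#'
#' Builds the grid of `(theta0, theta, sigma0_sq, sigma_sq)` configurations
#' over which the variational solutions are averaged. Slab variances are
#' scaled to the data through multiples of the median marginal-effect
#' standard error. Mode `"B"` (baseline, no enrichment) pins `theta = 0`
#' and `sigma_sq = 0`; modes `"N"` and `"H"` differ only in the annotation
#' they are paired with, not in the grid itself. Hyper-prior weights are
#' uniform.
#'
#' @param mode `"B"`, `"N"`, or `"H"`.
#' @param gwas GWAS data frame used to set the standard-error scale (or
#'   pass `se_scale`).
#' @param theta0,theta Grid values (log10-odds).
#' @param sigma0_mult,sigma_mult Slab SD multipliers of `se_scale`;
#'   `sigma0_sq = (sigma0_mult * se_scale)^2` and likewise for `sigma_sq`.
#' @param se_scale Standard-error scale; defaults to `median(gwas$se)`.
#' @return Data frame grid with a uniform `weight` column.
#' @export
rssnet_grid <- function(mode = c("H", "N", "B"), gwas = NULL,
                        theta0 = seq(-4, -1, length.out = 5),
                        theta = seq(0, 3, length.out = 4),
                        sigma0_mult = c(2, 4, 6, 8),
                        sigma_mult = c(0, 2, 4, 6),
                        se_scale = NULL) {
  mode <- match.arg(mode)
  if (is.null(se_scale)) {
    if (is.null(gwas)) .err("supply gwas or se_scale")
    se_scale <- median(gwas$se)
  }
  if (mode == "B") {
    theta <- 0
    sigma_mult <- 0
  }
  g <- expand.grid(theta0 = theta0, theta = theta,
                   sigma0_sq = (sigma0_mult * se_scale)^2,
                   sigma_sq = (sigma_mult * se_scale)^2,
                   KEEP.OUT.ATTRS = FALSE)
  g <- unique(g)
  g$weight <- 1 / nrow(g)
  g
}

#' Fit the enrichment model over a hyper-parameter grid
#'
#' Runs [variational_fit()] at every grid point, using the previous point's
#' solution as a warm start (`warm_start = TRUE`; additional deterministic
#' restarts can be requested, keeping the best ELBO per point). Posterior
#' quantities are model-averaged with weights proportional to the
#' hyper-prior times the exponentiated ELBO, and the log marginal
#' likelihood of the mode is approximated by the log of the
#' hyper-prior-weighted sum of exponentiated ELBOs.
#'
#' @param gwas Harmonized GWAS data frame aligned with `ld`.
#' @param ld An [ld_from_genotypes()] result.
#' @param annotation Binary 0/1 vector (ignored in mode `"B"`). Modes `"N"`
#'   and `"H"` with an all-zero annotation collapse to the baseline model
#'   (with a warning): reliable enrichment estimation needs annotated SNPs.
#' @param grid Hyper-parameter grid from [rssnet_grid()]; defaults to the
#'   mode's standard grid.
#' @param mode `"B"` baseline (no enrichment), `"N"` enrichment for all
#'   elements, `"H"` enrichment for conserved elements.
#' @param tol,max_iter Passed to [variational_fit()].
#' @param restarts Number of deterministic initializations per grid point
#'   (1 to 3).
#' @param warm_start Use the previous grid point's solution as one
#'   initialization.
#' @return Object of class `rssnet_fit`: the grid with per-point `elbo`
#'   and posterior `weight`, the per-point inclusion matrix `alpha`, the
#'   model-averaged `alpha_avg`, `logml`, `mode`, and `snp_id`.
#' @export
fit_model <- function(gwas, ld, annotation = NULL, grid = NULL,
                      mode = c("H", "N", "B"), tol = 1e-8, max_iter = 500L,
                      restarts = 1L, warm_start = TRUE) {
  mode <- match.arg(mode)
  p <- nrow(gwas)
  a <- if (mode == "B" || is.null(annotation)) numeric(p)
       else as.numeric(annotation)
  if (length(a) != p) .err("annotation length must match SNP count")
  if (mode != "B" && all(a == 0))
    warning("annotation has no SNPs; enrichment model collapses to baseline")
  if (is.null(grid)) grid <- rssnet_grid(mode, gwas)
  if (mode == "B" && any(grid$theta != 0 | grid$sigma_sq != 0))
    .err("baseline grids must have theta = 0 and sigma_sq = 0")
  restarts <- max(1L, min(3L, as.integer(restarts)))
  o <- order(grid$theta0, grid$theta, grid$sigma0_sq, grid$sigma_sq)
  grid <- grid[o, , drop = FALSE]
  G <- nrow(grid)
  alpha_mat <- matrix(NA_real_, p, G)
  elbo <- numeric(G)
  converged <- logical(G)
  prev <- NULL
  pre <- .ld_precompute(gwas, ld)
  for (g in seq_len(G)) {
    prior <- effect_prior(grid$theta0[g], grid$theta[g],
                          grid$sigma0_sq[g], grid$sigma_sq[g], a)
    inits <- list(NULL)  # alpha = pi, mu = 0
    if (warm_start && !is.null(prev)) inits <- c(inits, list(prev))
    if (restarts >= 2L)
      inits <- c(inits, list(list(
        alpha = pmin(pmax(2 * pnorm(abs(gwas$z)) - 1, 0.01), 0.99),
        mu = gwas$beta)))
    if (restarts >= 3L)
      inits <- c(inits, list(list(alpha = rep(0.5, p), mu = numeric(p))))
    best <- NULL
    for (ini in inits) {
      fit <- variational_fit(gwas, ld, prior, tol = tol,
                             max_iter = max_iter, init = ini,
                             precomputed = pre)
      if (is.null(best) || fit$elbo > best$elbo) best <- fit
    }
    alpha_mat[, g] <- best$alpha
    elbo[g] <- best$elbo
    converged[g] <- all(best$converged)
    prev <- list(alpha = best$alpha, mu = best$mu)
  }
  lw <- elbo + log(grid$weight / sum(grid$weight))
  logml <- .logsumexp(lw)
  w <- exp(lw - logml)
  grid$elbo <- elbo
  grid$post_weight <- w
  structure(list(grid = grid, alpha = alpha_mat,
                 alpha_avg = pmin(pmax(as.numeric(alpha_mat %*% w), 0), 1),
                 logml = logml, mode = mode,
                 snp_id = as.character(gwas$snp_id),
                 converged = converged),
            class = "rssnet_fit")
}

#' @export
print.rssnet_fit <- function(x, ...) {
  cat(sprintf(
    "rssnet_fit (mode %s): %d SNPs, %d grid points, log-ML approx %.2f\n",
    x$mode, length(x$snp_id), nrow(x$grid), x$logml))
  top <- x$grid[order(-x$grid$post_weight), ][1, ]
  cat(sprintf("  top point: theta0=%.2f theta=%.2f weight=%.2f\n",
              top$theta0, top$theta, top$post_weight))
  invisible(x)
}

#' Enrichment Bayes factor
#'
#' Ratio of hyper-prior-averaged marginal-likelihood approximations for the
#' enrichment configurations (`theta > 0` or `sigma_sq > 0`) of the
#' enriched fit against the no-enrichment baseline fit
#' (`theta = 0` and `sigma_sq = 0`). Computed on the log scale. If the
#' enriched grid contains no enrichment point, its full grid is used, so a
#' grid degenerate at the null gives a Bayes factor of exactly 1 against
#' the same baseline.
#'
#' @param fit_enriched,fit_baseline [fit_model()] results on identical
#'   harmonized data.
#' @return List with `bf` and `log10_bf`.
#' @export
bayes_factor <- function(fit_enriched, fit_baseline) {
  stopifnot(inherits(fit_enriched, "rssnet_fit"),
            inherits(fit_baseline, "rssnet_fit"))
  if (!identical(fit_enriched$snp_id, fit_baseline$snp_id))
    .err("fits must be computed on identical harmonized data")
  g <- fit_enriched$grid
  pts <- which(g$theta > 0 | g$sigma_sq > 0)
  if (!length(pts)) pts <- seq_len(nrow(g))
  wts <- g$weight[pts] / sum(g$weight[pts])
  num <- .logsumexp(g$elbo[pts] + log(wts))
  log_bf <- num - fit_baseline$logml
  list(bf = exp(log_bf), log10_bf = log_bf / log(10))
}

#' Posterior probability that an element harbors a trait-associated SNP
#'
#' Under the factorized variational posterior averaged over the
#' hyper-parameter grid, the probability that at least one SNP inside an
#' element is associated is `P1 = 1 - prod_j (1 - alpha_j)` over the
#' element's SNPs. Superscripts B/N/H in reports refer to the mode of the
#' fit supplying `alpha`.
#'
#' @param fit An [fit_model()] result.
#' @param elements `GRanges` of elements.
#' @param snps SNP table with `snp_id`, `chrom`, `pos` covering the fit's
#'   SNPs.
#' @return Numeric vector of P1 values, one per element.
#' @export
element_p1 <- function(fit, elements, snps) {
  stopifnot(inherits(fit, "rssnet_fit"), is(elements, "GRanges"))
  m <- match(fit$snp_id, snps$snp_id)
  if (anyNA(m)) .err("fit contains SNPs missing from the SNP table")
  gr <- GRanges(snps$chrom[m], IRanges(snps$pos[m], width = 1L))
  ov <- findOverlaps(gr, elements, ignore.strand = TRUE)
  idx <- split(queryHits(ov), factor(subjectHits(ov),
                                     levels = seq_along(elements)))
  if (any(lengths(idx) == 0L))
    .err("P1 undefined: %d element(s) contain no fitted SNP",
         sum(lengths(idx) == 0L))
  .p1_from_alpha(fit$alpha_avg, idx)
}

.p1_from_alpha <- function(alpha, idx_list) {
  vapply(idx_list, function(i) min(max(1 - prod(1 - alpha[i]), 0), 1),
         numeric(1), USE.NAMES = FALSE)
}
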