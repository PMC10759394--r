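#' Define a simulation scenario
#'
#' Bundles the knobs of the simulation design used to validate the
#' enrichment model: the numbers of SNPs and individuals, the annotated
#' fraction, the overall proportion of trait-associated SNPs, the fraction
#' of phenotypic variance explained by all SNPs (PVE), and the spike-and-
#' slab prior parameters. A scenario with `theta = 0` and `sigma_sq = 0` is
#' a "negative" (no-enrichment) scenario.
#'
#' @param n_snps,n_individuals Problem sizes.
#' @param frac_annotated Fraction of SNPs carrying the annotation.
#' @param prop_causal Proportion of trait-associated SNPs, in (0, 1).
#' @param pve Phenotypic variance explained by all SNPs, in \[0, 1).
#' @param theta0 Baseline log10-odds of association; if `NULL`, it is
#'   derived so the mean association probability equals `prop_causal`
#'   given `theta` and `frac_annotated`.
#' @param theta Enrichment log10-odds (>= 0).
#' @param sigma0_sq Baseline slab variance (> 0).
#' @param sigma_sq Enrichment slab variance (>= 0).
#' @param seed Integer seed stored with the scenario.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_snps = 2000, n_individuals = 1500,
                                frac_annotated = 0.1, prop_causal = 0.005,
                                pve = 0.2, theta0 = NULL, theta = 0,
                                sigma0_sq = 1, sigma_sq = 0, seed = 1L) {
  if (!.is_count(n_snps) || !.is_count(n_individuals))
    .err("n_snps and n_individuals must be positive counts")
  if (!.is_prop(frac_annotated)) .err("frac_annotated must lie in [0, 1]")
  if (!is.numeric(prop_causal) || prop_causal <= 0 || prop_causal >= 1)
    .err("prop_causal must lie in (0, 1)")
  if (!is.numeric(pve) || pve < 0 || pve >= 1) .err("pve must lie in [0, 1)")
  if (theta < 0) .err("theta must be non-negative")
  if (sigma0_sq <= 0) .err("sigma0_sq must be positive")
  if (sigma_sq < 0) .err("sigma_sq must be non-negative")
  if (is.null(theta0))
    theta0 <- match_theta0(prop_causal, theta, frac_annotated)
  structure(list(n_snps = as.integer(n_snps),
                 n_individuals = as.integer(n_individuals),
                 frac_annotated = frac_annotated, prop_causal = prop_causal,
                 pve = pve, theta0 = theta0, theta = theta,
                 sigma0_sq = sigma0_sq, sigma_sq = sigma_sq,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(paste0("simulation_scenario: %d SNPs x %d individuals\n",
                     "  prop_causal=%.4g  pve=%.3g  theta0=%.3f  theta=%.3g",
                     "  sigma0_sq=%.3g  sigma_sq=%.3g  (%s)\n"),
              x$n_snps, x$n_individuals, x$prop_causal, x$pve, x$theta0,
              x$theta, x$sigma0_sq, x$sigma_sq,
              if (x$theta == 0 && x$sigma_sq == 0) "negative" else "positive"))
  invisible(x)
}

#' Baseline log10-odds matching a target causal proportion
#'
#' Solves for `theta0` so that the average prior association probability
#' `mean(1 / (1 + 10^-(theta0 + a_j * theta)))` over a population with an
#' annotated fraction `frac_annotated` equals `prop_causal`. Used to match
#' positive (enriched) and negative scenarios on the proportion of
#' trait-associated SNPs.
#'
#' @param prop_causal Target mean association probability.
#' @param theta Enrichment log10-odds.
#' @param frac_annotated Fraction of annotated SNPs.
#' @return The matching `theta0` (log10-odds).
#' @export
match_theta0 <- function(prop_causal, theta, frac_annotated) {
  f <- function(t0) {
    (1 - frac_annotated) / (1 + 10^(-t0)) +
      frac_annotated / (1 + 10^(-(t0 + theta))) - prop_causal
  }
  uniroot(f, c(-12, 6), tol = 1e-12)$root
}

#' Simulate block-structured genotypes
#'
#' Genotypes are generated from a latent Gaussian with AR(1) correlation
#' `rho` within LD blocks (blocks are independent), thresholded at
#' Hardy-Weinberg genotype-count quantiles of the sampled minor allele
#' frequency, so realized allele frequencies match the sampled values
#' exactly up to rounding and never fall below the configured floor.
#'
#' @param scenario A [simulation_scenario] (supplies `n_snps`,
#'   `n_individuals`, and the seed), or `NULL` to use the explicit sizes.
#' @param maf_dist Function of `n` returning `n` minor allele frequencies.
#' @param rho AR(1) latent correlation, `|rho| < 1` or exactly 1.
#' @param block_size SNPs per LD block.
#' @param n_snps,n_individuals Sizes used when `scenario` is `NULL`.
#' @param maf_floor Lower bound enforced on minor allele frequencies; must
#'   be below 0.5.
#' @param chrom Chromosome label given to all simulated SNPs.
#' @param seed Optional integer seed.
#' @return An object of class `genotypes`: list with the `n x p` matrix
#'   `X` (0/1/2 allele counts), `snp_id`, `chrom`, `pos`, alleles
#'   `a1`/`a2`, sampled `maf`, and `block` assignment.
#' @export
simulate_genotypes <- function(scenario = NULL,
                               maf_dist = function(n) runif(n, 0.05, 0.5),
                               rho = 0.5, block_size = 100L,
                               n_snps = 2000L, n_individuals = 1500L,
                               maf_floor = 0.05, chrom = "chr1",
                               seed = NULL) {
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "simulation_scenario"))
    n_snps <- scenario$n_snps
    n_individuals <- scenario$n_individuals
    if (is.null(seed)) seed <- scenario$seed
  }
  if (maf_floor >= 0.5) .err("maf floor must be below 0.5")
  if (!(abs(rho) < 1 || rho == 1)) .err("rho must satisfy |rho| < 1 or rho == 1")
  if (!.is_count(block_size)) .err("block_size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- as.integer(n_snps); n <- as.integer(n_individuals)
  maf <- maf_dist(p)
  maf[maf < maf_floor] <- maf_floor
  if (any(maf > 0.5)) .err("maf_dist produced frequencies above 0.5")
  block <- rep(seq_len(ceiling(p / block_size)), each = block_size)[seq_len(p)]
  X <- matrix(0L, n, p)
  for (b in unique(block)) {
    idx <- which(block == b)
    pb <- length(idx)
    E <- matrix(rnorm(n * pb), n, pb)
    L <- E
    if (pb > 1L && rho != 0) {
      for (j in 2:pb)
        L[, j] <- if (rho == 1) L[, j - 1L]
                  else rho * L[, j - 1L] + sqrt(1 - rho^2) * E[, j]
    }
    for (k in seq_len(pb)) {
      f <- maf[idx[k]]
      n2 <- round(n * f^2)
      n1 <- round(n * 2 * f * (1 - f))
      # guard the realized allele count against rounding below the floor
      while ((n1 + 2 * n2) < ceiling(2 * n * maf_floor) && (n1 + n2) < n)
        n1 <- n1 + 1L
      g <- integer(n)
      o <- order(L[, k], sample.int(n))  # random tie-break; ties are null sets
      if (n1 > 0L) g[o[seq.int(n - n2 - n1 + 1L, n - n2)]] <- 1L
      if (n2 > 0L) g[o[seq.int(n - n2 + 1L, n)]] <- 2L
      X[, idx[k]] <- g
    }
  }
  snp_id <- sprintf("rs%05d", seq_len(p))
  colnames(X) <- snp_id
  # within-block positions ~1 kb apart; blocks 1 Mb apart
  pos <- as.integer((block - 1L) * 1e6 +
                      stats::ave(rep(1e3, p), block, FUN = cumsum))
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, p, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
  structure(list(X = X, snp_id = snp_id, chrom = rep(chrom, p), pos = pos,
                 a1 = a1, a2 = unname(a2), maf = maf, block = block),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d individuals x %d SNPs in %d LD blocks\n",
              nrow(x$X), ncol(x$X), length(unique(x$block))))
  invisible(x)
}

#' Simulate SNP effects from the annotation-informed spike-and-slab prior
#'
#' Each effect is zero with probability `1 - pi_j` and otherwise drawn from
#' `N(0, sigma_j^2)`, where `pi_j = (1 + 10^-(theta0 + a_j * theta))^-1`
#' and `sigma_j^2 = sigma0_sq + a_j * sigma_sq`.
#'
#' @param annotation Binary 0/1 vector `a_j`.
#' @param theta0,theta Baseline and enrichment log10-odds of association.
#' @param sigma0_sq,sigma_sq Baseline and enrichment slab variances.
#' @param seed Optional integer seed.
#' @return List with `beta` (numeric effects), `causal` (logical), and
#'   `pi` (per-SNP prior association probabilities).
#' @export
simulate_effects <- function(annotation, theta0, theta, sigma0_sq, sigma_sq,
                             seed = NULL) {
  a <- as.numeric(annotation)
  if (any(!a %in% c(0, 1))) .err("annotation must be binary 0/1")
  if (sigma0_sq <= 0) .err("sigma0_sq must be positive")
  if (!is.null(seed)) set.seed(seed)
  pi_j <- 1 / (1 + 10^(-(theta0 + a * theta)))
  sigma_j <- sqrt(sigma0_sq + a * sigma_sq)
  causal <- runif(length(a)) < pi_j
  beta <- numeric(length(a))
  beta[causal] <- rnorm(sum(causal), 0, sigma_j[causal])
  list(beta = beta, causal = causal, pi = pi_j)
}

#' Simulate single-SNP GWAS summary statistics
#'
#' Phenotypes follow the additive model `y = X beta + e` with Gaussian
#' noise scaled so the SNP-explained variance fraction equals `pve`
#' (`Var(e) = Var(X beta) (1 - pve) / pve`; `pve = 0` yields pure
#' unit-variance noise). Each SNP is then tested by simple least-squares
#' regression of `y` on its allele count, giving the marginal effect, its
#' standard error, the z-score, and the sample size.
#'
#' @param genotypes A [simulate_genotypes()] object.
#' @param beta Per-SNP (per-allele) true effects.
#' @param pve Variance fraction explained by all SNPs, in \[0, 1).
#' @param seed Optional integer seed.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `a1`, `a2`, `beta`,
#'   `se`, `z`, `n`, plus the phenotype as attribute `"phenotype"`.
#' @export
simulate_gwas <- function(genotypes, beta, pve, seed = NULL) {
  stopifnot(inherits(genotypes, "genotypes"))
  X <- genotypes$X
  if (length(beta) != ncol(X)) .err("beta length must equal SNP count")
  if (!is.numeric(pve) || pve < 0 || pve >= 1) .err("pve must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  g <- as.numeric(X %*% beta)
  if (pve > 0) {
    if (all(beta == 0))
      .err("cannot scale noise to pve > 0 with all-zero effects")
    vg <- var(g)
    if (vg == 0) .err("genetic values have zero variance")
    y <- g + rnorm(n, 0, sqrt(vg * (1 - pve) / pve))
  } else {
    y <- rnorm(n)
  }
  yc <- y - mean(y)
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2)
  if (any(sxx == 0)) .err("monomorphic SNPs cannot be tested")
  sxy <- as.numeric(crossprod(xc, yc))
  bhat <- sxy / sxx
  rss <- sum(yc^2) - bhat^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  out <- data.frame(snp_id = genotypes$snp_id, chrom = genotypes$chrom,
                    pos = genotypes$pos, a1 = genotypes$a1,
                    a2 = genotypes$a2, beta = bhat, se = se,
                    z = bhat / se, n = n, stringsAsFactors = FALSE)
  attr(out, "phenotype") <- y
  out
}

#' Simulate fine-mapping posterior inclusion probabilities
#'
#' Draws PIPs from Beta distributions whose means differ by `enrich_ratio`
#' between annotated and unannotated SNPs (annotated mean capped at 1), so
#' the expected annotated PIP equals `enrich_ratio` times the expected
#' unannotated PIP.
#'
#' @param snp_table Data frame with at least `snp_id`.
#' @param annotation Binary 0/1 vector aligned to `snp_table`.
#' @param enrich_ratio Mean-PIP ratio for annotated SNPs (>= 1).
#' @param base_mean Mean PIP of unannotated SNPs.
#' @param concentration Beta concentration (shape1 + shape2).
#' @param trait,method Labels stored in the output.
#' @param seed Optional integer seed.
#' @return Data frame with `snp_id`, `trait`, `method`, `pip`.
#' @export
simulate_pips <- function(snp_table, annotation, enrich_ratio,
                          base_mean = 0.05, concentration = 10,
                          trait = "simtrait", method = "simfm",
                          seed = NULL) {
  a <- as.integer(annotation)
  if (length(a) != nrow(snp_table))
    .err("annotation length must match the SNP table")
  if (enrich_ratio < 1) .err("enrich_ratio must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- ifelse(a == 1, pmin(enrich_ratio * base_mean, 1), base_mean)
  pip <- numeric(length(a))
  at_one <- m >= 1
  pip[at_one] <- 1
  k <- !at_one
  pip[k] <- rbeta(sum(k), m[k] * concentration, (1 - m[k]) * concentration)
  data.frame(snp_id = snp_table$snp_id, trait = trait, method = method,
             pip = pip, stringsAsFactors = FALSE)
}
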