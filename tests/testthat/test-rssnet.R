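test_that("GWAS harmonization reconciles alleles against the reference", {
  ref <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                    a1 = c("G", "T", "A", "C", "G"),
                    a2 = c("T", "G", "C", "A", "A"))
  gwas <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4", "s6"),
    a1 = c("G", "G", "A", "T", "A"),
    a2 = c("T", "T", "T", "G", "C"),
    beta = c(0.1, 0.1, 0.2, 0.3, 0.4),
    se = rep(0.05, 5), z = c(2, 2, 4, 6, 8))
  h <- harmonize_gwas(gwas, ref)
  # s1 identical; s2 swapped (sign flip); s3 is A/T ambiguous (dropped);
  # s4 T/G vs reference C/A: opposite strand with swapped orientation, so
  # the alleles complement and the sign flips; s6 unmatched
  expect_setequal(h$gwas$snp_id, c("s1", "s2", "s4"))
  expect_equal(h$gwas$beta[h$gwas$snp_id == "s1"], 0.1)
  expect_equal(h$gwas$beta[h$gwas$snp_id == "s2"], -0.1)
  expect_equal(h$gwas$beta[h$gwas$snp_id == "s4"], -0.3)
  expect_equal(unname(h$report["strand_ambiguous"]), 1L)
  expect_equal(unname(h$report["unmatched"]), 1L)
  expect_equal(unname(h$report["flipped"]), 1L)
  expect_equal(unname(h$report["complement_flipped"]), 1L)

  # reference-identical input passes through with no exclusions
  clean <- data.frame(snp_id = c("s1", "s2"), a1 = c("G", "T"),
                      a2 = c("T", "G"), beta = c(1, 2), se = c(1, 1),
                      z = c(1, 2))
  h2 <- harmonize_gwas(clean, ref)
  expect_equal(h2$gwas$beta, c(1, 2))
  expect_true(all(h2$report[c("strand_ambiguous", "allele_mismatch",
                              "unmatched", "flipped")] == 0))
  bad <- data.frame(snp_id = "zz", a1 = "A", a2 = "C", beta = 1, se = 1)
  expect_error(harmonize_gwas(bad, ref), "matched")
})

test_that("the effect prior computes pi and slab variances exactly", {
  pr <- effect_prior(-2, 1, 0.1, 0.2, c(0, 1))
  expect_equal(pr$pi, c(1 / 101, 1 / 11))
  expect_equal(pr$sigma2, c(0.1, 0.3))
  expect_error(effect_prior(-2, -1, 0.1, 0, c(0, 1)), "non-negative")
  expect_error(effect_prior(-2, 1, 0, 0, c(0, 1)), "positive")
})

test_that("single-SNP variational solution equals the exact posterior", {
  for (s in 1:10) {
    fx <- small_rss_fixture(p = 1, pi0 = 0.2, sigma2 = 0.04, seed = s)
    pr <- effect_prior(log10(0.2 / 0.8), 0, 0.04, 0, 0)
    fit <- variational_fit(fx$gwas, fx$ld, pr)
    exact <- exact_spike_slab(fx$gwas$beta, fx$gwas$se,
                              fx$ld$blocks[[1]], 0.2, 0.04)
    expect_equal(fit$alpha, exact$inclusion, tolerance = 1e-6)
    # the ELBO lower-bounds the exact log marginal likelihood
    expect_lte(fit$elbo, exact$logml + 1e-8)
  }
})

test_that("few-SNP variational solutions track the enumeration oracle", {
  # 3 SNPs in LD: absolute accuracy of the inclusion probabilities
  for (s in 1:15) {
    fx <- small_rss_fixture(p = 3, rho = 0.4, pi0 = 0.15, sigma2 = 0.05,
                            seed = 100 + s)
    pr <- effect_prior(log10(0.15 / 0.85), 0, 0.05, 0,
                       rep(0, 3))
    fit <- variational_fit(fx$gwas, fx$ld, pr)
    exact <- exact_spike_slab(fx$gwas$beta, fx$gwas$se, fx$ld$blocks[[1]],
                              fx$pi, fx$sigma2)
    expect_lt(max(abs(fit$alpha - exact$inclusion)), 0.05)
    expect_lte(fit$elbo, exact$logml + 1e-8)
  }
})

test_that("the ELBO is non-decreasing at every coordinate-ascent sweep", {
  for (s in 1:10) {
    fx <- small_rss_fixture(p = 20, rho = 0.6, pi0 = 0.2, sigma2 = 0.05,
                            n_ind = 500, seed = 200 + s)
    pr <- effect_prior(-1, 0, 0.05, 0, rep(0, 20))
    fit <- variational_fit(fx$gwas, fx$ld, pr)
    for (tr in fit$elbo_trace) {
      if (length(tr) > 1)
        expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-length(tr)]))))
    }
  }
})

test_that("grid fits are deterministic and collapse correctly to baseline", {
  set.seed(210)
  geno <- simulate_genotypes(n_snps = 150, n_individuals = 500,
                             block_size = 30, seed = 211)
  a <- integer(150); a[sample.int(150, 30)] <- 1L
  eff <- simulate_effects(a, -1.5, 1, 0.05, 0.05, seed = 212)
  gwas <- simulate_gwas(geno, eff$beta, 0.3, seed = 213)
  ld <- ld_from_genotypes(geno)
  grid <- rssnet_grid("H", gwas, theta0 = c(-2, -1), theta = c(0, 1),
                      sigma0_mult = 4, sigma_mult = c(0, 3))
  f1 <- fit_model(gwas, ld, a, grid = grid, mode = "H")
  f2 <- fit_model(gwas, ld, a, grid = grid, mode = "H")
  expect_identical(f1$alpha_avg, f2$alpha_avg)
  expect_identical(f1$logml, f2$logml)

  # mode B with any annotation equals mode H with an all-zero annotation
  gridB <- rssnet_grid("B", gwas, theta0 = c(-2, -1), sigma0_mult = 4)
  fB <- fit_model(gwas, ld, a, grid = gridB, mode = "B")
  fH0 <- suppressWarnings(
    fit_model(gwas, ld, integer(150), grid = gridB, mode = "H"))
  expect_equal(fB$alpha_avg, fH0$alpha_avg, tolerance = 1e-12)
  expect_equal(fB$logml, fH0$logml, tolerance = 1e-12)
  expect_warning(fit_model(gwas, ld, integer(150), grid = gridB, mode = "H"),
                 "collapses to baseline")
})

test_that("Bayes factors compare enrichment against the baseline", {
  set.seed(220)
  geno <- simulate_genotypes(n_snps = 300, n_individuals = 800,
                             block_size = 50, seed = 221)
  a <- integer(300); a[sample.int(300, 60)] <- 1L
  ld <- ld_from_genotypes(geno)

  # a grid degenerate at theta = sigma_sq = 0 gives BF = 1 exactly
  eff <- simulate_effects(a, -1.5, 0, 0.05, 0, seed = 222)
  gwas <- simulate_gwas(geno, eff$beta, 0.3, seed = 223)
  null_grid <- rssnet_grid("B", gwas, theta0 = c(-2, -1), sigma0_mult = 4)
  fb <- fit_model(gwas, ld, grid = null_grid, mode = "B")
  fe <- suppressWarnings(fit_model(gwas, ld, a, grid = null_grid, mode = "H"))
  expect_equal(bayes_factor(fe, fb)$bf, 1, tolerance = 1e-12)

  # null simulations: log BF centered near 0; enriched: BF > 1 mostly
  logbf_null <- numeric(20); bf_enr <- numeric(20)
  for (s in 1:20) {
    grid <- NULL
    for (kind in c("null", "enriched")) {
      theta <- if (kind == "enriched") 2 else 0
      t0 <- match_theta0(0.04, theta, mean(a))
      eff <- simulate_effects(a, t0, theta, 0.05, 0)
      eff$beta[!eff$causal] <- 0
      if (!any(eff$causal)) next
      gw <- simulate_gwas(geno, eff$beta, 0.3)
      gridH <- rssnet_grid("H", gw, theta0 = c(-2, -1.4),
                           theta = c(0, 1, 2), sigma0_mult = c(3, 6),
                           sigma_mult = 0)
      gridB <- rssnet_grid("B", gw, theta0 = c(-2, -1.4),
                           sigma0_mult = c(3, 6))
      fH <- fit_model(gw, ld, a, grid = gridH, mode = "H")
      fB <- fit_model(gw, ld, grid = gridB, mode = "B")
      bf <- bayes_factor(fH, fB)
      if (kind == "null") logbf_null[s] <- log(bf$bf)
      else bf_enr[s] <- bf$bf
    }
  }
  # null data yield no systematic evidence for enrichment (the ELBO-based
  # approximation is slightly conservative, so the center sits at or below 0)
  expect_lte(median(logbf_null), 1)
  expect_gte(mean(bf_enr > 1), 0.9)
})

test_that("annotated inclusion rises with the simulated enrichment", {
  set.seed(230)
  geno <- simulate_genotypes(n_snps = 400, n_individuals = 800,
                             block_size = 50, seed = 231)
  a <- integer(400); a[sample.int(400, 80)] <- 1L
  ld <- ld_from_genotypes(geno)
  avg_alpha <- sapply(c(0, 1, 2), function(theta) {
    mean(vapply(1:10, function(s) {
      set.seed(3000 + 17 * s + theta)
      eff <- simulate_effects(a, -2, theta, 0.05, 0)
      if (!any(eff$causal)) return(NA_real_)
      gw <- simulate_gwas(geno, eff$beta, 0.3)
      grid <- rssnet_grid("H", gw, theta0 = c(-2.5, -1.5), theta = c(0, 2),
                          sigma0_mult = c(3, 6), sigma_mult = 0)
      fit <- fit_model(gw, ld, a, grid = grid, mode = "H")
      mean(fit$alpha_avg[a == 1])
    }, numeric(1)), na.rm = TRUE)
  })
  expect_true(all(diff(avg_alpha) > 0))
})

test_that("element P1 follows the factorized at-least-one form", {
  fit <- structure(list(alpha_avg = c(0.3, 0.5, 0.5, 0),
                        snp_id = sprintf("s%d", 1:4), mode = "H"),
                   class = "rssnet_fit")
  snps <- data.frame(snp_id = sprintf("s%d", 1:4), chrom = "chr1",
                     pos = c(100, 200, 210, 500))
  # single-SNP element: P1 equals alpha
  expect_equal(element_p1(fit, gr0("chr1", 90, 110), snps), 0.3)
  # two SNPs at alpha 0.5: P1 = 0.75
  expect_equal(element_p1(fit, gr0("chr1", 150, 300), snps), 0.75)
  # all-zero alpha inside the element: P1 = 0
  expect_equal(element_p1(fit, gr0("chr1", 450, 550), snps), 0)
  expect_error(element_p1(fit, gr0("chr1", 1000, 1100), snps),
               "no fitted SNP")
})

test_that("enrichment-informed P1 exceeds baseline P1 for true elements", {
  set.seed(240)
  geno <- simulate_genotypes(n_snps = 400, n_individuals = 1000,
                             block_size = 50, seed = 241)
  a <- integer(400)
  idx <- lapply(seq(1, 400, by = 20)[1:20], function(s) s:(s + 1))
  a[unlist(idx)] <- 1L
  ld <- ld_from_genotypes(geno)
  gaps <- numeric(0)
  for (s in 1:5) {
    t0 <- match_theta0(0.05, 2, mean(a))
    eff <- simulate_effects(a, t0, 2, 0.05, 0)
    if (!any(eff$causal)) next
    gw <- simulate_gwas(geno, eff$beta, 0.4)
    grid <- rssnet_grid("H", gw, theta0 = c(-2, -1.3), theta = c(0, 2),
                        sigma0_mult = c(3, 6), sigma_mult = 0)
    gridB <- rssnet_grid("B", gw, theta0 = c(-2, -1.3),
                         sigma0_mult = c(3, 6))
    fH <- fit_model(gw, ld, a, grid = grid, mode = "H")
    fB <- fit_model(gw, ld, grid = gridB, mode = "B")
    truth <- vapply(idx, function(i) any(eff$causal[i]), logical(1))
    if (!any(truth)) next
    p1H <- conselem:::.p1_from_alpha(fH$alpha_avg, idx)
    p1B <- conselem:::.p1_from_alpha(fB$alpha_avg, idx)
    gaps <- c(gaps, p1H[truth] - p1B[truth])
  }
  expect_gt(mean(gaps), 0)
})
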