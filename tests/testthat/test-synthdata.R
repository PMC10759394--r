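test_that("peak simulation honors the overlap fraction at its extremes", {
  g <- tiny_genome()
  p0 <- simulate_context_peaks(g, 50, overlap_frac = 0, seed = 21)
  expect_length(intersect_peaks(p0$h3k27ac, p0$accessible), 0)

  p1 <- simulate_context_peaks(g, 50, overlap_frac = 1, seed = 22)
  expect_identical(granges(p1$h3k27ac), granges(p1$accessible))
  expect_identical(granges(intersect_peaks(p1$h3k27ac, p1$accessible)),
                   granges(reduce(p1$h3k27ac)))
})

test_that("peak simulation is seeded, sorted, in bounds, and calibrated", {
  g <- genome_spec(c(chr1 = 1000000L, chr2 = 500000L))
  a <- simulate_context_peaks(g, 500, overlap_frac = 0.4, seed = 23)
  b <- simulate_context_peaks(g, 500, overlap_frac = 0.4, seed = 23)
  expect_identical(a, b)
  for (gr in a) {
    expect_false(is.unsorted(order(as.factor(seqnames(gr)), start(gr))))
    expect_true(all(start(gr) >= 1))
    expect_true(all(end(gr) <= unclass(g)[as.character(seqnames(gr))]))
  }
  # covered fraction of H3K27ac bases across seeds is near overlap_frac
  fr <- vapply(1:20, function(s) {
    p <- simulate_context_peaks(g, 200, overlap_frac = 0.4, seed = 100 + s)
    ov <- intersect_peaks(p$h3k27ac, p$accessible)
    sum(width(ov)) / sum(width(p$h3k27ac))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.4), 0.05)
  expect_error(simulate_context_peaks(genome_spec(integer()), 10, 0.5),
               "chromosome")
})

test_that("alignment blocks hit the target coverage and stay disjoint", {
  g <- genome_spec(c(chr1 = 1500000L))
  for (cov in c(0.2, 0.5, 0.9)) {
    bl <- simulate_alignment_blocks(g, cov, seed = 24)
    expect_true(isDisjoint(bl$source))
    expect_identical(width(bl$source), width(bl$target))
    realized <- sum(width(bl$source)) / 1500000
    expect_lt(abs(realized - cov), 0.02)
  }
  b0 <- simulate_alignment_blocks(g, 0, seed = 25)
  expect_length(b0$source, 0)
  expect_equal(conservation_fraction(gr0("chr1", 100, 400), b0), 0)
  b1 <- simulate_alignment_blocks(g, 1, seed = 26)
  expect_equal(conservation_fraction(gr0("chr1", 100, 400), b1), 1)
})

test_that("genotypes are 0/1/2 with floored MAFs and AR(1) block LD", {
  geno <- simulate_genotypes(n_snps = 100, n_individuals = 800,
                             block_size = 25, rho = 0.5, seed = 27)
  expect_true(all(geno$X %in% 0:2))
  expect_true(all(colMeans(geno$X) / 2 >= 0.05))
  expect_identical(
    geno, simulate_genotypes(n_snps = 100, n_individuals = 800,
                             block_size = 25, rho = 0.5, seed = 27))
  expect_error(simulate_genotypes(maf_floor = 0.5), "below 0.5")

  # rho = 0: off-diagonal sample correlations vanish as n grows
  g0 <- simulate_genotypes(n_snps = 40, n_individuals = 5000, rho = 0,
                           block_size = 40, seed = 28)
  cc <- cor(g0$X)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.02)

  # rho = 1 with a shared MAF: identical standardized genotype vectors
  g1 <- simulate_genotypes(n_snps = 10, n_individuals = 300, rho = 1,
                           block_size = 10,
                           maf_dist = function(n) rep(0.3, n), seed = 29)
  zs <- scale(g1$X)
  expect_true(all(abs(zs - zs[, 1]) < 1e-12))

  # SNPs in different blocks are generated independently
  gx <- simulate_genotypes(n_snps = 40, n_individuals = 4000, rho = 0.9,
                           block_size = 20, seed = 30)
  cross <- cor(gx$X[, 1:20], gx$X[, 21:40])
  expect_lt(mean(abs(cross)), 0.03)
})

test_that("effects follow the annotation-informed spike-and-slab prior", {
  a <- c(rep(0, 5), rep(1, 5))
  eff <- simulate_effects(a, theta0 = -2, theta = 0, sigma0_sq = 0.1,
                          sigma_sq = 0.2, seed = 31)
  expect_equal(eff$pi, rep(1 / 101, 10))
  eff2 <- simulate_effects(a, theta0 = -2, theta = 1, sigma0_sq = 0.1,
                           sigma_sq = 0.2, seed = 31)
  expect_equal(eff2$pi[a == 1], rep(1 / 11, 5))
  expect_equal(eff2$pi[a == 0], rep(1 / 101, 5))
  expect_error(simulate_effects(a, -2, 0, 0, 0.2), "positive")
  expect_error(simulate_effects(c(0, 2), -2, 0, 0.1, 0), "binary")

  # law of large numbers: causal fraction matches mean pi at 1e5 draws
  a_big <- rep(c(0, 1), length.out = 1e5)
  eff3 <- simulate_effects(a_big, theta0 = -2, theta = 1, sigma0_sq = 0.1,
                           sigma_sq = 0.2, seed = 32)
  pbar <- mean(eff3$pi)
  mc_sd <- sqrt(pbar * (1 - pbar) / 1e5)
  expect_lt(abs(mean(eff3$causal) - pbar), 3 * mc_sd)
  # annotated slab variance adds the enrichment component
  expect_equal(unique(0.1 + a * 0.2), c(0.1, 0.3))
})

test_that("null GWAS z-scores are standard normal and seeds reproduce", {
  geno <- simulate_genotypes(n_snps = 2000, n_individuals = 600, rho = 0,
                             block_size = 2000, seed = 33)
  gw <- simulate_gwas(geno, rep(0, 2000), pve = 0, seed = 34)
  expect_lt(abs(mean(gw$z)), 0.05)
  expect_true(var(gw$z) > 0.9 && var(gw$z) < 1.1)
  gw2 <- simulate_gwas(geno, rep(0, 2000), pve = 0, seed = 34)
  expect_identical(gw, gw2)
  expect_error(simulate_gwas(geno, rep(0, 2000), pve = 0.3),
               "all-zero")
})

test_that("a lone causal SNP without LD attains the top |z|", {
  geno <- simulate_genotypes(n_snps = 50, n_individuals = 800, rho = 0,
                             block_size = 50, seed = 35)
  beta <- numeric(50); beta[17] <- 1
  hits <- vapply(1:100, function(s) {
    gw <- simulate_gwas(geno, beta, pve = 0.3, seed = 1000 + s)
    which.max(abs(gw$z)) == 17
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulated PIPs are calibrated to the enrichment ratio", {
  snps <- data.frame(snp_id = sprintf("rs%d", 1:20000))
  a <- rep(c(1, 0), c(5000, 15000))
  p1 <- simulate_pips(snps, a, enrich_ratio = 1, seed = 36)
  expect_true(all(p1$pip >= 0 & p1$pip <= 1))
  expect_lt(abs(mean(p1$pip[a == 1]) - mean(p1$pip[a == 0])), 0.005)
  p3 <- simulate_pips(snps, a, enrich_ratio = 3, seed = 37)
  expect_lt(abs(mean(p3$pip[a == 1]) / mean(p3$pip[a == 0]) - 3), 0.2)
  expect_identical(p3, simulate_pips(snps, a, enrich_ratio = 3, seed = 37))
  expect_error(simulate_pips(snps, a, enrich_ratio = 0.5), ">= 1")
})

test_that("scenario constructor enforces the design invariants", {
  sc <- simulation_scenario(prop_causal = 0.01, pve = 0.3, theta = 2)
  expect_s3_class(sc, "simulation_scenario")
  # derived theta0 reproduces the causal proportion
  pi_bar <- (1 - sc$frac_annotated) / (1 + 10^(-sc$theta0)) +
    sc$frac_annotated / (1 + 10^(-(sc$theta0 + sc$theta)))
  expect_equal(pi_bar, 0.01, tolerance = 1e-8)
  expect_error(simulation_scenario(prop_causal = 0), "prop_causal")
  expect_error(simulation_scenario(pve = 1), "pve")
  expect_error(simulation_scenario(theta = -1), "theta")
  expect_error(simulation_scenario(sigma_sq = -1), "sigma_sq")
})

test_that("positive and negative scenario pairs match causal proportions", {
  # matching invariant: mean prior association probability is equal
  for (pc in c(0.005, 0.02)) {
    t0_pos <- match_theta0(pc, theta = 2, frac_annotated = 0.1)
    pi_pos <- 0.9 / (1 + 10^(-t0_pos)) + 0.1 / (1 + 10^(-(t0_pos + 2)))
    t0_neg <- log10(pc / (1 - pc))
    pi_neg <- 1 / (1 + 10^(-t0_neg))
    expect_equal(pi_pos, pc, tolerance = 1e-8)
    expect_equal(pi_neg, pc, tolerance = 1e-12)
  }
})
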