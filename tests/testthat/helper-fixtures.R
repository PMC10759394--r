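suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# build a GRanges from 0-based half-open coordinates (BED convention),
# the convention used for interval literals throughout the tests
gr0 <- function(chrom, start, end) {
  GRanges(chrom, IRanges(start + 1L, end))
}

tiny_genome <- function() genome_spec(c(chr1 = 100000L, chr2 = 50000L))

# random peak set as 0/1 coverage over a small chromosome, for per-base
# oracles
random_intervals <- function(n, chrom_len, max_len = 500L) {
  s <- sample.int(chrom_len - max_len, n)
  w <- sample.int(max_len, n, replace = TRUE)
  reduce(GRanges("chr1", IRanges(s, width = w)))
}

coverage_vector <- function(gr, chrom_len) {
  v <- logical(chrom_len)
  for (i in seq_along(gr)) v[start(gr)[i]:end(gr)[i]] <- TRUE
  v
}

# small genotype panel shared by LD-score and model tests
small_genotypes <- function(n_snps = 60, n_ind = 400, rho = 0.5,
                            block_size = 20, seed = 101) {
  simulate_genotypes(n_snps = n_snps, n_individuals = n_ind, rho = rho,
                     block_size = block_size, seed = seed)
}

# random RSS fixture on a handful of SNPs for exact-posterior oracles:
# draws LD from an AR correlation, effects from the spike-and-slab prior,
# and marginal statistics from individual-level data
small_rss_fixture <- function(p = 3, n_ind = 600, rho = 0.4, pi0 = 0.1,
                              sigma2 = 0.05, pve = 0.3, seed = 1) {
  set.seed(seed)
  geno <- simulate_genotypes(n_snps = p, n_individuals = n_ind, rho = rho,
                             block_size = p, seed = NULL)
  beta <- ifelse(runif(p) < pi0, rnorm(p, 0, sqrt(sigma2)), 0)
  gwas <- if (all(beta == 0)) simulate_gwas(geno, beta, 0)
          else simulate_gwas(geno, beta, pve)
  ld <- ld_from_genotypes(geno, shrink = 0.1)
  list(geno = geno, gwas = gwas, ld = ld, beta = beta,
       pi = rep(pi0, p), sigma2 = rep(sigma2, p))
}
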