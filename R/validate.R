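#' Default simulation-validation scenarios
#'
#' Four desk-scale scenarios crossing the proportion of trait-associated
#' SNPs (0.005, 0.02) with the SNP-explained variance fraction (0.2, 0.5),
#' alternating the enrichment mechanism of the positive datasets between
#' the prior-odds channel (`theta = 2`, `sigma_sq = 0`) and the
#' effect-size channel (`theta = 0`, annotated slab variance tripled).
#' Matched negative datasets use `theta = 0`, `sigma_sq = 0` with the
#' baseline log10-odds solved so the mean association probability equals
#' the positive datasets' (see [match_theta0()]).
#'
#' @return Data frame with one row per scenario.
#' @export
validation_scenarios <- function() {
  data.frame(
    scenario = paste0("S", 1:4),
    prop_causal = c(0.005, 0.005, 0.02, 0.02),
    pve = c(0.2, 0.5, 0.2, 0.5),
    enrich_mode = c("theta", "sigma", "theta", "sigma"),
    theta = c(2, 0, 2, 0),
    sigma_mult = c(0, 2, 0, 2),  # sigma_sq = sigma_mult * sigma0_sq
    stringsAsFactors = FALSE
  )
}

#' Simulation validation of element-level association calls
#'
#' End-to-end harness for the enrichment model: fixed reference genotypes
#' in AR(1) LD blocks; a fixed panel of elements each covering a few
#' adjacent SNPs (the annotated ~10% of SNPs); per scenario, positive
#' datasets with SNP effects drawn from the annotation-enriched
#' spike-and-slab prior and matched negative datasets without enrichment;
#' phenotypes from the additive model; single-SNP GWAS summary statistics;
#' a mode-"H" enrichment fit; and element-level `P1` calls at
#' `p1_cutoff`. An element call is true when the element contains at least
#' one SNP with a nonzero simulated effect.
#'
#' The reported false positive rate is the fraction of truly null
#' element-dataset pairs in negative datasets called at the cutoff; the
#' false discovery rate is the false fraction among all calls across
#' positive and negative datasets (0 when there are no calls).
#'
#' @param scenarios Scenario table as from [validation_scenarios()].
#' @param n_pos,n_neg Positive/negative datasets per scenario.
#' @param n_snps,n_blocks,n_individuals Genotype panel dimensions.
#' @param n_elements,snps_per_element Element panel layout.
#' @param rho AR(1) LD parameter.
#' @param p1_cutoff Association call threshold on `P1`.
#' @param grid Hyper-parameter grid; defaults to a compact desk-scale grid
#'   built from the first simulated dataset's SE scale.
#' @param seed Integer seed for the whole harness.
#' @param progress Print one line per scenario.
#' @return Object of class `rssnet_validation`: list with the per-call
#'   table `calls`, `fpr`, `fdr`, counts, and the configuration.
#' @export
rssnet_validate <- function(scenarios = validation_scenarios(),
                            n_pos = 50L, n_neg = 50L,
                            n_snps = 2000L, n_blocks = 20L,
                            n_individuals = 1500L,
                            n_elements = 100L, snps_per_element = 2L,
                            rho = 0.5, p1_cutoff = 0.9, grid = NULL,
                            seed = 1L, progress = FALSE) {
  set.seed(seed)
  block_size <- ceiling(n_snps / n_blocks)
  geno <- simulate_genotypes(rho = rho, block_size = block_size,
                             n_snps = n_snps, n_individuals = n_individuals,
                             seed = NULL)
  panel <- .element_panel(geno, n_elements, snps_per_element)
  annotation <- panel$annotation
  frac_annotated <- mean(annotation)
  ld <- ld_from_genotypes(geno)
  results <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    sigma0_sq <- 1
    sigma_sq_pos <- sc$sigma_mult * sigma0_sq
    theta0_pos <- match_theta0(sc$prop_causal, sc$theta, frac_annotated)
    theta0_neg <- log10(sc$prop_causal / (1 - sc$prop_causal))
    for (type in c("positive", "negative")) {
      n_d <- if (type == "positive") n_pos else n_neg
      for (d in seq_len(n_d)) {
        eff <- .effects_with_causal(
          annotation,
          theta0 = if (type == "positive") theta0_pos else theta0_neg,
          theta = if (type == "positive") sc$theta else 0,
          sigma0_sq = sigma0_sq,
          sigma_sq = if (type == "positive") sigma_sq_pos else 0)
        gwas <- simulate_gwas(geno, eff$beta, sc$pve)
        if (is.null(grid))
          grid <- rssnet_grid("H", gwas,
                              theta0 = c(-3, -2.3, -1.6),
                              theta = c(0, 1, 2),
                              sigma0_mult = c(3, 6),
                              sigma_mult = c(0, 3))
        fit <- fit_model(gwas, ld, annotation, grid = grid, mode = "H")
        p1 <- .p1_from_alpha(fit$alpha_avg, panel$idx)
        truth <- vapply(panel$idx, function(i) any(eff$causal[i]), logical(1))
        results[[length(results) + 1L]] <- data.frame(
          scenario = sc$scenario, type = type, dataset = d,
          element = seq_along(p1), p1 = p1, truth = truth,
          stringsAsFactors = FALSE)
      }
    }
    if (progress)
      message(sprintf("scenario %s done (%d datasets)", sc$scenario,
                      n_pos + n_neg))
  }
  calls <- do.call(rbind, results)
  called <- calls$p1 >= p1_cutoff
  neg_null <- calls$type == "negative" & !calls$truth
  fpr <- if (any(neg_null)) mean(called[neg_null]) else NA_real_
  n_calls <- sum(called)
  fdr <- if (n_calls > 0) mean(!calls$truth[called]) else 0
  structure(list(calls = calls, fpr = fpr, fdr = fdr,
                 n_calls = n_calls,
                 n_true_calls = sum(called & calls$truth),
                 n_false_calls = sum(called & !calls$truth),
                 n_element_datasets = nrow(calls),
                 p1_cutoff = p1_cutoff, scenarios = scenarios,
                 config = list(n_pos = n_pos, n_neg = n_neg,
                               n_snps = n_snps, n_blocks = n_blocks,
                               n_individuals = n_individuals,
                               n_elements = n_elements,
                               snps_per_element = snps_per_element,
                               rho = rho, seed = seed)),
            class = "rssnet_validation")
}

#' @export
print.rssnet_validation <- function(x, ...) {
  cat(sprintf("rssnet_validation: %d element-dataset pairs, cutoff P1 >= %g\n",
              x$n_element_datasets, x$p1_cutoff))
  cat(sprintf("  calls: %d (%d true, %d false)\n", x$n_calls,
              x$n_true_calls, x$n_false_calls))
  cat(sprintf("  false positive rate (negative datasets): %.3g\n", x$fpr))
  cat(sprintf("  false discovery rate (all calls):        %.3g\n", x$fdr))
  invisible(x)
}

# fixed element panel: per LD block, disjoint runs of adjacent SNPs
.element_panel <- function(geno, n_elements, snps_per_element) {
  blocks <- unique(geno$block)
  per_block <- ceiling(n_elements / length(blocks))
  idx <- list()
  for (b in blocks) {
    snps <- which(geno$block == b)
    n_slots <- floor(length(snps) / (2 * snps_per_element))
    take <- min(per_block, n_slots)
    if (take == 0L) next
    starts <- sort(sample(n_slots, take)) * 2L * snps_per_element -
      2L * snps_per_element + 1L
    for (s in starts)
      idx[[length(idx) + 1L]] <- snps[s:(s + snps_per_element - 1L)]
  }
  idx <- idx[seq_len(min(length(idx), n_elements))]
  annotation <- integer(length(geno$snp_id))
  annotation[unlist(idx)] <- 1L
  elements <- GRanges(geno$chrom[vapply(idx, `[`, integer(1), 1L)],
                      IRanges(geno$pos[vapply(idx, `[`, integer(1), 1L)],
                              geno$pos[vapply(idx, function(i)
                                i[length(i)], integer(1))]))
  list(idx = idx, annotation = annotation, elements = elements)
}

# rejection wrapper: redraw when no SNP is causal (the additive model
# cannot be scaled to a positive pve with an all-zero effect vector)
.effects_with_causal <- function(annotation, theta0, theta, sigma0_sq,
                                 sigma_sq, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    eff <- simulate_effects(annotation, theta0, theta, sigma0_sq, sigma_sq)
    if (any(eff$causal)) return(eff)
  }
  .err("no causal SNPs drawn in %d attempts", max_tries)
}
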