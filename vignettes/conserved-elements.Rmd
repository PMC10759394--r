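---
title: "Sequence-conserved enhancer-like elements: models and methods"
author: "conselem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-conserved enhancer-like elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical choices, and what the simulation
suite does and does not demonstrate.

## Element identification and conservation classes

A context (a tissue or cell type) contributes an H3K27ac peak set and an
accessible-chromatin peak set. `intersect_peaks()` takes their base-level
intersection, merged into maximal intervals: an enhancer-like element is
a region supported by both marks. Coordinates are 0-based half-open on
disk (BED) and 1-based closed in memory (`GRanges`); all distances are in
bases.

Conservation is scored against gapless alignment blocks between the
source (human) and a target (mouse) genome. For an element `E`,
`conservation_fraction()` returns the covered fraction
`|E ∩ blocks| / |E|`, and `classify_conservation()` admits `E` into the
level-`m` class when the fraction is at least `m`. The default levels
0.1, 0.5, 0.9 define the low (LC), moderate (MC), and high (HC)
conservation classes; because the rule is a threshold on one scalar, the
classes are nested by construction (HC ⊆ MC ⊆ LC ⊆ NC) and the retained
record is always the original source-genome interval. This is a
deterministic approximation of liftOver's minMatch semantics: the
coordinate-lifting tool splits regions and reports target-side
coordinates in edge cases, whereas the rule here never alters the
interval. Analyses that treat elements as source-genome intervals are
unaffected; base-precise target coordinates are not produced.

`merge_omnibus()` pools context-specific element sets into an "omnibus"
set of non-overlapping intervals. Bookended (adjacent) intervals are
merged, matching the semantics of a merged non-overlapping segmentation.
The identity `a(j; omnibus) = max_k a(j; context k)` then holds exactly
for the binary SNP annotation, and the test suite checks it on a
thousand random context collections.

TSS proximity classes use the minimum base distance between any element
base and any TSS: within 200 bp is promoter-proximal, within 2,000 bp
(boundary inclusive) near-proximal, otherwise distal.

## SNP annotation and correlation

`annotate_snps()` sets `a(j) = 1` when SNP `j` lies inside at least one
element; a SNP exactly at a half-open end coordinate is outside. Binary
annotation pairs are compared with Cramér's V, computed as
`sqrt(chisq / n)` from the 2×2 table without continuity or bias
correction — the conventional definition; binary–quantitative pairs use
Pearson's R. Annotation standard deviations use the population
(divide-by-n) convention, `SD_a = sqrt(q(1−q))` for an annotated
proportion `q`, because the standardized effect size below multiplies by
`SD_a`.

## Stratified heritability regression

The per-SNP effect-variance model is

    Var(beta_j) = tau_0 + sum_d tau_d * a_d(j)

over a background (all-SNPs) annotation and any number of covariate and
focal annotations; the conditional analysis of a conserved subset is the
joint fit with the full element annotation and covariates in the design.
With LD scores `l(j, a) = sum_k r^2(j, k) a(k)` (squared sample
correlations of reference genotype columns within a window, 1 Mb by
default, no small-sample adjustment), the expected GWAS chi-squared
statistic is linear in `n * l(j, ·)`. `fit_sldsc()` performs weighted
least squares of `z_j^2` on `n * l(j, ·)` with a free intercept and
heteroskedasticity-motivated weights `1 / (2 (1 + n l_base(j) / p)^2)`.
Standard errors come from a delete-block jackknife over contiguous SNP
blocks — 200 blocks by default, scaled down proportionally below 2,000
SNPs. Summaries follow the standard definitions: enrichment
`(h2_a / h2) / (|a| / p)` with a one-sided P-value on the per-SNP
difference contrast `h2_a/|a| − (h2 − h2_a)/(p − |a|)`, and the
standardized effect `tau* = p SD_a tau_a / h2` with a one-sided Z test.
The all-SNPs annotation has enrichment exactly 1 and a zero-width
contrast. Exact regression weights and SNP filters of released
heritability-regression software are not restated here; the defaults
above are documented approximations, and the common-SNP filter
(MAF ≥ 0.05) applies when the GWAS table carries a `maf` column.

Cross-study summaries: `meta_random_effects()` pools estimates by
DerSimonian–Laird (delegating to `metafor::rma(method = "DL")`) with a
one-sided Z P-value, returning single studies unchanged;
`deming_fit()` is a generalized errors-in-variables regression
minimizing `sum_i (y_i − a − b x_i)^2 / (se_y_i^2 + b^2 se_x_i^2)`, with
the intercept profiled in closed form, the slope found by an angle-grid
search polished on the stationarity condition, and leave-one-out
jackknife standard errors.

## Fine-mapping overlap

For each PIP threshold `t` (inclusive, `>=`, a documented choice since
either convention is defensible), the annotated passing fraction `f_in`
is compared with the overall fraction `f_all`, reporting the difference,
the ratio, and the exact one-sided binomial tail probability
`P(X >= k)` for `X ~ Binomial(n_annotated, f_all)`. Fine-mapping QC
(credible-set membership, LD-linked exclusions) is accepted as
precomputed row filters; when several fine-mapping methods appear in one
table, results are computed per method and never merged.

## The enrichment model on summary statistics

Marginal effect estimates are modeled per LD block as jointly normal
with mean `S R S^{-1} beta` and covariance `S R S`, where `S` is the
diagonal of standard errors and `R` the reference LD correlation matrix.
Effects carry the annotation-informed spike-and-slab prior

    beta_j ~ pi_j N(0, sigma_j^2) + (1 − pi_j) delta_0
    pi_j = (1 + 10^{−(theta0 + a_j theta)})^{−1}
    sigma_j^2 = sigma0^2 + a_j sigma^2

so annotated SNPs can be enriched through the prior-odds channel
(`theta > 0`) and/or the effect-size channel (`sigma^2 > 0`).

Inference uses a fully factorized spike-and-slab variational family
optimized by coordinate ascent (compiled inner loop), SNPs updated in
descending `|z|`, convergence when the ELBO changes by less than
`tol (1 + |ELBO|)` with `tol = 1e-8`, iteration cap 500 with
non-convergence flagged rather than raised. The default initialization
is `alpha = pi, mu = 0`; across a hyper-parameter grid the previous
point's solution warm-starts the next (grids are traversed in sorted
parameter order, so this is deterministic), and up to three distinct
deterministic initializations can be requested, keeping the best ELBO.
For one SNP the family is exact and the solution equals the
two-component posterior; for small systems the tests compare against
exhaustive enumeration over all sparsity patterns. Reference LD is
regularized by shrinkage toward the identity (weight 0.1 by default)
plus an eigenvalue floor at `1e-8`, rescaled to unit diagonal.

Hyper-parameter grids place `theta0` on a log10-odds grid, `theta` on
`[0, 3]`, and the slab variances on multiples of the median marginal
standard error — a data-adaptive scale chosen because the slab must live
on the scale of detectable marginal effects, which depends on the sample
size through the SEs. Grid weights are uniform. These grids are package
defaults (the quantities they stand in for are tuning choices, not
estimands); all are arguments.

Model averaging weights each grid point by its hyper-prior times the
exponentiated ELBO; the mode-level log marginal likelihood is the
log-sum-exp of those terms. The enrichment Bayes factor divides the
average over enrichment points (`theta > 0` or `sigma^2 > 0`) by the
baseline fit (`theta = sigma^2 = 0`). Because each marginal likelihood
is replaced by its variational lower bound, and the bound is loosest for
prior configurations that misfit the data, null-data Bayes factors
center somewhat below 1 rather than at 1 — a conservative direction for
an enrichment claim — while simulations with genuine enrichment place
most Bayes factors well above 1.

Per-element association uses
`P1 = 1 − prod_j (1 − alpha_j)` over the element's SNPs with
grid-averaged `alpha`. Under the factorized family the exact joint
"at least one nonzero" probability is unavailable; the product form is
the documented approximation, and `P1^B`, `P1^N`, `P1^H` label the prior
configuration (baseline, all-element enrichment, conserved-element
enrichment) that produced `alpha`.

## Synthetic data and the validation harness

The generators produce every input the pipeline consumes. Peaks:
rejection-sampled disjoint intervals; the accessibility set duplicates
each H3K27ac peak with probability `overlap_frac` and places the rest
disjointly, so the expected shared base fraction equals `overlap_frac`.
Alignment blocks: per chromosome, block lengths are drawn until their
sum is the rounded coverage target and the slack is distributed among
the gaps at random, so realized coverage is exact up to one-base
rounding. Genotypes: a latent Gaussian with AR(1) correlation `rho`
within blocks (blocks independent), thresholded at Hardy–Weinberg
genotype-count quantiles of the sampled MAF — a construction chosen for
its closed-form latent correlation target and exact realized allele
frequencies (never below the configured floor). Effects come from the
spike-and-slab prior above; phenotypes follow `y = X beta + e` with
`Var(e) = Var(X beta)(1 − pve)/pve` so the realized SNP-explained
fraction equals `pve` (pure unit-variance noise at `pve = 0`); summary
statistics are per-SNP least squares. PIP tables draw from Beta
distributions whose means differ by the requested enrichment ratio.
Every generator is deterministic given its seed.

`rssnet_validate()` assembles these into the validation harness: 2,000
SNPs in 20 AR(1) blocks (`rho = 0.5`) for 1,500 individuals; 100
elements of two adjacent SNPs each, i.e. ~10% of SNPs annotated; four
scenarios crossing the causal proportion (0.005, 0.02) with the
SNP-explained variance (0.2, 0.5), the positive arm enriched through the
prior-odds channel (`theta = 2`) in two scenarios and the effect-size
channel (annotated slab variance tripled) in the other two; 50 positive
and 50 negative datasets per scenario. Negative datasets are matched to
positive ones on both the causal proportion — `match_theta0()` solves
the baseline log10-odds so the mean prior association probability is
identical — and the explained variance, which the noise scaling enforces
by construction. Elements are called at `P1^H >= 0.9`; a call is true
when the element contains a SNP with a nonzero simulated effect. The
harness reports the false positive rate among truly null elements in
negative datasets and the false discovery rate across all calls; these
sizes keep the whole harness within a few minutes on one CPU, and
`scripts/acceptance.R` reruns it from scratch for any seed.

The generators emulate the statistical structure the analyses assume —
block LD, annotation-dependent priors, additive phenotypes — but not
several features of real data: no minor-allele-frequency dependence of
effect sizes, no long-range or cross-block LD, no population
stratification or relatedness, no genotyping or imputation error, and
element panels far smaller than a genome-wide catalogue. Passing the
harness therefore demonstrates correctness and calibration of the
machinery under its own model, not performance on real cohorts.

## Numerical and degenerate-input conventions

- Half-open interval semantics throughout; a SNP at an element's end
  coordinate is outside; bookended intervals merge.
- `classify_conservation()` requires strictly increasing levels in
  (0, 1]; degenerate all-covered or empty block sets yield fractions of
  exactly 1 or 0.
- Rank-deficient heritability designs raise an error naming the
  collinear annotations; monomorphic reference SNPs are dropped with a
  warning.
- Enrichment is undefined for an empty annotation (error); the all-SNPs
  annotation returns enrichment exactly 1 with a `NA` P-value.
- The binomial test requires `p0` strictly inside (0, 1); thresholds
  where every variant passes report `NA` P-values.
- Strand-ambiguous (A/T, C/G) SNPs are always dropped during
  harmonization; allele mismatches and unmatched SNPs are dropped and
  counted in the exclusion report.
- `P1` and averaged `alpha` are clamped to [0, 1] against floating-point
  overshoot in the weighted average.
- All simulators accept `seed = NULL` to draw from the ambient RNG
  stream, which is how the harness derives every dataset from one seed.

## Limitations

The liftOver approximation ignores split mappings; the heritability
regression implements the core model but none of the released software's
auxiliary filters; the variational posterior is a factorized
approximation whose Bayes factors are conservative under the null; and
the validation evidence is simulation-based at desk scale, as discussed
above.
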