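#' Random-effects meta-analysis of estimates and standard errors
#'
#' DerSimonian-Laird pooling (via [metafor::rma()] with `method = "DL"`),
#' returning the pooled estimate, its standard error, and a one-sided
#' P-value testing whether the pooled estimate exceeds zero. A single study
#' is returned unchanged, since between-study heterogeneity is not
#' estimable.
#'
#' @param estimates,ses Equal-length numeric vectors; `ses` must be
#'   positive.
#' @return List with `estimate`, `se`, `p` (one-sided, greater than 0),
#'   and `k` (number of studies).
#' @export
meta_random_effects <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    .err("estimates and ses must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0)) .err("SEs must be positive")
  k <- length(estimates)
  if (k == 0L) .err("no studies supplied")
  if (k == 1L) {
    est <- estimates[1]; se <- ses[1]
  } else {
    fit <- metafor::rma(yi = estimates, sei = ses, method = "DL")
    est <- as.numeric(fit$beta); se <- fit$se
  }
  list(estimate = est, se = se,
       p = pnorm(est / se, lower.tail = FALSE), k = k)
}

#' Generalized Deming regression with per-observation error variances
#'
#' Errors-in-variables straight-line fit of `y` on `x` minimizing the
#' SE-weighted orthogonal residual sum
#' `sum_i (y_i - a - b x_i)^2 / (se_y_i^2 + b^2 se_x_i^2)`, with the
#' intercept profiled out in closed form and the slope found by a
#' deterministic angle-grid search refined by golden-section optimization.
#' Standard errors come from a leave-one-out jackknife.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param se_x,se_y Positive per-observation standard errors.
#' @return List with `slope`, `intercept`, `slope_se`, `intercept_se`.
#' @export
deming_fit <- function(x, y, se_x, se_y) {
  n <- length(x)
  if (n < 3) .err("Deming regression needs at least 3 points")
  if (length(y) != n || length(se_x) != n || length(se_y) != n)
    .err("x, y, se_x, se_y must have equal length")
  if (any(se_x <= 0) || any(se_y <= 0)) .err("SEs must be positive")
  if (var(x) == 0) .err("x has zero variance")
  est <- .deming_point(x, y, se_x, se_y)
  jack <- t(vapply(seq_len(n), function(i)
    .deming_point(x[-i], y[-i], se_x[-i], se_y[-i]), numeric(2)))
  jse <- sqrt((n - 1) / n * colSums(sweep(jack, 2, colMeans(jack))^2))
  list(slope = est[1], intercept = est[2],
       slope_se = jse[1], intercept_se = jse[2])
}

.deming_point <- function(x, y, se_x, se_y) {
  obj <- function(b) {
    w <- 1 / (se_y^2 + b^2 * se_x^2)
    a <- sum(w * (y - b * x)) / sum(w)
    sum(w * (y - a - b * x)^2)
  }
  # analytic gradient of the profiled objective (the intercept term drops
  # because sum(w r) = 0 at the profiled intercept)
  grad <- function(b) {
    w <- 1 / (se_y^2 + b^2 * se_x^2)
    a <- sum(w * (y - b * x)) / sum(w)
    r <- y - a - b * x
    sum(-2 * b * se_x^2 * w^2 * r^2 - 2 * w * r * x)
  }
  # coarse angle grid avoids local minima; slope = tan(angle)
  ang <- seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = 721)
  vals <- vapply(tan(ang), obj, numeric(1))
  i <- which.min(vals)
  lo <- tan(ang[max(1, i - 1)]); hi <- tan(ang[min(length(ang), i + 1)])
  b <- optimize(obj, c(lo, hi), tol = 1e-10)$minimum
  # polish to near machine precision on the stationarity condition
  eps <- 1e-6 * (1 + abs(b))
  if (is.finite(grad(b - eps)) && is.finite(grad(b + eps)) &&
      sign(grad(b - eps)) < 0 && sign(grad(b + eps)) > 0) {
    b <- uniroot(grad, c(b - eps, b + eps),
                 tol = 1e-14 * (1 + abs(b)))$root
  }
  w <- 1 / (se_y^2 + b^2 * se_x^2)
  a <- sum(w * (y - b * x)) / sum(w)
  c(unname(b), a)
}
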