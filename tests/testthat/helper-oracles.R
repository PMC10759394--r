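# Independent oracles, written from the definitions rather than reusing
# the package's code paths.

# multivariate normal log density via Cholesky
mvn_logpdf <- function(x, V) {
  ch <- chol(V)
  u <- backsolve(ch, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
}

# exact per-SNP posterior inclusion for the summary-statistic spike-and-
# slab model, by enumerating all 2^p sparsity patterns: under pattern g,
# betahat ~ N(0, S R S + M diag(g sigma2) M') with M = S R S^{-1}
exact_spike_slab <- function(bhat, se, R, pi, sigma2) {
  p <- length(bhat)
  S <- diag(se, p)
  Sigma <- S %*% R %*% S
  M <- S %*% R %*% diag(1 / se, p)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  logpost <- apply(configs, 1, function(g) {
    V <- Sigma + M %*% diag(g * sigma2, p) %*% t(M)
    mvn_logpdf(bhat, V) + sum(g * log(pi) + (1 - g) * log(1 - pi))
  })
  m <- max(logpost)
  w <- exp(logpost - m)
  list(inclusion = as.numeric(crossprod(configs, w / sum(w))),
       logml = m + log(sum(w)))
}

# DerSimonian-Laird pooling, straight from the formulas
dl_pool_oracle <- function(e, s) {
  w <- 1 / s^2
  k <- length(e)
  ybar <- sum(w * e) / sum(w)
  Q <- sum(w * (e - ybar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  wr <- 1 / (s^2 + tau2)
  c(est = sum(wr * e) / sum(wr), se = sqrt(1 / sum(wr)))
}

# closed-form Deming slope for a constant error-variance ratio
# delta = se_y^2 / se_x^2
deming_oracle <- function(x, y, delta) {
  xm <- x - mean(x); ym <- y - mean(y)
  sxx <- sum(xm^2); syy <- sum(ym^2); sxy <- sum(xm * ym)
  b <- (syy - delta * sxx + sqrt((syy - delta * sxx)^2 +
                                   4 * delta * sxy^2)) / (2 * sxy)
  c(slope = b, intercept = mean(y) - b * mean(x))
}

# upper-tail binomial probability by term-by-term summation
binom_tail_oracle <- function(k, n, p0) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# Cramer's V for a 2x2 table from the closed form
cramers_v_oracle <- function(x, y) {
  a <- as.numeric(sum(x == 1 & y == 1)); b <- as.numeric(sum(x == 1 & y == 0))
  cc <- as.numeric(sum(x == 0 & y == 1)); d <- as.numeric(sum(x == 0 & y == 0))
  n <- a + b + cc + d
  chi2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  sqrt(chi2 / n)
}

# LD scores by direct double-loop evaluation
ld_scores_oracle <- function(X, pos, chrom, A, window) {
  p <- ncol(X)
  out <- matrix(0, p, ncol(A))
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      if (chrom[j] != chrom[k] || abs(pos[j] - pos[k]) > window) next
      r2 <- cor(X[, j], X[, k])^2
      out[j, ] <- out[j, ] + r2 * A[k, ]
    }
  }
  out
}
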