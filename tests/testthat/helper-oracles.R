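# Independent brute-force oracles used to freeze expected values.

# BH step-up from the definition: sort, q_(i) = min_{j >= i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Hypergeometric upper tail P(X >= k) as a sum of pmf terms; numerators
# are exact integers for N <= 50 (well below 2^53), divided once.
hyper_upper_oracle <- function(k, N, K, n) {
  j <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided exact binomial sign test at p = 1/2 by pmf enumeration:
# sum of all outcome probabilities not exceeding that of the observed k.
sign_test_oracle <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  sum(pmf[pmf <= pmf[k + 1] + 1e-12])
}

# VIF by explicit per-column regression.
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, 0)
}

# Mahalanobis distance from the explicit quadratic form.
mahalanobis_oracle <- function(x) {
  ctr <- colMeans(x)
  Sinv <- solve(stats::cov(x))
  apply(x, 1, function(r) sqrt(drop(t(r - ctr) %*% Sinv %*% (r - ctr))))
}

# Per-probe OLS through the normal equations, one probe at a time.
ols_oracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  t(apply(y, 1, function(row) drop(XtXi %*% t(X) %*% row)))
}
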