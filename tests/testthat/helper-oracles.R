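# Independent brute-force oracles. Everything here avoids the package's own
# computational path: tails are summed term by term in log space, posteriors
# are normalized by trapezoid quadrature on dense grids, and HPD intervals
# come from exhaustive shortest-interval search.

# Unnormalized posterior kernel on the prevalence scale.
oracle_kernel <- function(gamma, k, n, alpha) {
  th <- alpha + gamma * (1 - alpha)
  th^k * (1 - th)^(n - k)
}

# Trapezoid-normalized density values on a grid.
oracle_density <- function(gamma, k, n, alpha, m = 200001) {
  g <- seq(0, 1, length.out = m)
  f <- oracle_kernel(g, k, n, alpha)
  z <- sum((f[-1] + f[-m]) / 2) * (g[2] - g[1])
  oracle_kernel(gamma, k, n, alpha) / z
}

# Posterior mean by quadrature.
oracle_posterior_mean <- function(k, n, alpha, m = 200001) {
  g <- seq(0, 1, length.out = m)
  f <- oracle_kernel(g, k, n, alpha)
  trap <- function(y) sum((y[-1] + y[-m]) / 2) * (g[2] - g[1])
  trap(g * f) / trap(f)
}

# CDF-grid quantile function, independent of qbeta.
oracle_quantile_fun <- function(k, n, alpha, m = 200001) {
  g <- seq(0, 1, length.out = m)
  f <- oracle_kernel(g, k, n, alpha)
  cdf <- cumsum((c(0, f[-m]) + f) / 2) * (g[2] - g[1])
  cdf <- cdf / cdf[m]
  approxfun(cdf, g, ties = "ordered", rule = 2)
}

# Brute-force shortest interval over a quantile grid.
oracle_hpdi <- function(k, n, alpha, mass, n_t = 4001) {
  qf <- oracle_quantile_fun(k, n, alpha)
  ts <- seq(0, 1 - mass, length.out = n_t)
  lo <- qf(ts)
  hi <- qf(ts + mass)
  i <- which.min(hi - lo)
  c(lo[i], hi[i])
}

# Upper binomial tail P(X >= k) by log-space term summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  j <- k:n
  lt <- lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

# Posterior P(delta > 0) for the paired model by exhaustive evaluation over
# a simplex grid (uniform prior); ties delta == 0 counted with half weight.
oracle_paired_p_greater <- function(counts, alpha1, alpha2, step = 0.02) {
  m <- round(1 / step)
  grid <- expand.grid(i = 0:m, j = 0:m, l = 0:m)
  grid <- grid[grid$i + grid$j + grid$l <= m, ]
  rho <- cbind(grid$i, grid$j, grid$l, m - grid$i - grid$j - grid$l) / m
  cp <- cbind(
    rho[, 1] + rho[, 2] * alpha2 + rho[, 3] * alpha1 + rho[, 4] * alpha1 * alpha2,
    rho[, 2] * (1 - alpha2) + rho[, 4] * alpha1 * (1 - alpha2),
    rho[, 3] * (1 - alpha1) + rho[, 4] * (1 - alpha1) * alpha2,
    rho[, 4] * (1 - alpha1) * (1 - alpha2))
  ll <- numeric(nrow(rho))
  for (c_i in which(counts > 0)) ll <- ll + counts[c_i] * log(cp[, c_i])
  w <- exp(ll - max(ll))
  delta <- rho[, 2] - rho[, 3]
  (sum(w[delta > 0]) + 0.5 * sum(w[delta == 0])) / sum(w)
}

# Random but valid (k, n, alpha) triples for property-style loops.
random_outcomes <- function(n_cases, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n_cases), function(i) {
      n <- sample(1:80, 1)
      alpha <- runif(1, 0.005, 0.3)
      k <- rbinom(1, n, runif(1))
      test_outcomes(k, n, alpha)
    })
  })
}
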