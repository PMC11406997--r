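# Shared fixtures and independent oracles used across the suite.

# Small, fast synthetic configuration for end-to-end tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_clusters = 120, core_fraction = 0.45, unique_fraction = 0.3,
             seed = seed, ...)
}

# Brute-force Procrustes oracle: numeric maximization of the matching
# correlation over rotation angle and reflection (2-D configurations,
# symmetric scaling), independent of the SVD solution.
bruteforce_m2 <- function(X, Y) {
  X <- scale(X, scale = FALSE); X <- X / sqrt(sum(X^2))
  Y <- scale(Y, scale = FALSE); Y <- Y / sqrt(sum(Y^2))
  match_corr <- function(theta, refl) {
    R <- matrix(c(cos(theta), sin(theta),
                  -refl * sin(theta), refl * cos(theta)), 2)
    sum(X * (Y %*% R))
  }
  best <- -Inf
  for (refl in c(1, -1)) {
    grid <- seq(0, 2 * pi, length.out = 361)
    vals <- vapply(grid, match_corr, numeric(1), refl = refl)
    th0 <- grid[which.max(vals)]
    opt <- stats::optimize(match_corr, c(th0 - 0.05, th0 + 0.05),
                           refl = refl, maximum = TRUE)
    best <- max(best, max(vals), opt$objective)
  }
  1 - max(best, 0)^2
}

# Exact one-sided Fisher p-values by explicit hypergeometric enumeration
# over the whole support of the 2x2 table [a b; d e].
enumerate_fisher <- function(a, b, d, e) {
  set_size <- a + b       # margin: items in the set
  cat_size <- a + d       # margin: items in the category
  total <- a + b + d + e
  support <- max(0, set_size + cat_size - total):min(set_size, cat_size)
  logp <- lchoose(cat_size, support) +
    lchoose(total - cat_size, set_size - support) -
    lchoose(total, set_size)
  p <- exp(logp)
  c(enrich = sum(p[support >= a]), deplete = sum(p[support <= a]))
}

# mean-1 lognormal noise with coefficient of variation cv
ln_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
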