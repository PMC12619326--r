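# Brute-force wrapped-normal density: plain sum over many wraps, independent
# of the package's truncation logic.
wn_bruteforce <- function(x, mu, sigma, period = 180, k = 50) {
  sapply(x, function(xx) {
    sum(stats::dnorm(xx - mu + (-k:k) * period, mean = 0, sd = sigma))
  })
}

# Small hand-rolled circular mean via optimization on the doubled circle,
# used as an independent cross-check of read-out code.
circ_mean_numeric <- function(support, mass) {
  obj <- function(m) sum(mass * (1 - cos((support - m) * pi / 90)))
  opt <- stats::optimize(obj, c(0, 180))
  opt$minimum %% 180
}

# Mixture log-likelihood evaluated with base-R densities only (oracle path).
oracle_mix_loglik <- function(x1, x2, pi1, mu1, s1, mu2, s2) {
  f <- pi1 * wn_bruteforce(x1, mu1[1], s1[1]) * stats::dnorm(x2, mu2[1], s2) +
    (1 - pi1) * wn_bruteforce(x1, mu1[2], s1[2]) * stats::dnorm(x2, mu2[2], s2)
  sum(log(f))
}

# Coarse grid-search maximizer of the two-component mixture likelihood:
# orientation means on a grid, sigmas on a coarse grid, temporal means and
# mixing weight pinned at the generative values.
grid_search_loglik <- function(x1, x2, mu_step = 2,
                               sigma_grid = c(12, 18, 24, 40, 60, 80),
                               mu2 = c(10, -10), s2 = 20) {
  mus <- seq(0, 180 - mu_step, by = mu_step)
  t1 <- stats::dnorm(x2, mu2[1], s2)
  t2 <- stats::dnorm(x2, mu2[2], s2)
  dens <- lapply(sigma_grid, function(s) {
    # rows: candidate means, cols: data points
    outer(mus, x1, function(m, x) wn_bruteforce_mat(x, m, s))
  })
  best <- -Inf
  for (a in seq_along(sigma_grid)) {
    A <- dens[[a]] * rep(t1, each = length(mus))
    for (b in seq_along(sigma_grid)) {
      B <- dens[[b]] * rep(t2, each = length(mus))
      for (i in seq_along(mus)) {
        ll <- rowSums(log(0.5 * rep(A[i, ], each = length(mus)) + 0.5 * B))
        m <- max(ll)
        if (m > best) best <- m
      }
    }
  }
  best
}

# vectorized wrapped-normal density for the grid search (x and m vectors)
wn_bruteforce_mat <- function(x, m, sigma, period = 180, k = 6) {
  out <- 0
  for (kk in -k:k) out <- out + stats::dnorm(x - m + kk * period, 0, sigma)
  out
}
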