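params_fast <- bayes_observer_params(grid_step = 1)

test_that("transition kernel: uniform limit, symmetry, peaked at center", {
  p0 <- bayes_observer_params(p_same = 0, grid_step = 1)
  k0 <- transition_kernel(33, p0)
  expect_equal(k0$mass, rep(1 / 180, 180), tolerance = 1e-12)

  k <- transition_kernel(90, params_fast)
  expect_equal(sum(k$mass), 1, tolerance = 1e-9)
  expect_equal(k$support[which.max(k$mass)], 90)
  # symmetry about the center for every grid offset
  for (d in c(1, 10, 45, 89)) {
    expect_equal(k$mass[match(90 + d, k$support)],
                 k$mass[match(90 - d, k$support)])
  }
  # peaked: mass at zero offset exceeds mass at 90-degree offset
  expect_gt(k$mass[match(90, k$support)], k$mass[match(0, k$support)])
})

test_that("prior propagation: identity on delta, fixed point on uniform, entropy grows", {
  # delta posterior -> prior equals the transition kernel at that center
  m <- rep(0, 180); m[46] <- 1   # delta at 45 deg on the 1-degree grid
  pr <- compute_prior(belief_grid(m, 1), params_fast)
  expect_equal(pr$mass, transition_kernel(45, params_fast)$mass,
               tolerance = 1e-12)

  u <- uniform_belief(1)
  expect_equal(compute_prior(u, params_fast)$mass, u$mass, tolerance = 1e-12)

  # convolution + uniform mixing cannot sharpen a belief
  set.seed(21)
  ent <- function(m) -sum(ifelse(m > 0, m * log(m), 0))
  for (i in 1:20) {
    b <- belief_grid(rexp(180), 1)
    expect_gte(ent(compute_prior(b, params_fast)$mass), ent(b$mass) - 1e-9)
  }

  expect_error(compute_prior(uniform_belief(0.5), params_fast), "grid mismatch")
})

test_that("posterior update matches an explicit product oracle and concentrates", {
  # uniform prior: posterior mean equals the measurement
  u <- uniform_belief(0.5)
  po <- posterior_update(71.3, 9, u)
  expect_equal(response_from_posterior(po), 71.3, tolerance = 0.02)

  # fine-grid oracle: explicit wrap-sum likelihood times prior, renormalized
  step <- 0.1
  sup <- seq(0, 180 - step, by = step)
  prior_mass <- wn_bruteforce(sup, 120, 30) ; prior_mass <- prior_mass / sum(prior_mass)
  pr <- belief_grid(prior_mass, step)
  po2 <- posterior_update(100, 6, pr)
  oracle <- wn_bruteforce(sup, 100, 6) * prior_mass
  oracle <- oracle / sum(oracle)
  expect_equal(po2$mass, oracle, tolerance = 1e-9)

  # a near-noiseless likelihood dominates any smooth prior
  po3 <- posterior_update(42, 0.1, pr)
  expect_equal(response_from_posterior(po3), 42, tolerance = 0.1)

  expect_error(posterior_update(10, 0, u), "positive")
})

test_that("posterior read-out is the circular mean and refines with the grid", {
  step <- 0.5
  sup <- seq(0, 180 - step, by = step)
  m <- rep(0, length(sup)); m[sup == 37] <- 1
  expect_equal(response_from_posterior(belief_grid(m, step)), 37)

  sym <- dwrapnorm(sup, 120, 14)
  expect_equal(response_from_posterior(belief_grid(sym, step)), 120,
               tolerance = 1e-6)

  # skewed two-bump posterior: agree with a high-resolution numerical mean
  dens <- function(x) 0.7 * dwrapnorm(x, 60, 8) + 0.3 * dwrapnorm(x, 95, 20)
  coarse <- belief_grid(dens(sup), step)
  fine_sup <- seq(0, 180 - 0.02, by = 0.02)
  fine <- dens(fine_sup); fine <- fine / sum(fine)
  ref <- circ_mean_numeric(fine_sup, fine)
  expect_equal(response_from_posterior(coarse), ref, tolerance = 0.05)
})

test_that("simulated observer is unbiased without a transition prior", {
  p0 <- bayes_observer_params(p_same = 0, grid_step = 1)
  s <- simulate_bayes_session(2e4, p0, seed = 9)
  b <- s$signed_bias[!is.na(s$signed_bias)]
  expect_lt(abs(mean(b)), 3 * sd(b) / sqrt(length(b)))
  # and per dissimilarity bin
  ad <- abs(s$delta_prev[!is.na(s$signed_bias)])
  for (lo in c(0, 30, 60)) {
    sel <- ad >= lo & ad < lo + 30
    expect_lt(abs(mean(b[sel])), 3 * sd(b[sel]) / sqrt(sum(sel)))
  }
})

test_that("observer simulation is reproducible and well-formed", {
  s1 <- simulate_bayes_session(300, params_fast, seed = 5)
  s2 <- simulate_bayes_session(300, params_fast, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$stimulus >= 0 & s1$stimulus < 180))
  expect_true(all(s1$response >= 0 & s1$response < 180))
  expect_equal(s1$signed_error, ori_diff(s1$response, s1$stimulus))
  expect_true(all(s1$noise_sigma %in% c(6, 9, 12)))
  expect_true(is.na(s1$signed_bias[1]))
})
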