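test_that("mixture density: term-by-term oracle, normalization, single-component limit", {
  th <- demix_params(pi1 = 0.3, mu_ori = c(80, 30), sigma_ori = c(10, 25),
                     sigma_temp = 20, dprime_temp = 1)
  # hand-computed two-term sum at a probe point
  probe <- mixture_density(50, 5, th)
  byhand <- 0.3 * wn_bruteforce(50, 80, 10) * dnorm(5, 10, 20) +
    0.7 * wn_bruteforce(50, 30, 25) * dnorm(5, -10, 20)
  expect_equal(probe, byhand, tolerance = 1e-12)

  # integrates to one over orientation period x temporal line
  inner <- function(x2) {
    sapply(x2, function(t2) {
      integrate(function(x1) mixture_density(x1, rep(t2, length(x1)), th),
                0, 180)$value
    })
  }
  total <- integrate(inner, -150, 150)$value
  expect_equal(total, 1, tolerance = 1e-4)

  # near-degenerate mixing weight reduces to one component
  th1 <- demix_params(pi1 = 1 - 1e-12, mu_ori = c(80, 30),
                      sigma_ori = c(10, 25))
  expect_equal(mixture_density(50, 5, th1),
               wn_bruteforce(50, 80, 10) * dnorm(5, 10, 20),
               tolerance = 1e-9)
})

test_that("sampling honors mixing weight and per-component moments", {
  th <- demix_params(pi1 = 0.5, mu_ori = c(100, 40), sigma_ori = c(0.01, 0.01))
  m <- sample_measurements(th, seed = 3)
  expect_length(m$x_ori, th$n_meas)
  near <- pmin(abs(ori_diff(m$x_ori, 100)), abs(ori_diff(m$x_ori, 40)))
  expect_true(all(near < 1))  # orientation samples cluster at the two means

  th2 <- demix_params(pi1 = 0.3, n_meas = 4000)
  m2 <- sample_measurements(th2, seed = 4)
  # component frequency within 3 binomial SEs of pi1
  f <- mean(m2$component_truth == 1L)
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
  # temporal sample means per true component near the generative means
  for (j in 1:2) {
    xt <- m2$x_temp[m2$component_truth == j]
    expect_lt(abs(mean(xt) - th2$mu_temp[j]), 3 * 20 / sqrt(length(xt)))
  }
})

test_that("EM recovers well-separated components and dominates the truth", {
  th <- demix_params(mu_ori = c(120, 30), sigma_ori = c(5, 5), n_meas = 1000)
  m <- sample_measurements(th, seed = 11)
  f <- em_fit(m, n_restarts = 10, seed = 12)
  expect_true(f$converged)
  expect_true(f$monotone)
  expect_lt(abs(ori_diff(f$mu_ori[1], 120)), 2)
  expect_lt(abs(ori_diff(f$mu_ori[2], 30)), 2)
  # component labels ordered by temporal mean, larger first
  expect_gt(f$mu_temp[1], f$mu_temp[2])
  # MLE dominance on the sample
  expect_gte(f$loglik, demix_loglik(m, th) - 1e-6)
})

test_that("EM is deterministic given a seed and handles identical components", {
  th <- demix_params(mu_ori = c(60, 60), sigma_ori = c(12, 12), n_meas = 400)
  m <- sample_measurements(th, seed = 21)
  f1 <- em_fit(m, n_restarts = 5, seed = 22)
  f2 <- em_fit(m, n_restarts = 5, seed = 22)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$mu_ori, f2$mu_ori)
  # identical components: both orientation means near the common truth
  expect_lt(abs(ori_diff(f1$mu_ori[1], 60)), 3)
  expect_lt(abs(ori_diff(f1$mu_ori[2], 60)), 3)
})

test_that("EM matches a brute-force grid-search maximizer on small instances", {
  set.seed(31)
  for (i in 1:5) {
    dd <- runif(1, 10, 80)
    mu1 <- runif(1, 0, 180)
    th <- demix_params(mu_ori = c(mu1, wrap_ori(mu1 + dd)),
                       sigma_ori = c(24, 60), n_meas = 50)
    m <- sample_measurements(th)
    f <- em_fit(m, n_restarts = 20, seed = 100 + i)
    gll <- grid_search_loglik(m$x_ori, m$x_temp)
    expect_gte(f$loglik, gll - 0.1)
  }
})

test_that("parameter recovery sharpens with more measurements", {
  set.seed(51)
  rmse_at <- function(n) {
    errs <- replicate(30, {
      th <- demix_params(mu_ori = c(90, 30), sigma_ori = c(18, 45), n_meas = n)
      # a few slow-converging overlapping fits are fine for an RMSE contrast
      f <- suppressWarnings(em_fit(sample_measurements(th), n_restarts = 5,
                                   tol = 1e-6, max_iter = 200))
      ori_diff(f$mu_ori[1], 90)
    })
    sqrt(mean(errs^2))
  }
  r50 <- rmse_at(50); r400 <- rmse_at(400)
  expect_lt(r400, r50)
})

test_that("response read-out picks the temporally later component", {
  mk <- function(mu_temp, mu_ori) {
    structure(list(pi1 = 0.5, mu_ori = mu_ori, sigma_ori = c(10, 10),
                   mu_temp = mu_temp, sigma_temp = 20, loglik = -1,
                   converged = TRUE), class = "demix_fit")
  }
  # read-out rule and its swap (labels arrive already temporally ordered)
  expect_equal(dm_response(mk(c(10, -10), c(40, 120))), 40)
  expect_equal(dm_response(mk(c(5, -3), c(120, 40))), 120)
  expect_warning(dm_response(mk(c(4, 4), c(70, 10))), "tie")
})

test_that("demixing grid: zero difference gives zero mean bias, reproducibly", {
  g <- simulate_dm_grid(sigma11 = 24, sigma12 = 60, diffs = 0,
                        n_trials = 200, n_restarts = 5, seed = 61)
  expect_lt(abs(g$mean_bias), 3 * g$sd_bias / sqrt(g$n))
  g2 <- simulate_dm_grid(sigma11 = 24, sigma12 = 60, diffs = 0,
                         n_trials = 200, n_restarts = 5, seed = 61)
  expect_identical(g, g2)
})
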