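#' Parameters of the Bayesian ideal observer
#'
#' The observer assumes consecutive stimuli are related as in natural scenes:
#' with probability `p_same` the orientation changes smoothly according to a
#' peaked transition kernel `exp(-|delta|^gamma / (2 sigma_s^2))`, otherwise it
#' is redrawn uniformly. Defaults are the natural-statistics values sigma_s =
#' 16.9 deg, gamma = 2.6, p_same = 0.64. Noise levels are per-trial sensory
#' SDs in orientation degrees; all circularity is handled on the 180-degree
#' orientation circle.
#'
#' @param sigma_s Transition-kernel width in degrees (> 0).
#' @param gamma Kernel steepness exponent (> 0).
#' @param p_same Probability of a smooth transition, in `[0, 1]`.
#' @param grid_step Belief-grid resolution in degrees; must divide 180.
#' @param noise_levels Sensory noise SDs (degrees) assigned randomly per trial.
#' @return An object of class `bayes_observer_params`.
#' @export
bayes_observer_params <- function(sigma_s = 16.9, gamma = 2.6, p_same = 0.64,
                                  grid_step = 0.5, noise_levels = c(6, 9, 12)) {
  stopifnot(sigma_s > 0, gamma > 0, p_same >= 0, p_same <= 1,
            grid_step > 0, all(noise_levels > 0))
  if (abs(180 / grid_step - round(180 / grid_step)) > 1e-9) {
    stop("`grid_step` must divide 180", call. = FALSE)
  }
  structure(list(sigma_s = sigma_s, gamma = gamma, p_same = p_same,
                 grid_step = grid_step, noise_levels = noise_levels),
            class = "bayes_observer_params")
}

#' @export
print.bayes_observer_params <- function(x, ...) {
  cat("Bayesian observer parameters\n")
  cat(sprintf("  sigma_s = %.3g deg, gamma = %.3g, p_same = %.3g\n",
              x$sigma_s, x$gamma, x$p_same))
  cat(sprintf("  grid_step = %.3g deg (%d points), noise levels: %s deg\n",
              x$grid_step, round(180 / x$grid_step),
              paste(x$noise_levels, collapse = ", ")))
  invisible(x)
}

#' Construct a belief grid
#'
#' A discretized probability distribution over orientation: a uniform grid of
#' support points on `[0, 180)` with non-negative masses summing to one.
#'
#' @param mass Numeric vector of non-negative masses; will be normalized.
#' @param grid_step Grid resolution in degrees.
#' @return An object of class `belief_grid` with fields `support` and `mass`.
#' @export
belief_grid <- function(mass, grid_step) {
  n <- round(180 / grid_step)
  if (length(mass) != n) stop("`mass` length must equal 180/grid_step", call. = FALSE)
  if (any(mass < 0) || any(!is.finite(mass))) {
    stop("`mass` must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(mass)
  if (tot <= 0) stop("`mass` must have positive total", call. = FALSE)
  structure(list(support = seq(0, 180 - grid_step, by = grid_step),
                 mass = mass / tot, grid_step = grid_step),
            class = "belief_grid")
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf("Belief grid: %d points, step %.3g deg, circular mean %.2f deg\n",
              length(x$mass), x$grid_step, response_from_posterior(x)))
  invisible(x)
}

#' Uniform belief grid
#' @param grid_step Grid resolution in degrees.
#' @return A uniform `belief_grid`.
#' @export
uniform_belief <- function(grid_step = 0.5) {
  n <- round(180 / grid_step)
  belief_grid(rep(1 / n, n), grid_step)
}

# Unnormalized peaked transition profile on a vector of signed differences.
transition_profile <- function(delta, sigma_s, gamma) {
  exp(-abs(delta)^gamma / (2 * sigma_s^2))
}

#' Transition kernel of the Bayesian observer
#'
#' Mixture of a peaked component centred on `center` and a circular uniform:
#' `p_same * C + (1 - p_same) * U`, normalized on the grid. `C` is
#' proportional to `exp(-|delta|^gamma / (2 sigma_s^2))` where `delta` is the
#' acute orientation difference to `center`.
#'
#' @param center Orientation (degrees) the kernel is centred on.
#' @param params A [bayes_observer_params()] object.
#' @return A `belief_grid`.
#' @export
transition_kernel <- function(center, params) {
  stopifnot(inherits(params, "bayes_observer_params"))
  step <- params$grid_step
  support <- seq(0, 180 - step, by = step)
  delta <- ori_diff(support, wrap_ori(center))
  c_mass <- transition_profile(delta, params$sigma_s, params$gamma)
  c_mass <- c_mass / sum(c_mass)
  n <- length(support)
  belief_grid(params$p_same * c_mass + (1 - params$p_same) / n, step)
}

#' One-step prediction: convolve a posterior with the transition kernel
#'
#' Propagates yesterday's belief forward through the assumed environmental
#' dynamics: the posterior is circularly convolved with the peaked transition
#' component and mixed with the uniform component. Computed by FFT on the
#' grid.
#'
#' @param previous_posterior A `belief_grid`.
#' @param params A [bayes_observer_params()] object with matching `grid_step`.
#' @return The predictive prior as a `belief_grid`.
#' @export
compute_prior <- function(previous_posterior, params) {
  stopifnot(inherits(previous_posterior, "belief_grid"),
            inherits(params, "bayes_observer_params"))
  if (abs(previous_posterior$grid_step - params$grid_step) > 1e-9) {
    stop("grid mismatch between posterior and params", call. = FALSE)
  }
  step <- params$grid_step
  support <- seq(0, 180 - step, by = step)
  kern <- transition_profile(ori_diff(support, 0), params$sigma_s, params$gamma)
  kern <- kern / sum(kern)
  n <- length(support)
  conv <- Re(stats::fft(stats::fft(previous_posterior$mass) * stats::fft(kern),
                        inverse = TRUE)) / n
  conv <- pmax(conv, 0)
  belief_grid(params$p_same * conv / sum(conv) + (1 - params$p_same) / n, step)
}

#' Bayesian measurement update
#'
#' Multiplies the prior pointwise by a wrapped-normal likelihood centred on
#' the sensory measurement and renormalizes.
#'
#' @param measurement Measured orientation in degrees.
#' @param noise_sigma Sensory noise SD in degrees (> 0).
#' @param prior A `belief_grid`.
#' @return The posterior `belief_grid`.
#' @export
posterior_update <- function(measurement, noise_sigma, prior) {
  stopifnot(inherits(prior, "belief_grid"))
  if (!is.finite(noise_sigma) || noise_sigma <= 0) {
    stop("`noise_sigma` must be positive", call. = FALSE)
  }
  lik <- dwrapnorm(prior$support, mu = wrap_ori(measurement), sigma = noise_sigma)
  prod <- lik * prior$mass
  if (sum(prod) <= 0 || !all(is.finite(prod))) {
    stop("degenerate posterior: likelihood-prior product underflowed", call. = FALSE)
  }
  belief_grid(prod, prior$grid_step)
}

#' Posterior read-out: circular mean of a belief grid
#'
#' The observer responds with the circular mean of its posterior, computed on
#' the doubled-angle circle and mapped back to `[0, 180)`.
#'
#' @param post A `belief_grid`.
#' @return Orientation in degrees.
#' @export
response_from_posterior <- function(post) {
  stopifnot(inherits(post, "belief_grid"))
  m <- circ_weighted_mean(post$support, post$mass)
  if (is.na(m)) stop("posterior circular mean undefined (zero resultant)", call. = FALSE)
  m
}

#' Simulate a session of the Bayesian observer
#'
#' Sequential simulation: stimuli are drawn uniformly on `[0, 180)`; each
#' trial's measurement is the stimulus plus wrapped-normal noise at a level
#' drawn i.i.d. from `params$noise_levels`; the prior is uniform on trial one
#' and thereafter the previous posterior convolved with the transition kernel;
#' the response is the posterior circular mean. The signed bias is the signed
#' error multiplied by the sign of the distance to the previous stimulus, so
#' positive values indicate attraction toward the preceding trial.
#'
#' @param n_trials Number of trials (>= 2).
#' @param params A [bayes_observer_params()] object.
#' @param seed Integer seed; all randomness in the session flows from it.
#' @return A data.frame with one row per trial: `trial`, `stimulus`,
#'   `measurement`, `response`, `noise_sigma`, `prev_stimulus`,
#'   `prev_noise_sigma`, `delta_prev` (signed acute difference previous minus
#'   current stimulus), `signed_error`, `signed_bias`. `signed_bias` is `NA`
#'   on trial one and on trials whose `delta_prev` is exactly 0 or -90.
#' @export
simulate_bayes_session <- function(n_trials, params = bayes_observer_params(),
                                   seed = 1L) {
  stopifnot(inherits(params, "bayes_observer_params"), n_trials >= 2)
  set.seed(seed)
  step <- params$grid_step
  n <- round(180 / step)
  support <- seq(0, 180 - step, by = step)

  # precompute: fft of the peaked transition kernel, and for each noise level
  # a wrapped-normal likelihood profile indexed by grid offset
  kern <- transition_profile(ori_diff(support, 0), params$sigma_s, params$gamma)
  kern <- kern / sum(kern)
  fk <- stats::fft(kern)
  lev <- params$noise_levels
  lik_bank <- lapply(lev, function(s) dwrapnorm(support, mu = 0, sigma = s))
  cos2 <- cos(support * pi / 90)
  sin2 <- sin(support * pi / 90)

  stimulus <- stats::runif(n_trials, 0, 180)
  noise_idx <- sample.int(length(lev), n_trials, replace = TRUE)
  noise_sigma <- lev[noise_idx]
  measurement <- (stimulus + stats::rnorm(n_trials, 0, noise_sigma)) %% 180

  response <- numeric(n_trials)
  post <- rep(1 / n, n)
  for (t in seq_len(n_trials)) {
    if (t == 1L) {
      prior <- rep(1 / n, n)
    } else {
      conv <- Re(stats::fft(stats::fft(post) * fk, inverse = TRUE)) / n
      conv <- pmax(conv, 0)
      prior <- params$p_same * conv / sum(conv) + (1 - params$p_same) / n
    }
    # likelihood: bank profile rolled to the measurement's nearest grid point
    mi <- (round(measurement[t] / step)) %% n  # 0-based offset
    prof <- lik_bank[[noise_idx[t]]]
    idx <- ((seq_len(n) - 1L - mi) %% n) + 1L
    post <- prior * prof[idx]
    s <- sum(post)
    if (s <= 0) stop("degenerate posterior during simulation", call. = FALSE)
    post <- post / s
    cbar <- sum(post * cos2); sbar <- sum(post * sin2)
    response[t] <- (atan2(sbar, cbar) * 90 / pi) %% 180
  }

  prev_stimulus <- c(NA, stimulus[-n_trials])
  prev_noise <- c(NA, noise_sigma[-n_trials])
  signed_error <- ori_diff(response, stimulus)
  delta_prev <- rep(NA_real_, n_trials)
  delta_prev[-1] <- ori_diff(prev_stimulus[-1], stimulus[-1])
  sgn <- sign(delta_prev)
  signed_bias <- signed_error * sgn
  signed_bias[!is.na(delta_prev) & (delta_prev == 0 | delta_prev == -90)] <- NA

  data.frame(trial = seq_len(n_trials), stimulus = stimulus,
             measurement = measurement, response = response,
             noise_sigma = noise_sigma, prev_stimulus = prev_stimulus,
             prev_noise_sigma = prev_noise, delta_prev = delta_prev,
             signed_error = signed_error, signed_bias = signed_bias)
}

#' Peak attraction of an observer bias curve
#'
#' Kernel-smoothed mean signed bias as a function of absolute dissimilarity to
#' the previous stimulus, maximized over 0-90 degrees. Used to summarize
#' simulated sessions into one attraction amplitude per noise condition.
#'
#' @param delta Absolute dissimilarities in degrees.
#' @param bias Signed biases in degrees (positive = attraction).
#' @param bandwidth Gaussian kernel SD in degrees.
#' @param diffs Evaluation grid, default `0:90`.
#' @return A list with `peak` (max smoothed bias, degrees), `peak_at`
#'   (dissimilarity of the maximum) and `curve` (data.frame `diff`, `value`).
#' @export
peak_attraction <- function(delta, bias, bandwidth = 10, diffs = 0:90) {
  keep <- is.finite(delta) & is.finite(bias)
  delta <- abs(delta[keep]); bias <- bias[keep]
  if (length(bias) == 0L) stop("no usable trials", call. = FALSE)
  val <- vapply(diffs, function(d) {
    w <- exp(-((delta - d)^2) / (2 * bandwidth^2))
    sum(w * bias) / sum(w)
  }, numeric(1))
  i <- which.max(val)
  list(peak = val[i], peak_at = diffs[i],
       curve = data.frame(diff = diffs, value = val))
}
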