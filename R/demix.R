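#' Generative parameters of the demixing model
#'
#' The demixing model assumes each sensory measurement arises from one of two
#' sources: the current stimulus or the previous one. A measurement is
#' bivariate: an orientation (wrapped normal on the 180-degree circle) and a
#' value on a non-circular "temporal" dimension (normal) that lets the
#' observer tell the sources apart. Temporal means are placed symmetrically
#' at `+/- dprime_temp * sigma_temp / 2`, the current source later (larger).
#'
#' Defaults are the average-case simulation settings: equal mixing weights,
#' shared temporal SD 20 with temporal d-prime 1, and N = 100 measurements.
#'
#' @param pi1 Mixing weight of the current source, in (0, 1).
#' @param mu_ori Length-2 orientation means (degrees): current, previous.
#' @param sigma_ori Length-2 orientation SDs (degrees): current, previous.
#' @param sigma_temp Shared temporal SD.
#' @param dprime_temp Temporal discriminability `(mu_temp1 - mu_temp2) / sigma_temp`.
#' @param n_meas Number of measurements per trial.
#' @return An object of class `demix_params` (also carries `mu_temp`).
#' @export
demix_params <- function(pi1 = 0.5, mu_ori = c(90, 45),
                         sigma_ori = c(24, 60), sigma_temp = 20,
                         dprime_temp = 1, n_meas = 100) {
  stopifnot(pi1 > 0, pi1 < 1, length(mu_ori) == 2, length(sigma_ori) == 2,
            all(sigma_ori > 0), sigma_temp > 0, n_meas >= 1)
  half <- dprime_temp * sigma_temp / 2
  structure(list(pi1 = pi1, mu_ori = wrap_ori(mu_ori),
                 mu_temp = c(half, -half), sigma_ori = sigma_ori,
                 sigma_temp = sigma_temp, dprime_temp = dprime_temp,
                 n_meas = as.integer(n_meas)),
            class = "demix_params")
}

#' @export
print.demix_params <- function(x, ...) {
  cat("Demixing-model parameters (component 1 = current, 2 = previous)\n")
  cat(sprintf("  pi1 = %.3g; mu_ori = (%.1f, %.1f) deg; sigma_ori = (%.1f, %.1f) deg\n",
              x$pi1, x$mu_ori[1], x$mu_ori[2], x$sigma_ori[1], x$sigma_ori[2]))
  cat(sprintf("  mu_temp = (%.1f, %.1f), sigma_temp = %.1f (d' = %.2f), N = %d\n",
              x$mu_temp[1], x$mu_temp[2], x$sigma_temp, x$dprime_temp, x$n_meas))
  invisible(x)
}

#' Two-component mixture density of a measurement
#'
#' Evaluates `sum_j pi_j f_WN(x1; mu_ori_j, sigma_ori_j) f_N(x2; mu_temp_j,
#' sigma_temp)` for a bivariate measurement (orientation, temporal value).
#'
#' @param x1 Orientation component(s) in degrees.
#' @param x2 Temporal component(s), same length as `x1`.
#' @param theta A [demix_params()] object.
#' @return Mixture density values.
#' @export
mixture_density <- function(x1, x2, theta) {
  stopifnot(inherits(theta, "demix_params"), length(x1) == length(x2))
  theta$pi1 *
    dwrapnorm(x1, theta$mu_ori[1], theta$sigma_ori[1]) *
    stats::dnorm(x2, theta$mu_temp[1], theta$sigma_temp) +
  (1 - theta$pi1) *
    dwrapnorm(x1, theta$mu_ori[2], theta$sigma_ori[2]) *
    stats::dnorm(x2, theta$mu_temp[2], theta$sigma_temp)
}

#' Sample a set of sensory measurements from the demixing model
#'
#' Each measurement's source is Bernoulli(`pi1`); given the source the
#' orientation and temporal components are drawn independently.
#'
#' @param theta A [demix_params()] object.
#' @param seed Optional integer seed.
#' @return A list of class `measurement_set`: `x_ori`, `x_temp`,
#'   `component_truth` (1 = current, 2 = previous; generation bookkeeping).
#' @export
sample_measurements <- function(theta, seed = NULL) {
  stopifnot(inherits(theta, "demix_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- theta$n_meas
  comp <- ifelse(stats::runif(n) < theta$pi1, 1L, 2L)
  x_ori <- rwrapnorm(n, theta$mu_ori[comp], theta$sigma_ori[comp])
  x_temp <- stats::rnorm(n, theta$mu_temp[comp], theta$sigma_temp)
  structure(list(x_ori = x_ori, x_temp = x_temp, component_truth = comp),
            class = "measurement_set")
}

#' Maximum-likelihood demixing by multi-restart EM
#'
#' Fits the two-component orientation-by-time mixture by
#' expectation-maximization from random responsibility initializations,
#' keeping the best log-likelihood across restarts. The orientation M-step
#' uses the circular (doubled-angle) mean and the resultant-length-to-sigma
#' inversion of the wrapped normal; the temporal M-step uses linear means
#' with a pooled SD shared across components. Orientation and temporal SDs
#' are floored (defaults 0.5 deg / 0.5) to prevent component collapse.
#' Component labels are resolved so the temporally later source (larger
#' fitted temporal mean) is component 1.
#'
#' @param data A `measurement_set` (or list with `x_ori`, `x_temp`).
#' @param n_restarts Number of random initializations (default 50).
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Optional integer seed for the random initializations.
#' @param pin_pi If `TRUE`, fix the mixing weight at `pi_fixed` instead of
#'   estimating it.
#' @param pi_fixed Pinned mixing weight when `pin_pi = TRUE`.
#' @param sigma_floor_ori,sigma_floor_temp SD floors.
#' @return An object of class `demix_fit` with the estimated parameters
#'   (`pi1`, `mu_ori`, `sigma_ori`, `mu_temp`, `sigma_temp`), `loglik`,
#'   `converged`, `n_restarts_used`, `degenerate` (an SD hit its floor) and
#'   `monotone` (no EM run decreased its log-likelihood by more than 0.05
#'   units; the orientation M-step is an approximation to the exact
#'   wrapped-normal MLE, so decreases below that slack can occur).
#' @export
em_fit <- function(data, n_restarts = 50, tol = 1e-8, max_iter = 500,
                   seed = NULL, pin_pi = FALSE, pi_fixed = 0.5,
                   sigma_floor_ori = 0.5, sigma_floor_temp = 0.5) {
  x1 <- data$x_ori
  x2 <- data$x_temp
  n <- length(x1)
  stopifnot(n >= 4, length(x2) == n, n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  init <- matrix(stats::runif(n * n_restarts), nrow = n)
  res <- dm_em_cpp(x1, x2, init, tol, as.integer(max_iter),
                   sigma_floor_ori, sigma_floor_temp, pin_pi, pi_fixed)
  if (res$n_converged == 0L) {
    warning("no EM restart converged; returning best partial fit", call. = FALSE)
  }
  structure(res, class = "demix_fit")
}

#' @export
print.demix_fit <- function(x, ...) {
  cat("Demixing-model fit (component 1 = temporally later)\n")
  cat(sprintf("  mu_ori = (%.2f, %.2f) deg, sigma_ori = (%.2f, %.2f) deg\n",
              x$mu_ori[1], x$mu_ori[2], x$sigma_ori[1], x$sigma_ori[2]))
  cat(sprintf("  mu_temp = (%.2f, %.2f), sigma_temp = %.2f, pi1 = %.3f\n",
              x$mu_temp[1], x$mu_temp[2], x$sigma_temp, x$pi1))
  cat(sprintf("  loglik = %.4f; %d/%d restarts converged%s\n",
              x$loglik, x$n_converged, x$n_restarts_used,
              if (isTRUE(x$degenerate)) "; degenerate (SD at floor)" else ""))
  invisible(x)
}

#' Log-likelihood of a parameter set on a measurement set
#'
#' Convenience for comparing fits against the generating truth or against an
#' independent maximizer.
#'
#' @param data A `measurement_set`.
#' @param theta A `demix_params` or `demix_fit` (needs `pi1`, `mu_ori`,
#'   `sigma_ori`, `mu_temp`, `sigma_temp`).
#' @return Scalar log-likelihood.
#' @export
demix_loglik <- function(data, theta) {
  f <- theta$pi1 *
    dwrapnorm(data$x_ori, theta$mu_ori[1], theta$sigma_ori[1]) *
    stats::dnorm(data$x_temp, theta$mu_temp[1], theta$sigma_temp) +
    (1 - theta$pi1) *
    dwrapnorm(data$x_ori, theta$mu_ori[2], theta$sigma_ori[2]) *
    stats::dnorm(data$x_temp, theta$mu_temp[2], theta$sigma_temp)
  sum(log(pmax(f, 1e-300)))
}

#' Demixing-model response read-out
#'
#' The behavioral response is the estimated orientation mean of the component
#' with the higher fitted temporal mean (the source judged most recent).
#' Exact temporal ties are broken toward component 1 with a warning.
#'
#' @param fit A `demix_fit`.
#' @return Orientation in degrees.
#' @export
dm_response <- function(fit) {
  stopifnot(inherits(fit, "demix_fit"))
  if (fit$mu_temp[1] == fit$mu_temp[2]) {
    warning("tied temporal means; tie broken toward component 1", call. = FALSE)
  }
  # labels are already ordered with the larger temporal mean first
  fit$mu_ori[[1]]
}

#' Simulate the demixing model over a noise-by-dissimilarity grid
#'
#' For every combination of current-item orientation noise (`sigma11`),
#' previous-item orientation noise (`sigma12`) and orientation difference
#' (`diffs`), simulates `n_trials` trials: the current orientation is drawn
#' uniformly, the previous orientation sits at the required difference in a
#' random direction, a measurement set is sampled, the mixture is refit by EM
#' and the response read out. The response error relative to the true current
#' orientation, signed by the direction of the previous item, gives the
#' serial-dependence bias (positive = attraction toward the previous item).
#' Noise pairs are simulated with common random numbers (shared stimuli,
#' component assignments, standardized noise draws and EM initializations
#' per difference-by-trial unit), so comparisons across noise levels share
#' their Monte-Carlo error.
#'
#' @param sigma11 Vector of current-item orientation SDs (degrees).
#' @param sigma12 Vector of previous-item orientation SDs (degrees).
#' @param diffs Vector of orientation differences (degrees, 0-90).
#' @param n_trials Trials per cell.
#' @param n_restarts EM restarts per trial.
#' @param sigma_temp,dprime_temp,pi1,n_meas Generative settings (defaults:
#'   shared temporal SD 20, d-prime 1, equal weights, 100 measurements).
#' @param tol,max_iter EM settings (looser defaults than [em_fit()], sized
#'   for large grids).
#' @param exclude_outliers Apply the behavioral pipeline's outlier rule to
#'   the simulated responses: within each noise pair, trials whose absolute
#'   error exceeds `outlier_sd_mult` circular SDs (pooled over the
#'   difference grid) are excluded before aggregating. This mirrors how
#'   model predictions are put through the same procedure as real data, and
#'   removes component-mislabeling trials whose full-magnitude errors would
#'   otherwise dominate the mean.
#' @param outlier_sd_mult Outlier threshold in circular SD units.
#' @param seed Integer seed; all randomness flows from it.
#' @return A data.frame with one row per (sigma11, sigma12, diff) cell:
#'   `mean_bias` (degrees), `mean_asym` (mean sign of bias), `sd_bias`, `n`
#'   (trials retained), `n_excluded`, `n_trials_converged` (retained trials
#'   with at least one converged restart).
#' @export
simulate_dm_grid <- function(sigma11 = c(12, 16, 20, 24, 28),
                             sigma12 = c(40, 60, 80),
                             diffs = seq(5, 85, by = 10),
                             n_trials = 500, n_restarts = 10,
                             sigma_temp = 20, dprime_temp = 1, pi1 = 0.5,
                             n_meas = 100, tol = 1e-5, max_iter = 150,
                             exclude_outliers = TRUE, outlier_sd_mult = 3,
                             seed = 1L) {
  stopifnot(length(sigma11) >= 1, length(sigma12) >= 1, length(diffs) >= 1)
  set.seed(seed)
  half <- dprime_temp * sigma_temp / 2
  pairs <- expand.grid(sigma11 = sigma11, sigma12 = sigma12,
                       KEEP.OUT.ATTRS = FALSE)
  np <- nrow(pairs)
  # common random numbers: every (difference, trial) unit reuses the same
  # stimuli, directions, component assignments, standardized noise draws and
  # EM initializations across all noise pairs, so that comparisons between
  # noise levels share their Monte-Carlo error; each pair's marginal
  # distribution is exactly the model's
  err_all <- dir_all <- conv_all <-
    replicate(np, vector("list", length(diffs)), simplify = FALSE)
  for (di in seq_along(diffs)) {
    dd <- diffs[di]
    mu11 <- stats::runif(n_trials, 0, 180)
    dir <- sample(c(-1, 1), n_trials, replace = TRUE)
    comp <- matrix(stats::runif(n_meas * n_trials) < pi1, nrow = n_meas)
    z1 <- matrix(stats::rnorm(n_meas * n_trials), nrow = n_meas)
    z2 <- matrix(stats::rnorm(n_meas * n_trials), nrow = n_meas)
    init <- matrix(stats::runif(n_meas * n_restarts * n_trials),
                   nrow = n_meas)
    mu12 <- wrap_ori(mu11 + dir * dd)
    mu_t <- ifelse(comp, half, -half)
    mu_o <- ifelse(comp, rep(mu11, each = n_meas), rep(mu12, each = n_meas))
    x2 <- mu_t + sigma_temp * z2
    for (pi_ in seq_len(np)) {
      sd_o <- ifelse(comp, pairs$sigma11[pi_], pairs$sigma12[pi_])
      x1 <- (mu_o + sd_o * z1) %% 180
      fit <- dm_cell_cpp(x1, x2, init, as.integer(n_restarts), tol,
                         as.integer(max_iter), 0.5, 0.5, FALSE, pi1)
      err_all[[pi_]][[di]] <- ori_diff(fit$response, mu11)
      dir_all[[pi_]][[di]] <- dir
      conv_all[[pi_]][[di]] <- fit$n_converged > 0
    }
  }
  out <- vector("list", np * length(diffs))
  oi <- 1L
  for (pi_ in seq_len(np)) {
    # behavioral outlier rule, pooled over the difference grid per noise pair
    if (exclude_outliers) {
      csd <- circ_mean_sd(unlist(err_all[[pi_]]) %% 180)$sd
      thr <- outlier_sd_mult * csd
    } else {
      thr <- Inf
    }
    for (di in seq_along(diffs)) {
      err <- err_all[[pi_]][[di]]; dir <- dir_all[[pi_]][[di]]
      keep <- abs(err) <= thr
      bias <- err[keep] * dir[keep]
      out[[oi]] <- data.frame(
        sigma11 = pairs$sigma11[pi_], sigma12 = pairs$sigma12[pi_],
        diff = diffs[di],
        mean_bias = mean(bias), mean_asym = mean(sign(bias)),
        sd_bias = stats::sd(bias), n = sum(keep),
        n_excluded = sum(!keep),
        n_trials_converged = sum(conv_all[[pi_]][[di]][keep]))
      oi <- oi + 1L
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sigma11, res$sigma12, res$diff), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Serial-dependence amplitude per noise pair from a demixing-model grid
#'
#' Summarizes a [simulate_dm_grid()] result into per-(current-noise,
#' previous-noise) amplitudes, two ways:
#'
#' * `amplitude` — the mean signed bias averaged over the whole
#'   orientation-difference grid (trial-weighted). This is the headline
#'   magnitude statistic: like the behavioral mean-bias measure it counts
#'   repulsive regions of the curve against attractive ones, which is what
#'   makes the attraction-to-repulsion shift at matched noise levels
#'   visible as a net decrease.
#' * `peak` / `peak_at` — the maximum of the curve after kernel smoothing
#'   across the difference grid (same Gaussian kernel as the behavioral
#'   pipeline; smoothing keeps per-cell Monte-Carlo noise from inflating a
#'   raw maximum), and its location.
#'
#' @param grid A data.frame from [simulate_dm_grid()].
#' @param bandwidth Gaussian kernel SD in degrees for the peak statistic
#'   (default 10, as in the behavioral analysis). `0` disables smoothing.
#' @param diffs Evaluation grid for the smoothed curve.
#' @return A data.frame with `sigma11`, `sigma12`, `amplitude` (degrees,
#'   curve mean), `peak` (degrees, curve maximum) and `peak_at` (degrees).
#' @export
dm_bias_amplitude <- function(grid, bandwidth = 10, diffs = 0:90) {
  stopifnot(all(c("sigma11", "sigma12", "diff", "mean_bias") %in% names(grid)))
  sp <- split(grid, list(grid$sigma11, grid$sigma12), drop = TRUE)
  out <- lapply(sp, function(g) {
    avg <- sum(g$mean_bias * g$n) / sum(g$n)
    if (bandwidth > 0) {
      w <- exp(-outer(diffs, g$diff, "-")^2 / (2 * bandwidth^2)) *
        rep(g$n, each = length(diffs))
      val <- as.vector(w %*% g$mean_bias) / rowSums(w)
      i <- which.max(val)
      data.frame(sigma11 = g$sigma11[1], sigma12 = g$sigma12[1],
                 amplitude = avg, peak = val[i], peak_at = diffs[i])
    } else {
      i <- which.max(g$mean_bias)
      data.frame(sigma11 = g$sigma11[1], sigma12 = g$sigma12[1],
                 amplitude = avg, peak = g$mean_bias[i], peak_at = g$diff[i])
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sigma12, res$sigma11), ]
}
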