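#' Fit per-participant, per-condition serial-bias amplitudes
#'
#' Least-squares fit of the derivative-of-Gaussian shape to each
#' participant's signed errors as a function of the signed dissimilarity to
#' the inducer. The width is profiled over a grid and shared across
#' conditions within a participant (which stabilizes small condition
#' contrasts); at each candidate width the per-condition amplitudes are the
#' linear least-squares solution, and the width minimizing the pooled
#' residual sum of squares is kept.
#'
#' @param bias_df Output of [signed_bias()] (uses `delta` and `error`).
#' @param condition Name of the condition column.
#' @param widths Candidate widths in degrees.
#' @return A data.frame `participant_id`, `condition`, `amplitude`
#'   (degrees), `width` (shared best width), `converged`.
#' @export
fit_dog_amplitudes <- function(bias_df, condition,
                               widths = seq(15, 60, by = 2.5)) {
  conds <- sort(unique(as.character(bias_df[[condition]])))
  parts <- sort(unique(bias_df$participant_id))
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    d <- bias_df[bias_df$participant_id == parts[i], ]
    cvec <- as.character(d[[condition]])
    y <- d$error
    best <- NULL
    for (w in widths) {
      g <- (d$delta / w) * exp(0.5 - d$delta^2 / (2 * w^2))
      X <- sapply(conds, function(cc) g * (cvec == cc))
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(rss = rss, w = w, amp = fit$coefficients)
      }
    }
    ok <- all(is.finite(best$amp))
    out[[i]] <- data.frame(participant_id = parts[i], condition = conds,
                           amplitude = unname(best$amp), width = best$w,
                           converged = ok)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Power-analysis configuration
#'
#' @param design A [design_spec()].
#' @param effect_difference Condition difference in planted serial-bias
#'   amplitude, degrees (default 1).
#' @param baseline_amplitude Amplitude of the weaker condition, degrees.
#' @param width Planted profile width in degrees.
#' @param n_sims Number of simulated datasets (>= 100).
#' @param alpha Test level, in (0, 0.5).
#' @param test `"paired_t"` (two-condition streak design) or `"rm_anova"`
#'   (three congruence conditions of the dual-stimulus designs).
#' @param noise A [noise_spec()].
#' @param between_participant_sd Per-participant amplitude offset SD.
#' @param seed Integer master seed.
#' @return An object of class `power_config`.
#' @export
power_config <- function(design = design_spec("exp1"),
                         effect_difference = 1, baseline_amplitude = 2,
                         width = 35, n_sims = 1000, alpha = 0.05,
                         test = c("paired_t", "rm_anova"),
                         noise = noise_spec(response_sd = 9),
                         between_participant_sd = 0.5, seed = 1L) {
  test <- match.arg(test)
  stopifnot(inherits(design, "design_spec"), n_sims >= 100,
            alpha > 0, alpha < 0.5)
  structure(list(design = design, effect_difference = effect_difference,
                 baseline_amplitude = baseline_amplitude, width = width,
                 n_sims = as.integer(n_sims), alpha = alpha, test = test,
                 noise = noise,
                 between_participant_sd = between_participant_sd,
                 seed = as.integer(seed)),
            class = "power_config")
}

# One simulated dataset -> p-value of the configured test.
power_one_sim <- function(cfg, sim_seed) {
  d <- cfg$design
  prioritized <- cfg$baseline_amplitude + cfg$effect_difference
  if (d$experiment == "exp1") {
    profiles <- list(cued = sd_profile(prioritized, cfg$width),
                     uncued = sd_profile(cfg$baseline_amplitude, cfg$width))
  } else {
    profiles <- list(congruent = sd_profile(prioritized, cfg$width),
                     incongruent = sd_profile(cfg$baseline_amplitude, cfg$width))
  }
  tab <- generate_experiment(d, profiles, cfg$noise, seed = sim_seed,
                             between_participant_sd = cfg$between_participant_sd)
  bias <- signed_bias(tab, reference = "prev_target")
  if (cfg$test == "paired_t") {
    bias <- bias[!is.na(bias$inducer_cued), ]
    bias$cond <- ifelse(bias$inducer_cued, "cued", "uncued")
    amps <- fit_dog_amplitudes(bias, "cond")
    a <- stats::reshape(amps[c("participant_id", "condition", "amplitude")],
                        idvar = "participant_id", timevar = "condition",
                        direction = "wide")
    dd <- a$amplitude.cued - a$amplitude.uncued
    if (!all(is.finite(dd))) return(NA_real_)
    stats::t.test(dd)$p.value
  } else {
    # three congruence conditions: CC, CI, IC (II dropped as too rare)
    bias <- bias[!is.na(bias$congruent_prev), ]
    bias$cond <- paste0(ifelse(bias$congruent_prev, "c", "i"),
                        ifelse(bias$congruent_curr, "c", "i"))
    bias <- bias[bias$cond != "ii", ]
    amps <- fit_dog_amplitudes(bias, "cond")
    X <- matrix(amps$amplitude, ncol = 3, byrow = TRUE,
                dimnames = list(NULL, amps$condition[1:3]))
    if (!all(is.finite(X))) return(NA_real_)
    rm_anova_f(X)$p
  }
}

#' Simulation-based power estimate
#'
#' Repeatedly generates synthetic datasets in which the planted
#' serial-dependence amplitude differs between prioritized and
#' unprioritized inducers by `effect_difference` degrees, fits
#' per-participant per-condition amplitudes, applies the configured test,
#' and reports the rejection proportion with an exact binomial confidence
#' interval.
#'
#' @param cfg A [power_config()].
#' @param progress Print a dot every 50 simulations.
#' @return An object of class `power_result`: list with `power`, `mc_ci`
#'   (exact 95% binomial interval), `n_sims`, `rejected_count`,
#'   `n_nonconverged` and the config.
#' @export
estimate_power <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "power_config"))
  pvals <- numeric(cfg$n_sims)
  for (i in seq_len(cfg$n_sims)) {
    sim_seed <- (cfg$seed %% 100000L) * 20011L + i
    pvals[i] <- power_one_sim(cfg, sim_seed)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  bad <- sum(is.na(pvals))
  if (bad > 0.05 * cfg$n_sims) {
    warning("more than 5% of amplitude fits failed to converge", call. = FALSE)
  }
  rej <- sum(pvals < cfg$alpha, na.rm = TRUE)
  n_ok <- cfg$n_sims - bad
  bt <- stats::binom.test(rej, n_ok)
  structure(list(power = rej / n_ok, mc_ci = unname(bt$conf.int),
                 n_sims = n_ok, rejected_count = rej, n_nonconverged = bad,
                 config = cfg),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Simulated power: %.3f (95%% CI %.3f-%.3f; %d/%d rejections)\n",
              x$power, x$mc_ci[1], x$mc_ci[2], x$rejected_count, x$n_sims))
  cat(sprintf("  design %s, effect %.2g deg, alpha %.3g, test %s\n",
              x$config$design$experiment, x$config$effect_difference,
              x$config$alpha, x$config$test))
  invisible(x)
}
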