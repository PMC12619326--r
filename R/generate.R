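#' Experiment design specification
#'
#' Statistical layout of the three adjustment-task designs. The
#' single-stream streak design (`exp1`) presents pairs of consecutive Gabors
#' (648 trials per participant; one third of streaks are cued
#' report-and-hold-in-memory streaks whose first stimulus is reported twice).
#' The dual-stimulus designs (`exp2` pre-cue, `exp3` post-cue) present two
#' simultaneous Gabors per trial (720 trials; the reported item matches the
#' cue on 75% of trials).
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param n_participants Number of simulated participants.
#' @param n_trials Trials per participant; defaults 648 (`exp1`) or 720.
#' @param cue_fraction Fraction of cued streaks (`exp1` only).
#' @param congruent_fraction Fraction of congruent trials (`exp2`/`exp3`).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(experiment = c("exp1", "exp2", "exp3"),
                        n_participants = 18, n_trials = NULL,
                        cue_fraction = 1 / 3, congruent_fraction = 0.75) {
  experiment <- match.arg(experiment)
  if (is.null(n_trials)) n_trials <- if (experiment == "exp1") 648L else 720L
  if (cue_fraction < 0 || cue_fraction > 1 ||
      congruent_fraction < 0 || congruent_fraction > 1) {
    stop("design fractions must lie in [0, 1]", call. = FALSE)
  }
  if (experiment == "exp1" && n_trials %% 2 != 0) {
    stop("exp1 `n_trials` must be even (two stimuli per streak)", call. = FALSE)
  }
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 cue_fraction = cue_fraction,
                 congruent_fraction = congruent_fraction),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design %s: %d participants x %d trials", x$experiment,
              x$n_participants, x$n_trials))
  if (x$experiment == "exp1") {
    cat(sprintf(", cued streak fraction %.2f\n", x$cue_fraction))
  } else {
    cat(sprintf(", congruent fraction %.2f\n", x$congruent_fraction))
  }
  invisible(x)
}

#' Serial-dependence profile (derivative-of-Gaussian)
#'
#' Parametric shape of the planted serial bias: zero at zero dissimilarity,
#' peaking at `width` degrees with value `amplitude`, decaying toward 90.
#' Negative amplitudes plant repulsion.
#'
#' @param amplitude Peak attraction in degrees (may be 0 or negative).
#' @param width Dissimilarity of the peak in degrees (> 0).
#' @return An object of class `sd_profile`.
#' @export
sd_profile <- function(amplitude = 2, width = 35) {
  stopifnot(is.finite(amplitude), width > 0)
  structure(list(amplitude = amplitude, width = width), class = "sd_profile")
}

#' Response-noise specification
#'
#' @param response_sd Circular SD of response noise in degrees (> 0); the
#'   default 9 matches absolute-error levels around 7-9 degrees typical of
#'   orientation adjustment.
#' @param cardinal_amplitude Amplitude (degrees) of an idiosyncratic
#'   orientation-dependent bias, modeled as a sinusoid of the quadrupled
#'   orientation angle.
#' @param outlier_rate Probability a response is replaced by a uniform guess,
#'   in `[0, 0.2]`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(response_sd = 9, cardinal_amplitude = 0,
                       outlier_rate = 0) {
  stopifnot(response_sd > 0, outlier_rate >= 0, outlier_rate <= 0.2)
  structure(list(response_sd = response_sd,
                 cardinal_amplitude = cardinal_amplitude,
                 outlier_rate = outlier_rate), class = "noise_spec")
}

#' Derivative-of-Gaussian serial-bias shape
#'
#' `amplitude * (delta / width) * exp(1/2 - delta^2 / (2 width^2))`: an odd
#' function of the signed dissimilarity `delta` that equals `amplitude`
#' exactly at `delta = width`.
#'
#' @param delta Signed angular differences in degrees.
#' @param profile An [sd_profile()].
#' @return Bias values in degrees.
#' @examples
#' dog_bias(35, sd_profile(amplitude = 2, width = 35))  # exactly 2
#' @export
dog_bias <- function(delta, profile) {
  stopifnot(inherits(profile, "sd_profile"))
  profile$amplitude * (delta / profile$width) *
    exp(0.5 - delta^2 / (2 * profile$width^2))
}

# sinusoidal stand-in for an idiosyncratic cardinal bias
cardinal_term <- function(theta, amplitude) {
  amplitude * sin(theta * 4 * pi / 180)
}

#' Generate a synthetic experiment
#'
#' Emits a seeded trial table with the statistical structure of one of the
#' three designs. Stimuli are i.i.d. uniform on `[0, 180)`; the response to a
#' reported stimulus is the stimulus plus a derivative-of-Gaussian serial
#' bias toward the previous reported item, plus an optional cardinal
#' (orientation-dependent) term, plus wrapped-normal response noise; a small
#' fraction of responses can be replaced by uniform outliers.
#'
#' The bias profile is chosen by the prioritization status of the inducer
#' (the previously reported item): for `exp1` whether the inducer was the
#' cued, held-in-memory stimulus of its streak (`profiles$cued` /
#' `profiles$uncued`); for `exp2`/`exp3` whether the previous trial was
#' congruent, i.e. the previous report was of the cued item
#' (`profiles$congruent` / `profiles$incongruent`). Per-participant
#' variability in overall serial-dependence strength is modeled as a normal
#' amplitude offset shared across conditions.
#'
#' @param design A [design_spec()].
#' @param profiles Named list of [sd_profile()]s: `cued`/`uncued` for exp1,
#'   `congruent`/`incongruent` for exp2/exp3.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param between_participant_sd SD (degrees) of the per-participant
#'   amplitude offset (default 0.5).
#' @return A trial-table data.frame with columns `participant_id`,
#'   `trial_index` (0-based), `streak_index` (exp1; NA otherwise), `role`
#'   (`response1`/`response2`/`response3` for exp1; `target`/`distractor`
#'   for exp2/exp3), `cue`, `congruent_prev`, `congruent_curr`,
#'   `stimulus_ori`, `response_ori` (NA for distractor rows),
#'   `prev_inducer_ori`, `excluded`, plus the convenience flag
#'   `inducer_cued` (was the inducer prioritized).
#' @export
generate_experiment <- function(design, profiles = NULL,
                                noise = noise_spec(), seed = 1L,
                                between_participant_sd = 0.5) {
  stopifnot(inherits(design, "design_spec"), inherits(noise, "noise_spec"))
  if (is.null(profiles)) {
    profiles <- if (design$experiment == "exp1") {
      list(cued = sd_profile(), uncued = sd_profile())
    } else {
      list(congruent = sd_profile(), incongruent = sd_profile())
    }
  }
  need <- if (design$experiment == "exp1") c("cued", "uncued") else
    c("congruent", "incongruent")
  if (!all(need %in% names(profiles))) {
    stop("`profiles` must contain ", paste(need, collapse = " and "),
         call. = FALSE)
  }
  set.seed(seed)
  tabs <- lapply(seq_len(design$n_participants), function(p) {
    offset <- stats::rnorm(1, 0, between_participant_sd)
    if (design$experiment == "exp1") {
      generate_exp1_participant(p, design, profiles, noise, offset)
    } else {
      generate_exp23_participant(p, design, profiles, noise, offset)
    }
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# response = stimulus + planted bias + cardinal + noise (+ outliers)
make_responses <- function(stimulus, prev_inducer, amplitude, width, noise) {
  n <- length(stimulus)
  delta <- rep(NA_real_, n)
  ok <- !is.na(prev_inducer)
  delta[ok] <- ori_diff(prev_inducer[ok], stimulus[ok])
  bias <- ifelse(ok, amplitude * (delta / width) *
                   exp(0.5 - delta^2 / (2 * width^2)), 0)
  resp <- (stimulus + bias + cardinal_term(stimulus, noise$cardinal_amplitude) +
             stats::rnorm(n, 0, noise$response_sd)) %% 180
  if (noise$outlier_rate > 0) {
    out <- stats::runif(n) < noise$outlier_rate
    resp[out] <- stats::runif(sum(out), 0, 180)
  }
  resp
}

generate_exp1_participant <- function(p, design, profiles, noise, amp_offset) {
  n_streaks <- design$n_trials %/% 2L
  cue <- stats::runif(n_streaks) < design$cue_fraction
  s1 <- stats::runif(n_streaks, 0, 180)
  s2 <- stats::runif(n_streaks, 0, 180)

  # report rows in temporal order: R1 (s1), R2 (s2), and R3 (s1) in cued streaks
  rows_per <- 2L + as.integer(cue)
  streak_idx <- rep.int(seq_len(n_streaks), rows_per)
  role <- unlist(lapply(seq_len(n_streaks), function(k) {
    if (cue[k]) c("response1", "response2", "response3")
    else c("response1", "response2")
  }), use.names = FALSE)
  stimulus <- ifelse(role == "response2", s2[streak_idx], s1[streak_idx])
  # inducer: the previously reported stimulus in temporal order
  prev_inducer <- c(NA, stimulus[-length(stimulus)])
  # was the inducer the cued (held-in-memory) stimulus of its streak?
  prev_role <- c(NA, role[-length(role)])
  prev_streak <- c(NA, streak_idx[-length(streak_idx)])
  inducer_cued <- !is.na(prev_role) & prev_role != "response2" &
    cue[ifelse(is.na(prev_streak), 1L, prev_streak)]
  inducer_cued[is.na(prev_role)] <- NA

  amp <- ifelse(isTRUE_vec(inducer_cued),
                profiles$cued$amplitude, profiles$uncued$amplitude) + amp_offset
  width <- ifelse(isTRUE_vec(inducer_cued),
                  profiles$cued$width, profiles$uncued$width)
  resp <- make_responses(stimulus, prev_inducer, amp, width, noise)

  data.frame(participant_id = p,
             trial_index = seq_along(role) - 1L,
             streak_index = streak_idx,
             role = role,
             cue = cue[streak_idx],
             congruent_prev = NA,
             congruent_curr = NA,
             stimulus_ori = stimulus,
             response_ori = resp,
             prev_inducer_ori = prev_inducer,
             excluded = FALSE,
             inducer_cued = inducer_cued)
}

generate_exp23_participant <- function(p, design, profiles, noise, amp_offset) {
  n <- design$n_trials
  congruent <- stats::runif(n) < design$congruent_fraction
  target <- stats::runif(n, 0, 180)
  distractor <- stats::runif(n, 0, 180)
  prev_target <- c(NA, target[-n])
  congruent_prev <- c(NA, congruent[-n])

  amp <- ifelse(isTRUE_vec(congruent_prev),
                profiles$congruent$amplitude,
                profiles$incongruent$amplitude) + amp_offset
  width <- ifelse(isTRUE_vec(congruent_prev),
                  profiles$congruent$width, profiles$incongruent$width)
  resp <- make_responses(target, prev_target, amp, width, noise)

  tgt <- data.frame(participant_id = p, trial_index = seq_len(n) - 1L,
                    streak_index = NA_integer_, role = "target",
                    cue = congruent,  # reported item carries the cue iff congruent
                    congruent_prev = congruent_prev,
                    congruent_curr = congruent,
                    stimulus_ori = target, response_ori = resp,
                    prev_inducer_ori = prev_target, excluded = FALSE,
                    inducer_cued = congruent_prev)
  dst <- data.frame(participant_id = p, trial_index = seq_len(n) - 1L,
                    streak_index = NA_integer_, role = "distractor",
                    cue = !congruent,
                    congruent_prev = congruent_prev,
                    congruent_curr = congruent,
                    stimulus_ori = distractor, response_ori = NA_real_,
                    prev_inducer_ori = NA_real_, excluded = FALSE,
                    inducer_cued = NA)
  out <- rbind(tgt, dst)
  out[order(out$trial_index, out$role, method = "radix", decreasing = c(FALSE, TRUE)), ]
}

# NA-safe elementwise isTRUE
isTRUE_vec <- function(x) !is.na(x) & x
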