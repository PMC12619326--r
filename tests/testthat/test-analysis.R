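make_biasdf <- function(participant, abs_delta, bias, cond = "all") {
  data.frame(participant_id = participant, role = "response1", cue = NA,
             congruent_prev = NA, congruent_curr = NA, inducer_cued = NA,
             delta = abs_delta, abs_delta = abs(abs_delta),
             error = bias, bias = bias, cond = cond)
}

test_that("cardinal-bias removal strips an injected orientation-dependent bias", {
  d <- design_spec("exp1", n_participants = 4)
  prof <- list(cued = sd_profile(0, 35), uncued = sd_profile(0, 35))
  tt <- generate_experiment(d, prof, noise_spec(response_sd = 9,
                                                cardinal_amplitude = 3),
                            seed = 23, between_participant_sd = 0)
  pp <- preprocess_trials(tt)
  # refit the harmonic basis on corrected errors: residual amplitude must be small
  for (p in 1:4) {
    sel <- pp$participant_id == p & !is.na(pp$error_corr)
    th <- pp$stimulus_ori[sel] * pi / 180
    X <- cbind(sin(2 * th), cos(2 * th), sin(4 * th), cos(4 * th))
    cf <- coef(lm(pp$error_corr[sel] ~ X))[-1]
    expect_lt(sqrt(sum(cf^2, na.rm = TRUE)), 0.3)
  }
  # and the raw errors really carried the injected bias before correction
  sel <- pp$participant_id == 1 & !is.na(pp$error_raw)
  th <- pp$stimulus_ori[sel] * pi / 180
  cf_raw <- coef(lm(pp$error_raw[sel] ~ sin(4 * th)))[2]
  expect_equal(unname(cf_raw), 3, tolerance = 0.5)
})

test_that("preprocessing on clean data is benign and flags gross outliers", {
  d <- design_spec("exp1", n_participants = 2)
  prof <- list(cued = sd_profile(0, 35), uncued = sd_profile(0, 35))
  tt <- generate_experiment(d, prof, noise_spec(response_sd = 0.2), seed = 29,
                            between_participant_sd = 0)
  # plant one gross error
  i <- which(tt$participant_id == 1)[100]
  tt$response_ori[i] <- wrap_ori(tt$stimulus_ori[i] + 85)
  pp <- preprocess_trials(tt)
  expect_true(pp$excluded[i])
  # near-noiseless data: corrected errors equal raw errors closely (judge on
  # the participant without the planted outlier), few exclusions overall
  ok <- pp$participant_id == 2 & !is.na(pp$error_corr) & !pp$excluded
  expect_lt(max(abs(pp$error_corr[ok] - pp$error_raw[ok])), 0.1)
  expect_lt(sum(pp$excluded), 12)
  expect_length(attr(pp, "participant_excluded"), 0)
})

test_that("participants with wild responses or too few trials are flagged", {
  d <- design_spec("exp1", n_participants = 2, n_trials = 120)
  tt <- generate_experiment(d, seed = 31)
  # participant 2 responds at random: circular SD far above 30 degrees
  sel <- tt$participant_id == 2
  tt$response_ori[sel] <- runif(sum(sel), 0, 180)
  pp <- preprocess_trials(tt, min_trials = 50)
  expect_true(2 %in% attr(pp, "participant_excluded"))
  expect_true(all(pp$excluded[pp$participant_id == 2]))
  # too-few-trials participant is skipped with a warning
  small <- tt[tt$participant_id == 1 & tt$trial_index < 20, ]
  expect_warning(preprocess_trials(small, min_trials = 50), "skipped")
})

test_that("signed bias follows the sign convention and is mirror-antisymmetric", {
  tt <- data.frame(participant_id = 1, trial_index = 0:1,
                   streak_index = NA, role = "response1", cue = FALSE,
                   congruent_prev = NA, congruent_curr = NA,
                   stimulus_ori = c(100, 100), response_ori = c(105, 105),
                   prev_inducer_ori = c(130, 70), excluded = FALSE)
  b <- signed_bias(tt)
  # error +5 toward a reference at +30 -> +5; away (reference at -30) -> -5
  expect_equal(b$bias, c(5, -5))

  # mirror-reflecting all orientations flips errors and directions together,
  # leaving the attraction bias invariant; reflecting responses about their
  # stimulus flips only the error and negates every bias
  d <- design_spec("exp1", n_participants = 2)
  t1 <- generate_experiment(d, seed = 37)
  t2 <- t1
  t2$stimulus_ori <- wrap_ori(-t2$stimulus_ori)
  t2$response_ori <- wrap_ori(-t2$response_ori)
  t2$prev_inducer_ori <- wrap_ori(-t2$prev_inducer_ori)
  b1 <- signed_bias(t1); b2 <- signed_bias(t2)
  expect_equal(b2$bias, b1$bias, tolerance = 1e-9)
  expect_equal(b2$abs_delta, b1$abs_delta, tolerance = 1e-9)
  t3 <- t1
  err1 <- ori_diff(t1$response_ori, t1$stimulus_ori)
  t3$response_ori <- wrap_ori(t3$stimulus_ori - err1)
  b3 <- signed_bias(t3)
  expect_equal(b3$bias, -b1$bias, tolerance = 1e-9)

  # boundary references are dropped and counted
  tt$prev_inducer_ori <- c(100, wrap_ori(100 + 90))
  b3 <- signed_bias(tt)
  expect_equal(nrow(b3), 0)
  expect_equal(attr(b3, "n_dropped_undefined"), 2)
})

test_that("density-asymmetry curve: null flatness, exact oddness, bounded values", {
  set.seed(43)
  bdf <- make_biasdf(1, runif(4000, 0, 90), rnorm(4000, 0, 6))
  cur <- density_asymmetry_curve(bdf, n_boot = 100)
  expect_true(all(cur$asym >= -1 & cur$asym <= 1))
  se <- (cur$ci_high - cur$ci_low) / (2 * 1.96)
  expect_true(all(abs(cur$asym) < 3.5 * se))
  expect_true(all(cur$ci_low <= cur$asym & cur$asym <= cur$ci_high))

  neg <- bdf; neg$bias <- -neg$bias
  cneg <- density_asymmetry_curve(neg, n_boot = 0)
  expect_equal(cneg$asym, -cur$asym)
  expect_equal(cneg$mean_deg, -cur$mean_deg)
})

test_that("mean bias test: planted attraction detected, degenerate input flagged", {
  d <- design_spec("exp1", n_participants = 18)
  prof <- list(cued = sd_profile(2, 35), uncued = sd_profile(2, 35))
  tt <- generate_experiment(d, prof, seed = 47)
  b <- signed_bias(tt)
  mb <- mean_bias_test(b)
  expect_gt(mb$tests$mean_asym, 0)
  expect_lt(mb$tests$p, 0.05)
  # zero-variance input: descriptives plus a degenerate flag
  z <- make_biasdf(rep(1:3, each = 10), rep(1:10, 3), 0)
  mz <- mean_bias_test(z)
  expect_true(mz$tests$degenerate)
  expect_equal(mz$tests$mean_asym, 0)
})

test_that("per-degree tests: F equals squared paired t for two conditions", {
  set.seed(53)
  n <- 8
  bdf <- do.call(rbind, lapply(1:n, function(p) {
    rbind(make_biasdf(p, runif(300, 0, 90), rnorm(300, 1, 6), "a"),
          make_biasdf(p, runif(300, 0, 90), rnorm(300, 0, 6), "b"))
  }))
  rep_ <- per_degree_condition_tests(bdf, "cond", value = "mean_deg")
  pd <- rep_$per_degree
  curves <- serialdep:::participant_curves(bdf, "cond", 10, 0:90, "mean_deg")
  dmat <- curves$a - curves$b
  tstat <- colMeans(dmat) / (apply(dmat, 2, sd) / sqrt(n))
  expect_equal(pd$F, unname(tstat^2), tolerance = 1e-8)
})

test_that("per-degree tests localize a planted condition difference", {
  d <- design_spec("exp1", n_participants = 12)
  prof <- list(cued = sd_profile(2.5, 35), uncued = sd_profile(0, 35))
  tt <- generate_experiment(d, prof, seed = 59, between_participant_sd = 0)
  b <- signed_bias(tt)
  b <- b[!is.na(b$inducer_cued), ]
  b$cond <- ifelse(b$inducer_cued, "cued", "uncued")
  rep_ <- per_degree_condition_tests(b, "cond", value = "mean_deg")
  anova_cl <- rep_$clusters[rep_$clusters$condition == "anova", ]
  expect_gt(nrow(anova_cl), 0)
  covers <- any(anova_cl$start <= 35 & anova_cl$end >= 35)
  expect_true(covers)
  cued_cl <- rep_$clusters[rep_$clusters$condition == "cued" &
                             rep_$clusters$direction == "attraction", ]
  expect_true(any(cued_cl$start <= 35 & cued_cl$end >= 35))
})

test_that("peak localization flags boundaries and flat curves", {
  mono <- data.frame(diff = 0:90, asym = seq(0, 0.5, length.out = 91))
  p <- peak_location(mono)
  expect_equal(p$peak_at, 90)
  expect_true(p$boundary)
  flat <- data.frame(diff = 0:90, asym = rep(0.2, 91))
  expect_true(peak_location(flat)$flat)
  bump <- data.frame(diff = 0:90, asym = dnorm(0:90, 35, 12))
  expect_equal(peak_location(bump)$peak_at, 35)
  expect_error(peak_location(data.frame(diff = 1, asym = NA_real_)), "usable")
})

test_that("pipeline outputs are equivariant under participant relabeling", {
  d <- design_spec("exp1", n_participants = 4)
  tt <- generate_experiment(d, seed = 61)
  b <- signed_bias(tt)
  perm <- c(3, 1, 4, 2)
  b2 <- b; b2$participant_id <- perm[b2$participant_id]
  m1 <- mean_bias_test(b)$participants
  m2 <- mean_bias_test(b2)$participants
  m2$participant_id <- match(m2$participant_id, perm)
  expect_equal(m1$asym[order(m1$participant_id)],
               m2$asym[order(m2$participant_id)])
})
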