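#' Preprocess a trial table
#'
#' Per participant: (1) removes idiosyncratic orientation-dependent
#' (cardinal) bias by regressing the signed response error on sine and
#' cosine of the doubled and quadrupled stimulus angle and subtracting the
#' fit; (2) flags trials whose corrected error exceeds `outlier_sd_mult`
#' circular SDs as excluded; (3) flags whole participants whose error
#' circular SD exceeds `exclusion_circ_sd` (default 30 degrees, the
#' low-accuracy exclusion rule). Participants with fewer than `min_trials`
#' usable report rows are skipped with a warning.
#'
#' @param raw A trial-table data.frame (see [generate_experiment()]).
#' @param outlier_sd_mult Outlier threshold in units of the participant's
#'   circular SD (default 3).
#' @param exclusion_circ_sd Whole-participant exclusion threshold in degrees.
#' @param min_trials Minimum usable report rows per participant.
#' @return The table with added columns `error_raw`, `error_corr` (degrees)
#'   and updated `excluded`, plus attributes `participant_excluded` (ids) and
#'   `skipped` (ids with too few trials).
#' @export
preprocess_trials <- function(raw, outlier_sd_mult = 3,
                              exclusion_circ_sd = 30, min_trials = 50) {
  stopifnot(is.data.frame(raw))
  need <- c("participant_id", "stimulus_ori", "response_ori")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  raw$error_raw <- NA_real_
  raw$error_corr <- NA_real_
  if (is.null(raw$excluded)) raw$excluded <- FALSE
  part_excl <- integer(0)
  skipped <- integer(0)
  for (p in unique(raw$participant_id)) {
    sel <- which(raw$participant_id == p & !is.na(raw$response_ori))
    if (length(sel) < min_trials) {
      warning("participant ", p, " skipped: only ", length(sel),
              " usable trials", call. = FALSE)
      skipped <- c(skipped, p)
      raw$excluded[raw$participant_id == p] <- TRUE
      next
    }
    err <- ori_diff(raw$response_ori[sel], raw$stimulus_ori[sel])
    th <- raw$stimulus_ori[sel] * pi / 180
    X <- cbind(1, sin(2 * th), cos(2 * th), sin(4 * th), cos(4 * th))
    fit <- stats::lm.fit(X, err)
    corr <- fit$residuals
    raw$error_raw[sel] <- err
    raw$error_corr[sel] <- corr
    # circular SD of corrected errors (errors live on the orientation circle)
    csd <- circ_mean_sd(corr %% 180)$sd
    raw$excluded[sel] <- raw$excluded[sel] | abs(corr) > outlier_sd_mult * csd
    if (csd > exclusion_circ_sd) {
      part_excl <- c(part_excl, p)
      raw$excluded[raw$participant_id == p] <- TRUE
    }
  }
  attr(raw, "participant_excluded") <- part_excl
  attr(raw, "skipped") <- skipped
  raw
}

#' Per-trial signed serial-dependence bias
#'
#' For each usable report row, resolves the reference (inducer) orientation,
#' and computes `bias = error * sign(ori_diff(reference, stimulus))` so that
#' positive values indicate attraction toward the reference. Rows whose
#' reference sits exactly at 0 or +/-90 degrees from the stimulus have no
#' defined direction and are dropped (the count is reported as an attribute).
#'
#' @param trials A preprocessed trial table (needs `error_corr`; falls back
#'   to raw errors if [preprocess_trials()] was not run).
#' @param reference How to resolve the inducer: `"prev_target"` uses the
#'   previously reported stimulus (the `prev_inducer_ori` column);
#'   `"prev_distractor"` uses the previous trial's distractor row (dual-task
#'   designs); `"within_streak"` uses the first stimulus of the same streak
#'   for second reports (streak design).
#' @param drop_excluded Drop rows flagged `excluded`.
#' @return A data.frame with `participant_id`, `condition` columns carried
#'   over (`cue`, `congruent_prev`, `congruent_curr`, `inducer_cued`, `role`),
#'   `delta` (signed reference minus stimulus), `abs_delta`, `error`, `bias`.
#'   Attribute `n_dropped_undefined` counts dropped boundary rows.
#' @export
signed_bias <- function(trials,
                        reference = c("prev_target", "prev_distractor",
                                      "within_streak"),
                        drop_excluded = TRUE) {
  reference <- match.arg(reference)
  tt <- trials
  rep_rows <- !is.na(tt$response_ori)
  if (is.null(tt$error_corr)) {
    tt$error_corr <- NA_real_
    tt$error_corr[rep_rows] <- ori_diff(tt$response_ori[rep_rows],
                                        tt$stimulus_ori[rep_rows])
  }
  ref <- rep(NA_real_, nrow(tt))
  if (reference == "prev_target") {
    if (!is.null(tt$prev_inducer_ori)) {
      ref <- tt$prev_inducer_ori
    } else {
      for (p in unique(tt$participant_id)) {
        sel <- which(tt$participant_id == p & rep_rows)
        if (length(sel) > 1) ref[sel[-1]] <- tt$stimulus_ori[sel[-length(sel)]]
      }
    }
  } else if (reference == "prev_distractor") {
    dst <- tt[tt$role == "distractor", ]
    key <- paste(tt$participant_id, tt$trial_index - 1L)
    dkey <- paste(dst$participant_id, dst$trial_index)
    ref <- dst$stimulus_ori[match(key, dkey)]
  } else {  # within_streak: second report vs first stimulus of same streak
    first <- tt[tt$role == "response1", ]
    key <- paste(tt$participant_id, tt$streak_index)
    fkey <- paste(first$participant_id, first$streak_index)
    ref <- ifelse(tt$role == "response2",
                  first$stimulus_ori[match(key, fkey)], NA_real_)
  }
  keep <- rep_rows & !is.na(ref) & !is.na(tt$error_corr)
  if (drop_excluded && !is.null(tt$excluded)) keep <- keep & !tt$excluded
  delta <- ori_diff(ref[keep], tt$stimulus_ori[keep])
  undef <- delta == 0 | delta == -90
  out <- data.frame(participant_id = tt$participant_id[keep],
                    role = if (!is.null(tt$role)) tt$role[keep] else NA,
                    cue = if (!is.null(tt$cue)) tt$cue[keep] else NA,
                    congruent_prev = if (!is.null(tt$congruent_prev))
                      tt$congruent_prev[keep] else NA,
                    congruent_curr = if (!is.null(tt$congruent_curr))
                      tt$congruent_curr[keep] else NA,
                    inducer_cued = if (!is.null(tt$inducer_cued))
                      tt$inducer_cued[keep] else NA,
                    delta = delta, abs_delta = abs(delta),
                    error = tt$error_corr[keep],
                    bias = tt$error_corr[keep] * sign(delta))
  out <- out[!undef, ]
  attr(out, "n_dropped_undefined") <- sum(undef)
  rownames(out) <- NULL
  out
}

# Gaussian-kernel weighted curve of a statistic of bias vs |delta|.
kernel_curve <- function(abs_delta, values, bandwidth, diffs) {
  W <- exp(-outer(diffs, abs_delta, "-")^2 / (2 * bandwidth^2))
  sw <- rowSums(W)
  list(value = as.vector(W %*% values) / sw,
       n_eff = sw^2 / rowSums(W^2),
       empty = sw < 1e-10)
}

#' Kernel-weighted density-asymmetry bias curve
#'
#' For each dissimilarity step 0-90 degrees, all trials contribute, weighted
#' by a Gaussian kernel on the distance between their absolute dissimilarity
#' and the step. The headline statistic is the weighted mean of the sign of
#' the bias: the excess probability of erring toward versus away from the
#' inducer, in [-1, 1]. A parallel weighted mean of the signed bias in
#' degrees is returned alongside. Confidence intervals for the asymmetry are
#' bootstrapped over trials.
#'
#' @param bias_df Output of [signed_bias()] (needs `abs_delta`, `bias`).
#' @param bandwidth Gaussian kernel SD in degrees (default 10).
#' @param diffs Evaluation grid, default `0:90`.
#' @param n_boot Bootstrap replicates for the CI (0 disables).
#' @param conf Confidence level.
#' @return An object of class `bias_curve`: data.frame with `diff`, `asym`,
#'   `mean_deg`, `ci_low`, `ci_high` (on `asym`), `n_eff`, `empty`.
#' @export
density_asymmetry_curve <- function(bias_df, bandwidth = 10, diffs = 0:90,
                                    n_boot = 200, conf = 0.95) {
  stopifnot(bandwidth > 0, nrow(bias_df) >= 1)
  ad <- bias_df$abs_delta
  b <- bias_df$bias
  kc_s <- kernel_curve(ad, sign(b), bandwidth, diffs)
  kc_m <- kernel_curve(ad, b, bandwidth, diffs)
  ci_low <- ci_high <- rep(NA_real_, length(diffs))
  if (n_boot > 0) {
    n <- length(b)
    boot <- matrix(NA_real_, n_boot, length(diffs))
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot[r, ] <- kernel_curve(ad[idx], sign(b[idx]), bandwidth, diffs)$value
    }
    alpha <- (1 - conf) / 2
    qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    ci_low <- qs[1, ]; ci_high <- qs[2, ]
  }
  structure(data.frame(diff = diffs, asym = kc_s$value, mean_deg = kc_m$value,
                       ci_low = ci_low, ci_high = ci_high,
                       n_eff = kc_s$n_eff, empty = kc_s$empty),
            class = c("bias_curve", "data.frame"))
}

#' Per-participant mean bias with a one-sample test
#'
#' Computes each participant's mean density asymmetry (mean sign of bias)
#' and mean signed bias in degrees, optionally split by a condition column,
#' and runs a two-sided one-sample t-test against zero per condition. With a
#' single participant only descriptives are returned.
#'
#' @param bias_df Output of [signed_bias()].
#' @param condition Optional name of a condition column in `bias_df`.
#' @return A list with `participants` (per-participant means) and `tests`
#'   (per condition: mean asymmetry, mean bias in degrees, t, df, p; NA and a
#'   `degenerate` flag when the variance is zero).
#' @export
mean_bias_test <- function(bias_df, condition = NULL) {
  grp <- if (is.null(condition)) rep("all", nrow(bias_df)) else
    as.character(bias_df[[condition]])
  per <- stats::aggregate(cbind(asym = sign(bias_df$bias),
                                mean_deg = bias_df$bias),
                          by = list(participant_id = bias_df$participant_id,
                                    condition = grp), FUN = mean)
  tests <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    n <- nrow(d)
    degen <- n >= 2 && stats::sd(d$asym) == 0
    if (n >= 2 && !degen) {
      tt <- stats::t.test(d$asym)
      data.frame(condition = d$condition[1], n = n,
                 mean_asym = mean(d$asym), mean_deg = mean(d$mean_deg),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    } else {
      data.frame(condition = d$condition[1], n = n,
                 mean_asym = mean(d$asym), mean_deg = mean(d$mean_deg),
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 degenerate = degen)
    }
  }))
  rownames(tests) <- NULL
  list(participants = per, tests = tests)
}

# Per-participant smoothed curves: matrix participants x diffs per condition.
participant_curves <- function(bias_df, condition, bandwidth = 10,
                               diffs = 0:90, value = c("asym", "mean_deg")) {
  value <- match.arg(value)
  parts <- sort(unique(bias_df$participant_id))
  conds <- sort(unique(as.character(bias_df[[condition]])))
  out <- lapply(conds, function(cc) {
    m <- matrix(NA_real_, length(parts), length(diffs),
                dimnames = list(parts, diffs))
    for (i in seq_along(parts)) {
      d <- bias_df[bias_df$participant_id == parts[i] &
                     as.character(bias_df[[condition]]) == cc, ]
      if (nrow(d) == 0) {
        stop("participant ", parts[i], " has no trials in condition ", cc,
             call. = FALSE)
      }
      v <- if (value == "asym") sign(d$bias) else d$bias
      m[i, ] <- kernel_curve(d$abs_delta, v, bandwidth, diffs)$value
    }
    m
  })
  names(out) <- conds
  out
}

# Repeated-measures one-way ANOVA on a participants x conditions matrix.
rm_anova_f <- function(X) {
  n <- nrow(X); C <- ncol(X)
  gm <- mean(X)
  cm <- colMeans(X); rm_ <- rowMeans(X)
  ms_c <- n * sum((cm - gm)^2) / (C - 1)
  resid <- X - outer(rm_, rep(1, C)) - outer(rep(1, n), cm) + gm
  ms_e <- sum(resid^2) / ((n - 1) * (C - 1))
  f <- ms_c / ms_e
  list(F = f, df1 = C - 1, df2 = (n - 1) * (C - 1),
       p = stats::pf(f, C - 1, (n - 1) * (C - 1), lower.tail = FALSE))
}

#' Per-degree condition tests with cluster reporting
#'
#' Builds a smoothed bias curve per participant and condition, then at every
#' one-degree dissimilarity step runs a two-sided one-sample t-test per
#' condition against zero and a repeated-measures ANOVA across conditions.
#' Maximal contiguous runs of per-degree significance at `alpha` are reported
#' as clusters with their direction; no correction across the 91 steps is
#' applied (clusters are descriptive).
#'
#' @param bias_df Output of [signed_bias()].
#' @param condition Name of the condition column.
#' @param alpha Per-degree significance level.
#' @param bandwidth Kernel SD in degrees for the participant curves.
#' @param value Curve statistic: `"asym"` (density asymmetry) or
#'   `"mean_deg"` (mean signed bias, degrees).
#' @param diffs Evaluation grid.
#' @return An object of class `cluster_report`: list with `per_degree`
#'   (data.frame of means, t and p per condition plus the ANOVA F and p),
#'   `clusters` (data.frame: condition or "anova", start, end, direction)
#'   and the settings used.
#' @export
per_degree_condition_tests <- function(bias_df, condition, alpha = 0.05,
                                       bandwidth = 10,
                                       value = c("asym", "mean_deg"),
                                       diffs = 0:90) {
  value <- match.arg(value)
  curves <- participant_curves(bias_df, condition, bandwidth, diffs, value)
  conds <- names(curves)
  nd <- length(diffs)
  per <- data.frame(diff = diffs)
  clusters <- list()
  runs_from <- function(sig, dir, label) {
    if (!any(sig)) return(NULL)
    r <- rle(sig & !is.na(sig))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    do.call(rbind, lapply(keep, function(k) {
      dd <- if (is.null(dir)) "difference" else
        if (mean(dir[starts[k]:ends[k]]) >= 0) "attraction" else "repulsion"
      data.frame(condition = label, start = diffs[starts[k]],
                 end = diffs[ends[k]], direction = dd)
    }))
  }
  for (cc in conds) {
    m <- curves[[cc]]
    mu <- colMeans(m)
    se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
    tv <- mu / se
    pv <- 2 * stats::pt(-abs(tv), df = nrow(m) - 1)
    per[[paste0("mean_", cc)]] <- mu
    per[[paste0("t_", cc)]] <- tv
    per[[paste0("p_", cc)]] <- pv
    clusters[[cc]] <- runs_from(pv < alpha, mu, cc)
  }
  if (length(conds) >= 2) {
    fv <- pv <- numeric(nd)
    for (j in seq_len(nd)) {
      X <- sapply(curves, function(m) m[, j])
      a <- rm_anova_f(X)
      fv[j] <- a$F; pv[j] <- a$p
    }
    per$F <- fv
    per$p_F <- pv
    clusters[["anova"]] <- runs_from(pv < alpha, NULL, "anova")
  }
  cl <- do.call(rbind, clusters)
  rownames(cl) <- NULL
  structure(list(per_degree = per, clusters = cl, alpha = alpha,
                 bandwidth = bandwidth, value = value,
                 conditions = conds),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Per-degree condition tests (%s curves, bandwidth %.1f deg, alpha %.3g)\n",
              x$value, x$bandwidth, x$alpha))
  cat("Conditions:", paste(x$conditions, collapse = ", "), "\n")
  if (is.null(x$clusters) || nrow(x$clusters) == 0) {
    cat("No significant clusters.\n")
  } else {
    cat("Clusters (maximal runs of per-degree significance):\n")
    print(x$clusters)
  }
  invisible(x)
}

#' Location of the maximum of a bias curve
#'
#' @param curve A `bias_curve` (or data.frame with `diff` and a value
#'   column).
#' @param value Which column to maximize (default `"asym"`, falling back to
#'   `"value"`).
#' @param flat_tol Curves whose range is below this are declared flat.
#' @return A list with `peak_at` (degrees; NA if flat), `peak_value`,
#'   `boundary` (TRUE when the maximum sits at the first or last step) and
#'   `flat`.
#' @export
peak_location <- function(curve, value = NULL, flat_tol = 1e-9) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1)
  if (is.null(value)) {
    value <- if ("asym" %in% names(curve)) "asym" else "value"
  }
  v <- curve[[value]]
  ok <- is.finite(v)
  if (!is.null(curve$empty)) ok <- ok & !curve$empty
  if (!any(ok)) stop("curve has no usable bins", call. = FALSE)
  v <- v[ok]; d <- curve$diff[ok]
  if (diff(range(v)) < flat_tol) {
    return(list(peak_at = NA_real_, peak_value = v[1], boundary = FALSE,
                flat = TRUE))
  }
  i <- which.max(v)
  list(peak_at = d[i], peak_value = v[i],
       boundary = i == 1L || i == length(v), flat = FALSE)
}
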