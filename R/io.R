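trial_table_columns <- c("participant_id", "trial_index", "streak_index",
                         "role", "cue", "congruent_prev", "congruent_curr",
                         "stimulus_ori", "response_ori", "prev_inducer_ori",
                         "excluded")

#' Read a trial table from CSV
#'
#' Validates the documented schema, coerces orientation columns to numeric
#' and wraps them into `[0, 180)` (with a warning when wrapping changed any
#' value). Missing required columns raise a schema error naming them;
#' orientation entries that cannot be parsed raise an error listing the row
#' indices.
#'
#' @param path Path to a CSV file.
#' @return A trial-table data.frame.
#' @export
read_trial_table <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_table_columns, names(tt))
  if (length(miss)) {
    stop("trial table schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("stimulus_ori", "response_ori", "prev_inducer_ori")) {
    raw <- tt[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad)) {
      stop("unparsable orientation in column ", col, " at row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    wrapped <- num %% 180
    if (any(abs(wrapped - num) > 1e-9, na.rm = TRUE)) {
      warning("column ", col, " contained orientations outside [0, 180); wrapped",
              call. = FALSE)
    }
    tt[[col]] <- wrapped
  }
  tt$excluded <- as.logical(tt$excluded)
  tt
}

#' Write a trial table to CSV
#'
#' @param tt A trial-table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(tt, path) {
  miss <- setdiff(trial_table_columns, names(tt))
  if (length(miss)) {
    stop("trial table schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(tt, path, row.names = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' One nested list holding every tunable the package exposes, at its default:
#' the Bayesian observer's natural-statistics parameters (sigma_s 16.9,
#' gamma 2.6, p_same 0.64, noise levels 6/9/12 degrees), the demixing-model
#' simulation grids, and the analysis settings (kernel bandwidth, alpha,
#' outlier rules).
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    observer = list(sigma_s = 16.9, gamma = 2.6, p_same = 0.64,
                    grid_step = 0.5, noise_levels = c(6, 9, 12)),
    demix = list(sigma11 = c(12, 16, 20, 24, 28), sigma12 = c(40, 60, 80),
                 sigma_temp = 20, dprime_temp = 1, pi1 = 0.5, n_meas = 100,
                 n_restarts = 50),
    analysis = list(bandwidth = 10, alpha = 0.05, outlier_sd_mult = 3,
                    exclusion_circ_sd = 30),
    generator = list(response_sd = 9, cardinal_amplitude = 0,
                     outlier_rate = 0, between_participant_sd = 0.5)
  )
}

# (lower, upper, lower_open): lower_open = 1 means the value must exceed lower
config_ranges <- list(
  "observer.sigma_s" = c(0, Inf, 1), "observer.gamma" = c(0, Inf, 1),
  "observer.p_same" = c(0, 1, 0), "observer.grid_step" = c(0, 180, 1),
  "demix.sigma_temp" = c(0, Inf, 1), "demix.dprime_temp" = c(0, Inf, 0),
  "demix.pi1" = c(0, 1, 1), "demix.n_meas" = c(1, Inf, 0),
  "demix.n_restarts" = c(1, Inf, 0),
  "analysis.bandwidth" = c(0, Inf, 1), "analysis.alpha" = c(0, 0.5, 1),
  "analysis.outlier_sd_mult" = c(0, Inf, 1),
  "analysis.exclusion_circ_sd" = c(0, Inf, 1),
  "generator.response_sd" = c(0, Inf, 1),
  "generator.outlier_rate" = c(0, 0.2, 0),
  "generator.between_participant_sd" = c(0, Inf, 0)
)

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON configuration, fills unspecified entries with the
#' package defaults ([default_config()]), rejects unknown keys and collects
#' all out-of-range values into a single validation error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` returns the
#'   defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(user)) return(cfg)
  problems <- character(0)
  for (sect in names(user)) {
    if (!sect %in% names(cfg)) {
      problems <- c(problems, paste0("unknown section: ", sect))
      next
    }
    for (key in names(user[[sect]])) {
      if (!key %in% names(cfg[[sect]])) {
        problems <- c(problems, paste0("unknown key: ", sect, ".", key))
        next
      }
      cfg[[sect]][[key]] <- user[[sect]][[key]]
    }
  }
  for (nm in names(config_ranges)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- config_ranges[[nm]]
    low_bad <- if (rng[3] == 1) val <= rng[1] else val < rng[1]
    if (any(!is.finite(val)) || any(low_bad) || any(val > rng[2])) {
      problems <- c(problems, sprintf("%s = %s out of range %s%g, %g]",
                                      nm, paste(val, collapse = ","),
                                      if (rng[3] == 1) "(" else "[",
                                      rng[1], rng[2]))
    }
  }
  if (length(problems)) {
    stop("configuration validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' Write a configuration to file
#'
#' @param cfg Configuration list.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Build a run manifest
#'
#' Small reproducibility record emitted alongside generated or analyzed
#' data: the seed, a configuration snapshot, the package version and
#' per-stage row/exclusion counts.
#'
#' @param seed Integer seed of the run.
#' @param config Configuration list used.
#' @param counts Named list of row/exclusion counts per stage.
#' @param path Optional path to also write the manifest as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(seed, config = default_config(), counts = list(),
                         path = NULL) {
  man <- list(seed = seed,
              package = "serialdep",
              version = as.character(utils::packageVersion("serialdep")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              counts = counts,
              config = config)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
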