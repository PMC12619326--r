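#' Wrap orientations into [0, 180)
#'
#' Orientation stimuli are 180-degree periodic: a bar at 185 degrees is the
#' same bar as one at 5 degrees. All orientation values in the package live on
#' this half-circle.
#'
#' @param theta Numeric vector of orientations in degrees.
#' @return Numeric vector wrapped into `[0, 180)`.
#' @examples
#' wrap_ori(c(-10, 5, 185, 360))
#' @export
wrap_ori <- function(theta) {
  if (!is.numeric(theta)) stop("`theta` must be numeric", call. = FALSE)
  theta %% 180
}

#' Signed acute angular difference between orientations
#'
#' Computes `a - b` on the 180-degree-periodic orientation circle, wrapped into
#' the half-open interval `[-90, 90)`. An exact half-turn difference maps to
#' -90 by the half-open convention.
#'
#' @param a,b Numeric vectors of orientations in degrees (recycled).
#' @return Signed differences in degrees, in `[-90, 90)`.
#' @examples
#' ori_diff(45, 35)   #  +10
#' ori_diff(10, 170)  #  +20, wraps across 0/180
#' ori_diff(0, 90)    #  -90, boundary convention
#' @export
ori_diff <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("inputs to ori_diff() must be numeric", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("inputs to ori_diff() must be finite", call. = FALSE)
  }
  ((a - b + 90) %% 180) - 90
}

#' Wrapped-normal density on a circle
#'
#' Density of a normal distribution wrapped onto a circle of circumference
#' `period` (180 for orientations, 360 for full angles), evaluated by direct
#' summation over wraps. The number of wraps adapts to `sigma` so that
#' truncated terms are below 1e-12; very large `sigma` approaches the uniform
#' density `1/period`.
#'
#' @param x Numeric vector of points (degrees) at which to evaluate.
#' @param mu Mean direction in degrees.
#' @param sigma Standard deviation in degrees; must be positive.
#' @param period Circle circumference in degrees, 180 (default) or 360.
#' @return Densities (per degree), same length as `x`.
#' @examples
#' dwrapnorm(30, mu = 20, sigma = 9)
#' @export
dwrapnorm <- function(x, mu, sigma, period = 180) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (!period %in% c(180, 360)) stop("`period` must be 180 or 360", call. = FALSE)
  d <- (x - mu) %% period
  # wraps needed so the farthest retained term is below 1e-12 of the peak
  kmax <- max(10L, as.integer(ceiling(8 * sigma / period)) + 1L)
  out <- 0
  for (k in -kmax:kmax) {
    out <- out + stats::dnorm(d + k * period, mean = 0, sd = sigma)
  }
  out
}

#' Sample from a wrapped normal on the orientation circle
#'
#' @param n Number of draws.
#' @param mu Mean orientation in degrees.
#' @param sigma Standard deviation in degrees.
#' @param period Circle circumference in degrees.
#' @return Draws wrapped into `[0, period)`.
#' @export
rwrapnorm <- function(n, mu, sigma, period = 180) {
  stats::rnorm(n, mean = mu, sd = sigma) %% period
}

#' Circular mean and SD of orientations
#'
#' Orientations are doubled onto the full circle, the resultant vector is
#' computed there, and the mean direction and circular standard deviation are
#' mapped back to orientation degrees. With this convention the circular SD of
#' wrapped-normal data recovers the generating sigma.
#'
#' @param values Numeric vector of orientations in degrees; must be non-empty.
#' @param na.rm Drop missing values first.
#' @return A list with elements `mean` (degrees in `[0, 180)`), `sd` (degrees),
#'   `r` (resultant length on the doubled circle, in `[0, 1]`) and `undefined`
#'   (TRUE when the resultant length is numerically zero, in which case the
#'   mean is meaningless).
#' @examples
#' circ_mean_sd(c(170, 10))$mean  # 0, the circular mean across the wrap
#' @export
circ_mean_sd <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  phi <- values * pi / 90  # doubled angle in radians
  cbar <- mean(cos(phi))
  sbar <- mean(sin(phi))
  r <- sqrt(cbar^2 + sbar^2)
  undefined <- r < 1e-12
  m <- if (undefined) NA_real_ else (atan2(sbar, cbar) * 90 / pi) %% 180
  s <- if (undefined) Inf else sqrt(-2 * log(max(r, .Machine$double.xmin))) * 90 / pi
  list(mean = m, sd = s, r = r, undefined = undefined)
}

# Circular (doubled-angle) weighted mean of orientations; internal workhorse
# shared by the belief-grid read-out and the EM M-step checks.
circ_weighted_mean <- function(values, w) {
  phi <- values * pi / 90
  cbar <- sum(w * cos(phi))
  sbar <- sum(w * sin(phi))
  if (cbar^2 + sbar^2 < 1e-24) return(NA_real_)
  (atan2(sbar, cbar) * 90 / pi) %% 180
}
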