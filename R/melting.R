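#' Negative central-difference derivative of a GP curve
#'
#' At each interior grid point the derivative is the two-point centered
#' difference over the flanking neighbors,
#' `-(GP[i+1] - GP[i-1]) / (T[i+1] - T[i-1])`, sign-flipped so the gel-to-
#' fluid transition appears as a positive peak. Endpoints are dropped rather
#' than estimated one-sided, so the derivative grid has two fewer points
#' than the GP curve. Non-uniform temperature spacing is supported (the
#' stencil is then first-order accurate; it is second-order and exact for
#' quadratics on uniform grids).
#'
#' @param curve a [gp_curve()] with at least 3 points.
#' @return An object of class `"derivative_curve"` with fields
#'   `temperature_C` (interior points) and `neg_dgp_dt` (GP per degC).
#' @export
central_difference <- function(curve) {
  stopifnot(inherits(curve, "gp_curve"))
  n <- length(curve$temperature_C)
  if (n < 3L)
    ld_stop("need at least 3 temperatures for a central difference",
            "laurdan_insufficient_points_error")
  i <- 2:(n - 1L)
  d <- -(curve$gp_mean[i + 1L] - curve$gp_mean[i - 1L]) /
    (curve$temperature_C[i + 1L] - curve$temperature_C[i - 1L])
  structure(list(temperature_C = curve$temperature_C[i],
                 neg_dgp_dt = d,
                 sample_id = curve$sample_id, lipid = curve$lipid,
                 assembly = curve$assembly),
            class = "derivative_curve")
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat(sprintf("-dGP/dT curve: %s, %d interior points, %.2f-%.2f degC, peak %.4g GP/degC\n",
              x$sample_id, length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C), max(x$neg_dgp_dt)))
  invisible(x)
}

#' Decide whether a derivative curve contains a usable transition peak
#'
#' A transition is accepted when the maximum of -dGP/dT is strictly
#' positive, lies at an interior point of the derivative grid, and is at
#' least `prominence_factor` times the median absolute derivative (the
#' baseline level). This guards against reporting a melting temperature for
#' curves without an assayable transition, e.g. a lipid whose transition
#' lies outside the scanned range, or broad featureless mixtures.
#'
#' @param deriv a `"derivative_curve"` from [central_difference()].
#' @param prominence_factor peak-to-baseline ratio threshold (default 3).
#' @return `TRUE` or `FALSE`.
#' @export
detect_transition <- function(deriv, prominence_factor = 3) {
  stopifnot(inherits(deriv, "derivative_curve"))
  y <- deriv$neg_dgp_dt
  if (length(y) == 0L) return(FALSE)
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(FALSE)
  m <- y[i]
  if (!(m > 0)) return(FALSE)
  if (all(y == y[1L])) return(FALSE)
  m >= prominence_factor * stats::median(abs(y))
}

#' Melting temperature from the derivative peak
#'
#' The main transition temperature is the temperature at which -dGP/dT is
#' maximal. Ties are broken toward the lowest temperature so results on an
#' integer-degree grid are reproducible. With `refine = TRUE` a parabola is
#' fitted through the peak and its two neighbors and the vertex abscissa is
#' returned, clamped to the neighbor interval; the default reports the raw
#' grid temperature.
#'
#' @param deriv a `"derivative_curve"`.
#' @param refine logical; sub-grid parabolic refinement (default `FALSE`).
#' @return Transition temperature in degC.
#' @export
find_tm <- function(deriv, refine = FALSE) {
  stopifnot(inherits(deriv, "derivative_curve"))
  y <- deriv$neg_dgp_dt
  tt <- deriv$temperature_C
  if (length(y) == 0L)
    ld_stop("empty derivative curve", "laurdan_no_transition_error")
  if (length(y) > 2L && all(y == y[1L]))
    ld_stop("flat derivative: no transition peak", "laurdan_no_transition_error")
  i <- which.max(y)
  if (!refine || i == 1L || i == length(y)) return(tt[i])
  # vertex of the interpolating parabola through (t, y) at i-1, i, i+1
  t0 <- tt[i - 1L]; t1 <- tt[i]; t2 <- tt[i + 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- (t1 - t0) * (y1 - y2) - (t1 - t2) * (y1 - y0)
  if (denom == 0) return(t1)
  vertex <- t1 - 0.5 * ((t1 - t0)^2 * (y1 - y2) -
                          (t1 - t2)^2 * (y1 - y0)) / denom
  min(max(vertex, t0), t2)
}

#' Width at half-maximum of the derivative peak
#'
#' Cooperativity measure: the temperature width between the two
#' half-maximum crossings nearest the peak of -dGP/dT, each located by
#' linear interpolation between the bracketing grid points. If the peak is
#' truncated at either end of the measured range (the derivative never
#' falls below half maximum on that side) the width is undefined and a
#' truncated-peak error is raised; [fit_melting()] records `NA` in that
#' case rather than extrapolating.
#'
#' @param deriv a `"derivative_curve"`.
#' @return Full width at half maximum in degC.
#' @export
fwhm <- function(deriv) {
  stopifnot(inherits(deriv, "derivative_curve"))
  y <- deriv$neg_dgp_dt
  tt <- deriv$temperature_C
  if (length(y) < 3L)
    ld_stop("need at least 3 derivative points", "laurdan_insufficient_points_error")
  i <- which.max(y)
  half <- y[i] / 2
  cross <- function(j, k) {
    # linear interpolation of the half-max crossing between grid points j, k
    tt[j] + (half - y[j]) / (y[k] - y[j]) * (tt[k] - tt[j])
  }
  left <- NA_real_
  j <- i - 1L
  while (j >= 1L) {
    if (y[j] <= half) {
      left <- if (y[j] == half) tt[j] else cross(j, j + 1L)
      break
    }
    j <- j - 1L
  }
  right <- NA_real_
  j <- i + 1L
  while (j <= length(y)) {
    if (y[j] <= half) {
      right <- if (y[j] == half) tt[j] else cross(j - 1L, j)
      break
    }
    j <- j + 1L
  }
  if (is.na(left) || is.na(right))
    ld_stop("peak truncated at the range edge: no half-maximum crossing on one side",
            "laurdan_truncated_peak_error")
  right - left
}

#' Area under the derivative peak (enthalpy proxy)
#'
#' Trapezoidal integral of -dGP/dT over its temperature span. By the
#' fundamental theorem of calculus this approximates the total GP drop
#' across the measured range; it is an enthalpy proxy in GP units, not a
#' calorimetric enthalpy.
#'
#' @param deriv a `"derivative_curve"` with at least 2 points.
#' @return Area in GP units.
#' @export
auc <- function(deriv) {
  stopifnot(inherits(deriv, "derivative_curve"))
  y <- deriv$neg_dgp_dt
  tt <- deriv$temperature_C
  if (length(y) < 2L)
    ld_stop("need at least 2 derivative points", "laurdan_insufficient_points_error")
  sum(diff(tt) * (y[-1L] + y[-length(y)]) / 2)
}

#' Transition-temperature shift against a reference bilayer
#'
#' `sample Tm - reference Tm`; positive means the sample transition is
#' right-shifted (higher temperature) relative to the reference, typically
#' an LUV of the same lipid composition. If either fit has no detected
#' transition the shift is `NA` with a warning.
#'
#' @param sample,reference [fit_melting()] results.
#' @return Shift in degC, or `NA`.
#' @export
delta_tm <- function(sample, reference) {
  stopifnot(inherits(sample, "melting_fit"),
            inherits(reference, "melting_fit"))
  if (!isTRUE(sample$transition_detected) ||
      !isTRUE(reference$transition_detected)) {
    warning("transition not detected in sample and/or reference; delta Tm is NA")
    return(NA_real_)
  }
  sample$tm_C - reference$tm_C
}
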