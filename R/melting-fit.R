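#' Fit the derivative-based melting analysis to a GP curve
#'
#' The central estimator of the package. Takes a (replicate-aggregated) GP
#' versus temperature curve, optionally smooths it, forms the negative
#' central-difference derivative, and extracts the melting parameters:
#'
#' * `tm_C` — main transition temperature, the derivative peak location
#'   ([find_tm()]); `NA` when no transition is detected;
#' * `fwhm_C` — relative cooperativity, the width at half maximum of the
#'   peak ([fwhm()]); `NA` when the peak is truncated at the range edge;
#' * `auc_gp` — enthalpy proxy, the trapezoidal area under the peak
#'   ([auc()]), equal (up to discretization) to the GP drop across the
#'   range;
#' * `gp_high`/`gp_low` — GP at the lowest/highest measured temperature
#'   (the ordered and disordered plateaus when the range brackets the
#'   transition);
#' * `delta_tm_C` — shift versus a reference fit, when one is supplied.
#'
#' @param curve a [gp_curve()] with at least 3 temperatures.
#' @param smooth optional odd moving-average window (see [smooth_gp()]);
#'   default none — the analysis is designed for raw GP.
#' @param refine logical, sub-grid parabolic peak refinement (default
#'   `FALSE`: grid-resolution temperatures are reported).
#' @param prominence_factor transition-detection threshold passed to
#'   [detect_transition()].
#' @param reference optional `"melting_fit"` used to fill `delta_tm_C`.
#' @return An object of class `"melting_fit"` with the fields above plus
#'   the input curve (`curve`), the derivative curve (`deriv`) and
#'   `transition_detected`.
#' @examples
#' model <- melting_preset("DPPC", "LUV")
#' tt <- seq(31, 51, by = 1)
#' curve <- gp_curve(tt, gp_truth(tt, model), sample_id = "DPPC_LUV")
#' fit <- fit_melting(curve)
#' coef(fit)
#' @export
fit_melting <- function(curve, smooth = NULL, refine = FALSE,
                        prominence_factor = 3, reference = NULL) {
  stopifnot(inherits(curve, "gp_curve"))
  if (!is.null(smooth)) curve <- smooth_gp(curve, smooth)
  deriv <- central_difference(curve)
  detected <- detect_transition(deriv, prominence_factor)
  tm <- if (detected) find_tm(deriv, refine = refine) else NA_real_
  width <- if (detected) {
    tryCatch(fwhm(deriv),
             laurdan_truncated_peak_error = function(e) NA_real_)
  } else NA_real_
  area <- auc(deriv)
  n <- length(curve$gp_mean)
  fit <- structure(list(sample_id = curve$sample_id, lipid = curve$lipid,
                        assembly = curve$assembly,
                        tm_C = tm, fwhm_C = width, auc_gp = area,
                        gp_high = curve$gp_mean[1L],
                        gp_low = curve$gp_mean[n],
                        transition_detected = detected,
                        delta_tm_C = NA_real_,
                        reference_id = NA_character_,
                        curve = curve, deriv = deriv),
                   class = "melting_fit")
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "melting_fit"))
    fit$delta_tm_C <- delta_tm(fit, reference)
    fit$reference_id <- reference$sample_id
  }
  fit
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("Melting analysis: %s (%s, %s)\n", x$sample_id, x$lipid,
              x$assembly))
  if (x$transition_detected) {
    cat(sprintf("  Tm = %.2f degC, FWHM = %s degC, AUC = %.4f GP units\n",
                x$tm_C,
                if (is.na(x$fwhm_C)) "NA (truncated peak)"
                else sprintf("%.2f", x$fwhm_C),
                x$auc_gp))
    if (!is.na(x$delta_tm_C))
      cat(sprintf("  delta Tm vs %s = %+.2f degC\n", x$reference_id,
                  x$delta_tm_C))
  } else {
    cat("  no transition detected in the measured range\n")
  }
  invisible(x)
}

#' Summarize a melting fit as a flat record
#'
#' @param object a `"melting_fit"`.
#' @param ... unused.
#' @return Named list with `sample_id, tm_C, fwhm_C, auc_gp, gp_low,
#'   gp_high, transition_detected, delta_tm_C, reference_id` — the record
#'   serialized by [write_melting_summary()].
#' @export
summary.melting_fit <- function(object, ...) {
  list(sample_id = object$sample_id,
       tm_C = object$tm_C, fwhm_C = object$fwhm_C,
       auc_gp = object$auc_gp, gp_low = object$gp_low,
       gp_high = object$gp_high,
       transition_detected = object$transition_detected,
       delta_tm_C = object$delta_tm_C,
       reference_id = object$reference_id)
}

#' @export
coef.melting_fit <- function(object, ...) {
  c(tm_C = object$tm_C, fwhm_C = object$fwhm_C, auc_gp = object$auc_gp,
    gp_high = object$gp_high, gp_low = object$gp_low)
}

#' Plot a melting fit: GP curve and its derivative peak
#'
#' @param x a `"melting_fit"`.
#' @param ... further graphical parameters for the GP panel.
#' @export
plot.melting_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$curve, ...)
  if (x$transition_detected) graphics::abline(v = x$tm_C, lty = 2)
  graphics::plot(x$deriv$temperature_C, x$deriv$neg_dgp_dt, type = "b",
                 pch = 16, xlab = "Temperature (°C)",
                 ylab = expression(-dGP / dT))
  if (x$transition_detected) graphics::abline(v = x$tm_C, lty = 2)
  invisible(x)
}

#' Residuals of a melting fit against the two-state logistic shape
#'
#' Fits the closed-form two-state GP sigmoid with the estimated transition
#' parameters (midpoint `tm_C`, width from `fwhm_C`, plateaus `gp_high`,
#' `gp_low`) and returns observed minus fitted GP. Useful as a quick check
#' of how well a measured curve conforms to a simple two-state transition.
#'
#' @param object a `"melting_fit"` with a detected, non-truncated
#'   transition.
#' @param ... unused.
#' @return Numeric vector of GP residuals on the curve's temperature grid.
#' @export
residuals.melting_fit <- function(object, ...) {
  if (!object$transition_detected || is.na(object$fwhm_C))
    ld_stop("residuals need a detected transition with a finite width",
            "laurdan_no_transition_error")
  k <- object$fwhm_C / (2 * log(3 + 2 * sqrt(2)))
  model <- two_state_model(object$tm_C, k, gp_gel = object$gp_high,
                           gp_fluid = object$gp_low)
  object$curve$gp_mean - gp_truth(object$curve$temperature_C, model)
}
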