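#' Laurdan generalized polarization of one spectrum
#'
#' GP = (I_440 - I_490) / (I_440 + I_490), where the two intensities are
#' read at the exact grid wavelengths of the ordered (440 nm) and disordered
#' (490 nm) emission channels. Higher GP means tighter lipid packing. No
#' bandwidth integration and no interpolation is performed: a channel
#' wavelength absent from the grid is an error.
#'
#' @param spectrum an [emission_spectrum()].
#' @param lambda_ordered,lambda_disordered channel wavelengths in nm
#'   (defaults 440 and 490).
#' @return GP value in \[-1, 1\].
#' @export
compute_gp <- function(spectrum, lambda_ordered = 440,
                       lambda_disordered = 490) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  pick <- function(lambda) {
    i <- which(abs(spectrum$wavelength_nm - lambda) < 1e-6)
    if (length(i) != 1L)
      ld_stop(sprintf("wavelength %g nm is not on the spectrum grid (no interpolation is performed)",
                      lambda),
              "laurdan_missing_channel_error")
    spectrum$intensity[i]
  }
  i_ord <- pick(lambda_ordered)
  i_dis <- pick(lambda_disordered)
  denom <- i_ord + i_dis
  if (denom <= 0)
    ld_stop("degenerate spectrum: zero intensity in both GP channels",
            "laurdan_degenerate_spectrum_error")
  (i_ord - i_dis) / denom
}

#' GP-versus-temperature curve container
#'
#' Per-sample GP values on a strictly increasing temperature grid, with a
#' replicate mean, a sample standard deviation (n-1 denominator; `NA` when
#' only one replicate contributed) and the replicate count per point.
#'
#' @param temperature_C strictly increasing numeric vector.
#' @param gp_mean GP values in \[-1, 1\], same length.
#' @param gp_sd non-negative numeric or `NA`, same length.
#' @param n_replicates positive integer (scalar or per point).
#' @param sample_id,lipid,assembly character labels.
#' @return An object of class `"gp_curve"`.
#' @export
gp_curve <- function(temperature_C, gp_mean, gp_sd = NA_real_,
                     n_replicates = 1L, sample_id = "sample",
                     lipid = "unknown", assembly = "other") {
  temperature_C <- as.numeric(temperature_C)
  gp_mean <- as.numeric(gp_mean)
  n <- length(temperature_C)
  if (n < 1L || length(gp_mean) != n)
    ld_stop("temperatures and GP values must be non-empty and equal length",
            "laurdan_validation_error")
  if (any(diff(temperature_C) <= 0))
    ld_stop("temperatures must be strictly increasing",
            "laurdan_validation_error")
  if (any(is.finite(gp_mean) & abs(gp_mean) > 1 + 1e-9))
    ld_stop("GP values must lie in [-1, 1]", "laurdan_validation_error")
  gp_sd <- rep_len(as.numeric(gp_sd), n)
  if (any(!is.na(gp_sd) & gp_sd < 0))
    ld_stop("gp_sd must be non-negative or NA", "laurdan_validation_error")
  n_replicates <- rep_len(as.integer(n_replicates), n)
  if (any(is.na(n_replicates) | n_replicates < 1L))
    ld_stop("n_replicates must be positive", "laurdan_validation_error")
  structure(list(temperature_C = temperature_C, gp_mean = gp_mean,
                 gp_sd = gp_sd, n_replicates = n_replicates,
                 sample_id = as.character(sample_id),
                 lipid = as.character(lipid),
                 assembly = as.character(assembly)),
            class = "gp_curve")
}

#' @export
print.gp_curve <- function(x, ...) {
  cat(sprintf("GP curve: %s (%s, %s)\n", x$sample_id, x$lipid, x$assembly))
  cat(sprintf("  %d temperatures, %.2f-%.2f degC, GP %.4f to %.4f, max %d replicate(s)\n",
              length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C), min(x$gp_mean), max(x$gp_mean),
              max(x$n_replicates)))
  invisible(x)
}

#' @export
as.data.frame.gp_curve <- function(x, ...) {
  data.frame(sample_id = x$sample_id, lipid = x$lipid,
             assembly = x$assembly, temperature_C = x$temperature_C,
             gp_mean = x$gp_mean, gp_sd = x$gp_sd,
             n_replicates = x$n_replicates, stringsAsFactors = FALSE)
}

#' @export
plot.gp_curve <- function(x, ...) {
  graphics::plot(x$temperature_C, x$gp_mean, type = "b", pch = 16,
                 xlab = "Temperature (°C)", ylab = "GP",
                 main = x$sample_id, ...)
  has_sd <- !is.na(x$gp_sd)
  if (any(has_sd))
    graphics::arrows(x$temperature_C[has_sd],
                     x$gp_mean[has_sd] - x$gp_sd[has_sd],
                     x$temperature_C[has_sd],
                     x$gp_mean[has_sd] + x$gp_sd[has_sd],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Build a single-replicate GP curve from a scan-averaged spectrum series
#'
#' Computes GP at every temperature of a series of scan-averaged spectra
#' from one replicate of one sample and assembles the temperature-sorted
#' curve.
#'
#' @param series list of scan-averaged [emission_spectrum()] objects, one
#'   per temperature, sharing sample, lipid, assembly and replicate.
#' @param lambda_ordered,lambda_disordered GP channel wavelengths (nm).
#' @return A [gp_curve()] with `n_replicates = 1` and `gp_sd = NA`.
#' @export
build_gp_curve <- function(series, lambda_ordered = 440,
                           lambda_disordered = 490) {
  if (inherits(series, "emission_spectrum")) series <- list(series)
  if (length(series) < 1L)
    ld_stop("empty spectrum series", "laurdan_validation_error")
  stopifnot(all(vapply(series, inherits, logical(1), "emission_spectrum")))
  ref <- series[[1L]]
  for (s in series[-1L])
    if (!identical(s$sample_id, ref$sample_id) ||
        !identical(s$lipid, ref$lipid) ||
        !identical(s$assembly, ref$assembly) ||
        s$replicate != ref$replicate)
      ld_stop("series mixes samples, lipids, assemblies or replicates",
              "laurdan_validation_error")
  temps <- vapply(series, `[[`, numeric(1), "temperature_C")
  if (anyDuplicated(.temp_key(temps)))
    ld_stop("duplicate temperatures in series (scan-average first)",
            "laurdan_validation_error")
  ord <- order(temps)
  gp <- vapply(ord, function(i) {
    tryCatch(compute_gp(series[[i]], lambda_ordered, lambda_disordered),
             laurdan_error = function(e)
               ld_stop(sprintf("at %.2f degC: %s", temps[i],
                               conditionMessage(e)),
                       class(e)[1L]))
  }, numeric(1))
  gp_curve(temps[ord], gp, gp_sd = NA_real_, n_replicates = 1L,
           sample_id = ref$sample_id, lipid = ref$lipid,
           assembly = ref$assembly)
}

#' Aggregate replicate GP curves
#'
#' Per-temperature arithmetic mean and sample standard deviation (n-1
#' denominator) across independent replicate curves sharing one temperature
#' grid, as conventionally reported for triplicate measurements. A single
#' input curve is returned with `gp_sd = NA`.
#'
#' @param curves list of single-replicate [gp_curve()] objects with
#'   identical temperature grids and labels.
#' @return A [gp_curve()] with replicate mean, SD and count.
#' @export
aggregate_replicates <- function(curves) {
  if (inherits(curves, "gp_curve")) curves <- list(curves)
  if (length(curves) < 1L)
    ld_stop("need at least one GP curve", "laurdan_validation_error")
  stopifnot(all(vapply(curves, inherits, logical(1), "gp_curve")))
  ref <- curves[[1L]]
  for (cv in curves[-1L]) {
    if (length(cv$temperature_C) != length(ref$temperature_C) ||
        any(abs(cv$temperature_C - ref$temperature_C) > 1e-9)) {
      off <- if (length(cv$temperature_C) == length(ref$temperature_C))
        ref$temperature_C[abs(cv$temperature_C - ref$temperature_C) > 1e-9]
      else c(cv$temperature_C, ref$temperature_C)
      ld_stop(sprintf("replicate temperature grids differ (offending temperatures: %s)",
                      paste(format(unique(off)), collapse = ", ")),
              "laurdan_grid_mismatch_error")
    }
    if (!identical(cv$sample_id, ref$sample_id))
      ld_stop("replicate curves mix samples", "laurdan_validation_error")
  }
  n <- length(curves)
  mat <- vapply(curves, `[[`, numeric(length(ref$gp_mean)), "gp_mean")
  mat <- matrix(mat, ncol = n)
  gp_mean <- rowMeans(mat)
  gp_sd <- if (n > 1L) apply(mat, 1L, stats::sd) else NA_real_
  gp_curve(ref$temperature_C, gp_mean, gp_sd = gp_sd, n_replicates = n,
           sample_id = ref$sample_id, lipid = ref$lipid,
           assembly = ref$assembly)
}

#' Centered moving-average smoothing of a GP curve
#'
#' Optional pre-smoothing for noisy curves (off by default everywhere: the
#' analysis is designed for raw GP). The window must be odd; near the curve
#' ends the window shrinks symmetrically so no point is extrapolated.
#'
#' @param curve a [gp_curve()].
#' @param window odd integer window width >= 3.
#' @return The smoothed [gp_curve()].
#' @export
smooth_gp <- function(curve, window) {
  stopifnot(inherits(curve, "gp_curve"))
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    ld_stop("smoothing window must be an odd integer >= 3",
            "laurdan_validation_error")
  n <- length(curve$gp_mean)
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    mean(curve$gp_mean[(i - k):(i + k)])
  }, numeric(1))
  out <- curve
  out$gp_mean <- sm
  out
}
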