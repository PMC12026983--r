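#' Emission spectrum container
#'
#' Holds one wavelength-resolved fluorescence intensity trace acquired at a
#' single temperature, together with the sample metadata used throughout the
#' pipeline (lipid, assembly, replicate, scan). Intensities are in arbitrary
#' fluorescence units on a strictly increasing wavelength grid, nominally
#' 400--540 nm in 1 nm steps.
#'
#' @param wavelength_nm numeric, strictly increasing, length >= 2.
#' @param intensity numeric, finite and non-negative, same length as
#'   `wavelength_nm`.
#' @param temperature_C acquisition temperature in degrees Celsius.
#' @param sample_id,lipid character labels.
#' @param assembly one of `"LUV"`, `"spMSP1D1"`, `"spNW15"`, `"spNW25"`,
#'   `"spNW50"`, `"other"`.
#' @param replicate positive integer.
#' @param scan positive integer, or `"averaged"` for a scan-averaged
#'   spectrum.
#' @return An object of class `"emission_spectrum"`.
#' @seealso [average_scans()], [compute_gp()], [render_spectrum()]
#' @export
emission_spectrum <- function(wavelength_nm, intensity, temperature_C,
                              sample_id = "sample", lipid = "unknown",
                              assembly = "other", replicate = 1L,
                              scan = 1L) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) < 2L)
    ld_stop("wavelength grid must have at least 2 points",
            "laurdan_validation_error")
  if (length(wavelength_nm) != length(intensity))
    ld_stop("wavelengths and intensities must have equal length",
            "laurdan_validation_error")
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    ld_stop("wavelengths must be finite and strictly increasing",
            "laurdan_validation_error")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    ld_stop("intensities must be finite and non-negative",
            "laurdan_validation_error")
  if (!is.numeric(temperature_C) || length(temperature_C) != 1L ||
      !is.finite(temperature_C))
    ld_stop("temperature_C must be a single finite number",
            "laurdan_validation_error")
  assembly <- as.character(assembly)
  if (!assembly %in% .assemblies)
    ld_stop(sprintf("unknown assembly '%s' (expected one of %s)", assembly,
                    paste(.assemblies, collapse = ", ")),
            "laurdan_validation_error")
  scan <- if (is.character(scan)) unname(scan) else scan
  if (!identical(scan, "averaged")) {
    scan <- as.integer(scan)
    if (is.na(scan) || scan < 1L)
      ld_stop("scan must be a positive integer or \"averaged\"",
              "laurdan_validation_error")
  }
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    ld_stop("replicate must be a positive integer",
            "laurdan_validation_error")
  structure(list(wavelength_nm = wavelength_nm,
                 intensity = intensity,
                 temperature_C = as.numeric(temperature_C),
                 sample_id = as.character(sample_id),
                 lipid = as.character(lipid),
                 assembly = assembly,
                 replicate = replicate,
                 scan = scan),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "Emission spectrum: %s (%s, %s) replicate %d scan %s\n",
    x$sample_id, x$lipid, x$assembly, x$replicate, as.character(x$scan)))
  cat(sprintf("  %d points, %.0f-%.0f nm, T = %.2f degC\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$temperature_C))
  invisible(x)
}

#' @export
as.data.frame.emission_spectrum <- function(x, ...) {
  data.frame(sample_id = x$sample_id, lipid = x$lipid,
             assembly = x$assembly, replicate = x$replicate,
             scan = as.character(x$scan), temperature_C = x$temperature_C,
             wavelength_nm = x$wavelength_nm, intensity = x$intensity,
             stringsAsFactors = FALSE)
}

#' Average repeated instrument scans of one spectrum
#'
#' Pointwise arithmetic mean of the intensities of repeated scans acquired on
#' the same sample, replicate and temperature. Averaging happens on raw
#' spectra, before any GP computation. Wavelength grids must be identical;
#' mismatched grids are an error, never interpolated, because the 1 nm grid
#' is fixed by the acquisition protocol and silent resampling would hide
#' acquisition faults.
#'
#' @param spectra list of [emission_spectrum()] objects sharing sample,
#'   replicate and temperature (to 0.01 degC) on an identical wavelength
#'   grid.
#' @return One `"emission_spectrum"` with the mean intensities and
#'   `scan = "averaged"`; other metadata is taken from the first spectrum.
#' @export
average_scans <- function(spectra) {
  if (inherits(spectra, "emission_spectrum")) spectra <- list(spectra)
  if (length(spectra) < 1L)
    ld_stop("need at least one spectrum", "laurdan_validation_error")
  stopifnot(all(vapply(spectra, inherits, logical(1), "emission_spectrum")))
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (length(s$wavelength_nm) != length(ref$wavelength_nm) ||
        any(s$wavelength_nm != ref$wavelength_nm))
      ld_stop("scans have mismatched wavelength grids (no interpolation is performed)",
              "laurdan_grid_mismatch_error")
    if (.temp_key(s$temperature_C) != .temp_key(ref$temperature_C))
      ld_stop("scans mix different temperatures", "laurdan_validation_error")
    if (!identical(s$sample_id, ref$sample_id) ||
        s$replicate != ref$replicate)
      ld_stop("scans mix different samples or replicates",
              "laurdan_validation_error")
  }
  mean_int <- rowMeans(vapply(spectra, `[[`, numeric(length(ref$intensity)),
                              "intensity"))
  emission_spectrum(ref$wavelength_nm, mean_int, ref$temperature_C,
                    sample_id = ref$sample_id, lipid = ref$lipid,
                    assembly = ref$assembly, replicate = ref$replicate,
                    scan = "averaged")
}
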