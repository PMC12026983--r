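#' Two-state melting model
#'
#' Van't Hoff-style two-state description of the gel to liquid-crystalline
#' transition: the ordered (gel) fraction follows a logistic function of
#' temperature, `f(T) = 1 / (1 + exp((T - tm_C) / k_C))`, strictly
#' decreasing in T, and GP interpolates linearly between the two plateaus.
#'
#' @param tm_C transition midpoint in degC.
#' @param k_C positive transition width (degC); smaller is more
#'   cooperative. The derivative peak of the resulting GP sigmoid has
#'   FWHM = `2 k_C ln(3 + 2 sqrt(2))`.
#' @param gp_gel,gp_fluid GP plateaus in \[-1, 1\] with
#'   `gp_fluid < gp_gel`.
#' @return An object of class `"two_state_model"`.
#' @export
two_state_model <- function(tm_C, k_C, gp_gel = 0.55, gp_fluid = -0.15) {
  if (!is.finite(tm_C)) ld_stop("tm_C must be finite", "laurdan_validation_error")
  if (!is.finite(k_C) || k_C <= 0)
    ld_stop("k_C must be positive", "laurdan_validation_error")
  if (abs(gp_gel) > 1 || abs(gp_fluid) > 1 || gp_fluid >= gp_gel)
    ld_stop("need -1 <= gp_fluid < gp_gel <= 1", "laurdan_validation_error")
  structure(list(tm_C = as.numeric(tm_C), k_C = as.numeric(k_C),
                 gp_gel = as.numeric(gp_gel),
                 gp_fluid = as.numeric(gp_fluid)),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf("Two-state melting model: Tm = %g degC, k = %g degC, GP %g -> %g\n",
              x$tm_C, x$k_C, x$gp_gel, x$gp_fluid))
  invisible(x)
}

#' Ordered (gel) lipid fraction at a temperature
#'
#' @param temperature_C temperature(s) in degC; vectorized.
#' @param model a [two_state_model()].
#' @return Fraction(s) in (0, 1).
#' @export
ordered_fraction <- function(temperature_C, model) {
  stopifnot(inherits(model, "two_state_model"))
  1 / (1 + exp((temperature_C - model$tm_C) / model$k_C))
}

#' Noise-free GP of the two-state model
#'
#' `gp_fluid + (gp_gel - gp_fluid) * ordered_fraction(T)`.
#'
#' @inheritParams ordered_fraction
#' @return GP value(s).
#' @export
gp_truth <- function(temperature_C, model) {
  stopifnot(inherits(model, "two_state_model"))
  model$gp_fluid +
    (model$gp_gel - model$gp_fluid) * ordered_fraction(temperature_C, model)
}

#' Emission band model for synthetic Laurdan spectra
#'
#' Two peak-normalized Gaussian emission bands: an ordered-phase band at
#' 440 nm and a disordered-phase band at 490 nm. The default width
#' `sigma_nm = 18` keeps the cross-talk between the two GP channels around
#' 2%, which preserves realistic band overlap while leaving the rendered
#' GP an exactly linear (hence monotone) function of the ordered fraction.
#'
#' @param center_ordered_nm,center_disordered_nm band centers (nm).
#' @param sigma_nm common Gaussian width (nm), > 0.
#' @param amplitude peak intensity (arbitrary units), > 0.
#' @return An object of class `"band_model"`.
#' @export
band_model <- function(center_ordered_nm = 440, center_disordered_nm = 490,
                       sigma_nm = 18, amplitude = 1) {
  if (!is.finite(sigma_nm) || sigma_nm <= 0)
    ld_stop("sigma_nm must be positive", "laurdan_validation_error")
  if (!is.finite(amplitude) || amplitude <= 0)
    ld_stop("amplitude must be positive", "laurdan_validation_error")
  structure(list(center_ordered_nm = as.numeric(center_ordered_nm),
                 center_disordered_nm = as.numeric(center_disordered_nm),
                 sigma_nm = as.numeric(sigma_nm),
                 amplitude = as.numeric(amplitude)),
            class = "band_model")
}

# Built-in presets. LUV transition midpoints are the literature transition
# temperatures of the pure lipids; the 11 nm disc (spMSP1D1) midpoints
# carry the observed shifts (+5 DMPC, +2 DPPC, 0 DSPC). Midpoints for the
# intermediate disc sizes interpolate the observed ordering (Tm decreases
# toward the LUV value as disc diameter grows; spMSP1D1 and spNW15 are
# indistinguishable). Widths k encode the cooperativity ordering: LUVs are
# sharpest, small discs broadest. GP plateaus are nominal defaults.
.presets <- data.frame(
  lipid    = rep(c("DMPC", "DPPC", "DSPC", "POPC"), times = 5),
  assembly = rep(c("LUV", "spMSP1D1", "spNW15", "spNW25", "spNW50"),
                 each = 4),
  tm_C = c(24, 41, 54, -2,    # LUV
           29, 43, 54, -2,    # spMSP1D1 (11 nm)
           29, 43, 54, -2,    # spNW15
           27, 42, 54, -2,    # spNW25
           24, 41, 54, -2),   # spNW50
  k_C  = rep(c(0.4, 2.5, 2.5, 1.5, 0.8), each = 4),
  stringsAsFactors = FALSE)

#' Built-in synthetic melting presets
#'
#' `melting_preset()` returns the [two_state_model()] for one
#' lipid/assembly combination; `list_presets()` returns the whole preset
#' table.
#'
#' @param lipid one of `"DMPC"`, `"DPPC"`, `"DSPC"`, `"POPC"`.
#' @param assembly one of `"LUV"`, `"spMSP1D1"`, `"spNW15"`, `"spNW25"`,
#'   `"spNW50"`.
#' @param gp_gel,gp_fluid GP plateaus (common defaults for all presets).
#' @return A [two_state_model()] (`melting_preset`) or a data frame with
#'   columns `lipid, assembly, tm_C, k_C` (`list_presets`).
#' @export
melting_preset <- function(lipid, assembly, gp_gel = 0.55,
                           gp_fluid = -0.15) {
  hit <- .presets$lipid == lipid & .presets$assembly == assembly
  if (!any(hit))
    ld_stop(sprintf("unknown preset '%s:%s'; available presets: %s",
                    lipid, assembly,
                    paste(paste(.presets$lipid, .presets$assembly,
                                sep = ":"), collapse = ", ")),
            "laurdan_unknown_preset_error")
  row <- .presets[hit, ]
  two_state_model(row$tm_C, row$k_C, gp_gel = gp_gel, gp_fluid = gp_fluid)
}

#' @rdname melting_preset
#' @export
list_presets <- function() .presets

#' Render one synthetic emission spectrum
#'
#' Mixture of the two Gaussian emission bands weighted by the ordered
#' fraction: `I(lambda) = A [ f g(lambda; 440, sigma) +
#' (1 - f) g(lambda; 490, sigma) ] + eps`, with `g` peak-normalized to 1,
#' `f` the two-state ordered fraction at the given temperature, and `eps`
#' i.i.d. Gaussian detector noise with SD `noise_sd_frac * A`, after which
#' intensities are clipped at zero. Generation is reproducible for a given
#' seed and leaves the caller's RNG state untouched.
#'
#' @param temperature_C acquisition temperature (degC).
#' @param model a [two_state_model()].
#' @param bands a [band_model()].
#' @param noise_sd_frac noise SD as a fraction of the band amplitude,
#'   >= 0.
#' @param seed optional integer seed for the noise draw.
#' @param wavelength_nm emission grid (default 400--540 nm in 1 nm steps).
#' @param f optional override of the ordered fraction (in \[0, 1\]), e.g.
#'   to render the fully ordered (`f = 1`) or fully disordered (`f = 0`)
#'   limit directly.
#' @param sample_id,lipid,assembly,replicate,scan metadata passed to
#'   [emission_spectrum()].
#' @return An [emission_spectrum()].
#' @export
render_spectrum <- function(temperature_C, model, bands = band_model(),
                            noise_sd_frac = 0, seed = NULL,
                            wavelength_nm = 400:540, f = NULL,
                            sample_id = "synthetic", lipid = "unknown",
                            assembly = "other", replicate = 1L,
                            scan = 1L) {
  stopifnot(inherits(bands, "band_model"))
  if (!is.finite(noise_sd_frac) || noise_sd_frac < 0)
    ld_stop("noise_sd_frac must be >= 0", "laurdan_validation_error")
  if (is.null(f)) {
    f <- ordered_fraction(temperature_C, model)
  } else if (!is.finite(f) || f < 0 || f > 1) {
    ld_stop("f must lie in [0, 1]", "laurdan_validation_error")
  }
  g <- function(center) exp(-(wavelength_nm - center)^2 /
                              (2 * bands$sigma_nm^2))
  intensity <- bands$amplitude *
    (f * g(bands$center_ordered_nm) +
       (1 - f) * g(bands$center_disordered_nm))
  if (noise_sd_frac > 0) {
    eps <- with_local_seed(seed,
      stats::rnorm(length(wavelength_nm), mean = 0,
                   sd = noise_sd_frac * bands$amplitude))
    intensity <- pmax(intensity + eps, 0)
  }
  emission_spectrum(wavelength_nm, intensity, temperature_C,
                    sample_id = sample_id, lipid = lipid,
                    assembly = assembly, replicate = replicate,
                    scan = scan)
}

#' Simulate a full temperature-ramp Laurdan experiment
#'
#' Generates the complete synthetic dataset for one lipid/assembly preset
#' with the acquisition structure the analysis assumes: `n_scans` repeated
#' scans at each temperature, `n_replicates` independent replicates, and
#' additive detector noise. Each (replicate, scan, temperature) spectrum
#' gets a distinct sub-seed derived deterministically from the master
#' seed, so identical calls give byte-identical output files.
#'
#' @param lipid,assembly preset selector (see [list_presets()]); or supply
#'   `model` directly.
#' @param t_min,t_max,step temperature grid (degC); defaults to the preset
#'   midpoint plus/minus 10 degC in 1 degC steps. At least 3 grid points
#'   are required.
#' @param n_replicates,n_scans replicate and scan counts (defaults 3
#'   and 3).
#' @param noise_sd_frac detector-noise SD as a fraction of band amplitude.
#' @param seed master integer seed.
#' @param path optional output file; when given, the dataset is written in
#'   the long CSV dialect of [read_spectra()].
#' @param model optional [two_state_model()] overriding the preset.
#' @param bands a [band_model()].
#' @param sample_id sample label; default `"<lipid>_<assembly>"`.
#' @return List of [emission_spectrum()] objects, invisibly when `path`
#'   is given.
#' @export
simulate_experiment <- function(lipid, assembly, t_min = NULL,
                                t_max = NULL, step = 1, n_replicates = 3,
                                n_scans = 3, noise_sd_frac = 0, seed = 1,
                                path = NULL, model = NULL,
                                bands = band_model(),
                                sample_id = paste(lipid, assembly,
                                                  sep = "_")) {
  if (is.null(model)) model <- melting_preset(lipid, assembly)
  stopifnot(inherits(model, "two_state_model"))
  if (is.null(t_min)) t_min <- model$tm_C - 10
  if (is.null(t_max)) t_max <- model$tm_C + 10
  temps <- seq(t_min, t_max, by = step)
  if (length(temps) < 3L)
    ld_stop("temperature grid must contain at least 3 points",
            "laurdan_validation_error")
  asm <- if (assembly %in% .assemblies) assembly else "other"
  spectra <- vector("list", n_replicates * n_scans * length(temps))
  idx <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (scan_i in seq_len(n_scans)) {
      for (t_i in seq_along(temps)) {
        sub_seed <- (as.numeric(seed) * 1009 + rep_i * 1000003 +
                       scan_i * 10007 + t_i * 101) %% 2147483647
        idx <- idx + 1L
        spectra[[idx]] <- render_spectrum(
          temps[t_i], model, bands = bands,
          noise_sd_frac = noise_sd_frac, seed = sub_seed,
          sample_id = sample_id, lipid = lipid, assembly = asm,
          replicate = rep_i, scan = scan_i)
      }
    }
  }
  if (!is.null(path)) {
    write_spectra(spectra, path)
    return(invisible(spectra))
  }
  spectra
}
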