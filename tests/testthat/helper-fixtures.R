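# Shared fixture builders for the test suite. All fixtures are generated
# in code; nothing is read from disk except files the tests write
# themselves.

# Flat spectrum on the standard grid with chosen intensities at the two GP
# channel wavelengths and `base` everywhere else.
channel_spectrum <- function(i440, i490, base = 10, temperature_C = 25,
                             ...) {
  wl <- 400:540
  intensity <- rep(base, length(wl))
  intensity[wl == 440] <- i440
  intensity[wl == 490] <- i490
  emission_spectrum(wl, intensity, temperature_C, ...)
}

# Noise-free logistic GP curve sampled from a two-state model.
logistic_curve <- function(tm, k, t_min = tm - 10, t_max = tm + 10,
                           step = 1, gp_gel = 0.55, gp_fluid = -0.15,
                           ...) {
  model <- two_state_model(tm, k, gp_gel = gp_gel, gp_fluid = gp_fluid)
  tt <- seq(t_min, t_max, by = step)
  gp_curve(tt, gp_truth(tt, model), ...)
}

# Derivative curve built directly from raw values (bypasses the GP stage)
# for unit tests of the peak-analysis operations.
raw_deriv <- function(temperature_C, neg_dgp_dt) {
  structure(list(temperature_C = temperature_C, neg_dgp_dt = neg_dgp_dt,
                 sample_id = "raw", lipid = "unknown", assembly = "other"),
            class = "derivative_curve")
}

# Random valid emission spectrum (non-negative intensities, standard grid).
random_spectrum <- function() {
  wl <- 400:540
  emission_spectrum(wl, stats::runif(length(wl), min = 0, max = 100), 25)
}

# FWHM of the -dGP/dT peak of a logistic transition with width k, in degC.
logistic_fwhm <- function(k) 2 * k * log(3 + 2 * sqrt(2))
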