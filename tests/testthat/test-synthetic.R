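test_that("ordered fraction follows the two-state logistic", {
  m <- two_state_model(24, 1)
  expect_equal(ordered_fraction(24, m), 0.5)
  expect_equal(ordered_fraction(26, m), 1 / (1 + exp(2)))
  expect_equal(ordered_fraction(-1e4, m), 1, tolerance = 1e-12)
  expect_equal(ordered_fraction(1e4, m), 0, tolerance = 1e-12)
  expect_true(all(diff(ordered_fraction(seq(0, 50, 0.5), m)) < 0))
})

test_that("two-state GP interpolates between the plateaus", {
  m <- two_state_model(41, 2, gp_gel = 0.55, gp_fluid = -0.15)
  expect_equal(gp_truth(41, m), (0.55 - 0.15) / 2)
  expect_equal(gp_truth(41 - 10 * 2, m), 0.55, tolerance = 1e-4)
  # f = 1/4 at T = tm + k ln 3 by closed form
  expect_equal(gp_truth(41 + 2 * log(3), m), -0.15 + 0.25 * 0.7)
})

test_that("model constructors validate their parameters", {
  expect_error(two_state_model(24, 0), class = "laurdan_validation_error")
  expect_error(two_state_model(24, 1, gp_gel = -0.2, gp_fluid = 0.5),
               class = "laurdan_validation_error")
  expect_error(band_model(sigma_nm = -1),
               class = "laurdan_validation_error")
  expect_error(render_spectrum(25, two_state_model(24, 1),
                               noise_sd_frac = -0.1),
               class = "laurdan_validation_error")
  expect_error(melting_preset("DOPC", "LUV"), regexp = "DPPC:LUV",
               class = "laurdan_unknown_preset_error")
})

test_that("rendered spectra peak at the phase-specific band centers", {
  m <- melting_preset("DPPC", "LUV")
  ordered <- render_spectrum(25, m, f = 1)
  disordered <- render_spectrum(25, m, f = 0)
  expect_equal(ordered$wavelength_nm[which.max(ordered$intensity)], 440)
  expect_equal(disordered$wavelength_nm[which.max(disordered$intensity)],
               490)
  # far below / far above the midpoint without forcing f
  cold <- render_spectrum(m$tm_C - 30, m)
  hot <- render_spectrum(m$tm_C + 30, m)
  expect_equal(cold$wavelength_nm[which.max(cold$intensity)], 440)
  expect_equal(hot$wavelength_nm[which.max(hot$intensity)], 490)
})

test_that("noise-free rendered GP matches the closed-form band mixture", {
  m <- melting_preset("DMPC", "LUV")
  g <- function(l, c) exp(-(l - c)^2 / (2 * 18^2))
  a <- g(440, 440); b <- g(440, 490); cc <- g(490, 440); d <- g(490, 490)
  for (tt in c(14, 20, 24, 28, 34)) {
    f <- ordered_fraction(tt, m)
    oracle <- (f * a + (1 - f) * b - f * cc - (1 - f) * d) /
      (f * a + (1 - f) * b + f * cc + (1 - f) * d)
    expect_equal(compute_gp(render_spectrum(tt, m)), oracle,
                 tolerance = 1e-12)
  }
  # the channel cross-talk term itself
  expect_equal(b, exp(-(50 / 18)^2 / 2))
  expect_lt(b, 0.022)
})

test_that("rendered GP is strictly decreasing in temperature for random models", {
  set.seed(7)
  for (i in 1:10) {
    m <- two_state_model(stats::runif(1, 0, 60), stats::runif(1, 0.3, 3))
    tt <- seq(m$tm_C - 12, m$tm_C + 12, by = 0.5)
    gps <- vapply(tt, function(x) compute_gp(render_spectrum(x, m)),
                  numeric(1))
    expect_true(all(diff(gps) < 0))
  }
})

test_that("noise injection is seed-reproducible and leaves RNG state alone", {
  m <- melting_preset("DPPC", "LUV")
  set.seed(123)
  before <- .Random.seed
  s1 <- render_spectrum(41, m, noise_sd_frac = 0.05, seed = 99)
  expect_identical(.Random.seed, before)
  s2 <- render_spectrum(41, m, noise_sd_frac = 0.05, seed = 99)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- render_spectrum(41, m, noise_sd_frac = 0.05, seed = 100)
  expect_false(identical(s1$intensity, s3$intensity))
  expect_true(all(s1$intensity >= 0))
})

test_that("simulated experiments have the full scan/replicate structure", {
  spectra <- simulate_experiment("DMPC", "LUV", t_min = 20, t_max = 28,
                                 step = 2, n_replicates = 3, n_scans = 3,
                                 noise_sd_frac = 0.02, seed = 5)
  expect_length(spectra, 3 * 3 * 5)
  key <- vapply(spectra, function(s)
    paste(s$replicate, s$scan, s$temperature_C), character(1))
  expect_false(anyDuplicated(key) > 0)
  # distinct sub-seeds: scans of the same temperature differ under noise
  same_t <- spectra[key %in% c("1 1 24", "1 2 24")]
  expect_false(identical(same_t[[1]]$intensity, same_t[[2]]$intensity))
  expect_error(simulate_experiment("DMPC", "LUV", t_min = 20, t_max = 21,
                                   step = 1),
               class = "laurdan_validation_error")
})

test_that("identical master seeds give byte-identical simulation files", {
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  simulate_experiment("DPPC", "spMSP1D1", noise_sd_frac = 0.03, seed = 17,
                      path = p1)
  simulate_experiment("DPPC", "spMSP1D1", noise_sd_frac = 0.03, seed = 17,
                      path = p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- tempfile(fileext = ".csv")
  simulate_experiment("DPPC", "spMSP1D1", noise_sd_frac = 0.03, seed = 18,
                      path = p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("scan averaging of noise-free scans is a no-op", {
  spectra <- simulate_experiment("DPPC", "LUV", t_min = 39, t_max = 43,
                                 step = 2, n_replicates = 1, n_scans = 3,
                                 noise_sd_frac = 0, seed = 1)
  at41 <- Filter(function(s) s$temperature_C == 41, spectra)
  avg <- average_scans(at41)
  expect_equal(avg$intensity, at41[[1]]$intensity)
})

test_that("the pipeline recovers every preset midpoint on a 1 degC grid", {
  p <- list_presets()
  for (i in seq_len(nrow(p))) {
    m <- melting_preset(p$lipid[i], p$assembly[i])
    span <- max(10, 6 * m$k_C)
    path <- tempfile(fileext = ".csv")
    simulate_experiment(p$lipid[i], p$assembly[i], t_min = m$tm_C - span,
                        t_max = m$tm_C + span, noise_sd_frac = 0.01,
                        seed = 11, path = path)
    fit <- run_pipeline(path)$fits[[1]]
    expect_true(fit$transition_detected,
                label = paste(p$lipid[i], p$assembly[i], "detected"))
    expect_equal(fit$tm_C, m$tm_C,
                 label = paste(p$lipid[i], p$assembly[i], "tm"))
    unlink(path)
  }
})

test_that("recovered FWHM increases with the preset width parameter", {
  ks <- c(LUV = 0.4, spNW50 = 0.8, spNW25 = 1.5, spMSP1D1 = 2.5)
  widths <- vapply(names(ks), function(asm) {
    m <- melting_preset("DPPC", asm)
    span <- max(10, 6 * m$k_C)
    path <- tempfile(fileext = ".csv")
    simulate_experiment("DPPC", asm, t_min = m$tm_C - span,
                        t_max = m$tm_C + span, noise_sd_frac = 0,
                        seed = 2, path = path)
    w <- run_pipeline(path)$fits[[1]]$fwhm_C
    unlink(path)
    w
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
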