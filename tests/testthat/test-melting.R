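test_that("central difference matches the defining stencil", {
  # constant GP -> zero derivative
  flat <- central_difference(gp_curve(1:5, rep(0.2, 5)))
  expect_equal(flat$neg_dgp_dt, rep(0, 3))
  expect_equal(flat$temperature_C, 2:4)
  # affine GP: exact on any grid, including non-uniform spacing
  tt <- c(0, 1, 2.5, 3, 7)
  aff <- central_difference(gp_curve(tt, -0.02 * tt))
  expect_equal(aff$neg_dgp_dt, rep(0.02, 3))
  # quadratic: exact on uniform grids; scaled into GP range
  tt <- 0:10
  quad <- central_difference(gp_curve(tt, (tt / 10)^2))
  expect_equal(quad$neg_dgp_dt, -2 * (1:9) / 100)
  expect_error(central_difference(gp_curve(1:2, c(0, 0.1))),
               class = "laurdan_insufficient_points_error")
})

test_that("central difference converges at O(h^2) for a cubic", {
  # oracle: symbolic derivative of p(t) = t^3/4000 - t/10 on [0, 10]
  p <- function(t) t^3 / 4000 - t / 10
  dp <- function(t) 3 * t^2 / 4000 - 1 / 10
  err <- vapply(c(1, 0.5, 0.25), function(h) {
    tt <- seq(0, 10, by = h)
    d <- central_difference(gp_curve(tt, p(tt)))
    max(abs(d$neg_dgp_dt + dp(d$temperature_C)))
  }, numeric(1))
  expect_equal(err[1] / err[2], 4, tolerance = 0.05)
  expect_equal(err[2] / err[3], 4, tolerance = 0.05)
})

test_that("Tm is the derivative peak with low-temperature tie-breaking", {
  expect_equal(find_tm(raw_deriv(23:25, c(0.1, 0.5, 0.3))), 24)
  expect_equal(find_tm(raw_deriv(40:41, c(0.5, 0.5))), 40)
  expect_error(find_tm(raw_deriv(1:4, rep(0.2, 4))),
               class = "laurdan_no_transition_error")
  # logistic transition with Tm on the grid is recovered exactly;
  # oracle: the analytic logistic derivative peaks at Tm
  curve <- logistic_curve(41, 0.4, t_min = 31, t_max = 51)
  expect_equal(find_tm(central_difference(curve)), 41)
})

test_that("parabolic refinement interpolates the vertex and clamps", {
  # symmetric peak: vertex at the grid point
  expect_equal(find_tm(raw_deriv(1:3, c(0.1, 0.5, 0.1)), refine = TRUE), 2)
  # known parabola y = -(t - 2.3)^2 sampled at 1, 2, 3
  y <- -(c(1, 2, 3) - 2.3)^2
  expect_equal(find_tm(raw_deriv(1:3, y), refine = TRUE), 2.3)
  # vertex never leaves the neighbor interval
  expect_lte(find_tm(raw_deriv(1:3, c(0.499, 0.5, 0.1)), refine = TRUE), 3)
})

test_that("FWHM interpolates half-maximum crossings", {
  expect_equal(fwhm(raw_deriv(0:2, c(0, 1, 0))), 1)
  # asymmetric peak: crossings at 0.5 and 2.0 -> width 1.5
  expect_equal(fwhm(raw_deriv(0:3, c(0, 1, 0.5, 0))), 1.5)
  expect_error(fwhm(raw_deriv(0:4, c(0, 0.2, 0.4, 0.7, 1))),
               class = "laurdan_truncated_peak_error")
})

test_that("FWHM of a logistic transition converges to 2k ln(3 + 2 sqrt(2))", {
  k <- 2
  target <- logistic_fwhm(k)
  err <- vapply(c(1, 0.1, 0.01), function(h) {
    curve <- logistic_curve(41, k, t_min = 21, t_max = 61, step = h)
    abs(fwhm(central_difference(curve)) - target) / target
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("AUC equals the GP drop across the range", {
  expect_equal(auc(raw_deriv(1:4, rep(0, 4))), 0)
  # descending curve from 0.5 to -0.1: area ~ 0.6
  curve <- logistic_curve(25, 1.2, t_min = 10, t_max = 40, step = 0.5,
                          gp_gel = 0.5, gp_fluid = -0.1)
  expect_equal(auc(central_difference(curve)), 0.6, tolerance = 0.02)
  # default plateaus over tm +/- 10k: drop ~ 0.70
  curve <- logistic_curve(41, 1, t_min = 31, t_max = 51, step = 0.5)
  expect_equal(auc(central_difference(curve)),
               gp_truth(31, two_state_model(41, 1)) -
                 gp_truth(51, two_state_model(41, 1)),
               tolerance = 0.01)
})

test_that("AUC tracks GP(first) - GP(last) on random smooth curves", {
  set.seed(5)
  for (i in seq_len(25L)) {
    # random mixture of 1-3 logistic transitions, plateaus inside range
    n_tr <- sample(1:3, 1)
    tms <- sort(stats::runif(n_tr, 20, 60))
    ks <- stats::runif(n_tr, 0.8, 3)
    amps <- stats::runif(n_tr, 0.1, 0.4)
    tt <- seq(0, 80, by = 1)
    gp <- 0.5
    for (j in seq_len(n_tr))
      gp <- gp - amps[j] / (1 + exp(-(tt - tms[j]) / ks[j]))
    curve <- gp_curve(tt, gp)
    drop <- gp[1] - gp[length(gp)]
    expect_equal(auc(central_difference(curve)), drop, tolerance = 0.02)
  }
})

test_that("transition detection requires an interior, prominent peak", {
  sharp <- central_difference(logistic_curve(41, 0.4, t_min = 31,
                                             t_max = 51))
  expect_true(detect_transition(sharp))
  # strictly linear GP: constant derivative, no transition
  expect_false(detect_transition(
    central_difference(gp_curve(1:10, seq(0.5, -0.4, length.out = 10)))))
  # maximum at an edge of the derivative grid is excluded
  expect_false(detect_transition(raw_deriv(1:5, c(1, 0.1, 0.1, 0.1, 0.2))))
  # prominence threshold is configurable
  broad <- central_difference(logistic_curve(29, 2.5, t_min = 19,
                                             t_max = 39))
  expect_false(detect_transition(broad))
  expect_true(detect_transition(broad, prominence_factor = 1.5))
  # widening the scan restores detection at the default threshold
  wide <- central_difference(logistic_curve(29, 2.5, t_min = 14,
                                            t_max = 44))
  expect_true(detect_transition(wide))
})

test_that("delta Tm is the sample-minus-reference shift", {
  luv <- fit_melting(logistic_curve(24, 0.4, sample_id = "DMPC_LUV"))
  disc <- fit_melting(logistic_curve(29, 2.5, t_min = 14, t_max = 44,
                                     sample_id = "DMPC_disc"))
  expect_equal(delta_tm(disc, luv), 5)
  expect_equal(delta_tm(luv, luv), 0)
  dppc_luv <- fit_melting(logistic_curve(41, 0.4, sample_id = "DPPC_LUV"))
  dppc_disc <- fit_melting(logistic_curve(43, 2.5, t_min = 28, t_max = 58,
                                          sample_id = "DPPC_disc"))
  expect_equal(delta_tm(dppc_disc, dppc_luv), 2)
  flat <- fit_melting(gp_curve(1:5, c(0.5, 0.4, 0.3, 0.2, 0.1)))
  expect_warning(out <- delta_tm(flat, luv), "not detected")
  expect_true(is.na(out))
})

test_that("reported FWHM grows with the transition width parameter", {
  widths <- vapply(c(0.5, 1.5, 3), function(k) {
    curve <- logistic_curve(41, k, t_min = 41 - 8 * k, t_max = 41 + 8 * k,
                            step = 0.1)
    fit_melting(curve)$fwhm_C
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("melting fit collects parameters and supports its methods", {
  curve <- logistic_curve(41, 0.8, t_min = 31, t_max = 51,
                          sample_id = "DPPC_LUV", lipid = "DPPC",
                          assembly = "LUV")
  fit <- fit_melting(curve)
  expect_s3_class(fit, "melting_fit")
  expect_true(fit$transition_detected)
  expect_equal(fit$tm_C, 41)
  expect_equal(fit$gp_high, curve$gp_mean[1])
  expect_equal(fit$gp_low, curve$gp_mean[length(curve$gp_mean)])
  expect_named(coef(fit), c("tm_C", "fwhm_C", "auc_gp", "gp_high",
                            "gp_low"))
  sm <- summary(fit)
  expect_equal(sm$sample_id, "DPPC_LUV")
  expect_output(print(fit), "Tm = 41")
  # residuals of a true two-state curve against the refitted sigmoid are
  # small relative to the GP range
  expect_lt(max(abs(residuals(fit))), 0.05)
})
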