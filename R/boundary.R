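#' Unperturbed lipid area fraction of a nanodisc
#'
#' Treats the disc as a circle of diameter `d` with a rim annulus of width
#' `w` containing the scaffold-perturbed boundary lipids; the unperturbed
#' fraction is the area ratio of the inner circle,
#' `f = ((d/2 - w) / (d/2))^2`, clamped to 0 when the annulus covers the
#' whole disc (`w >= d/2`). `f` is strictly increasing in `d` for fixed
#' `w > 0` and strictly decreasing in `w` for fixed `d`.
#'
#' @param d disc diameter in nm, > 0; vectorized.
#' @param w boundary annulus width in nm, >= 0.
#' @return Unperturbed area fraction(s) in \[0, 1\].
#' @export
unperturbed_fraction <- function(d, w) {
  if (any(!is.finite(d)) || any(d <= 0))
    ld_stop("diameter must be positive", "laurdan_validation_error")
  if (any(!is.finite(w)) || any(w < 0))
    ld_stop("boundary width must be >= 0", "laurdan_validation_error")
  pmax(0, (d / 2 - w) / (d / 2))^2
}

#' Boundary width implied by an observed unperturbed fraction
#'
#' Closed-form inverse of [unperturbed_fraction()]:
#' `w = (d/2) (1 - sqrt(f))`. Round-trips through
#' [unperturbed_fraction()] to machine precision for `w < d/2`. Useful to
#' ask what rim-layer width a reported unperturbed-lipid percentage
#' corresponds to under the annulus-area model.
#'
#' @param d disc diameter in nm, > 0; vectorized.
#' @param f_observed unperturbed fraction(s) in (0, 1\].
#' @return Boundary width(s) in nm.
#' @export
calibrate_boundary_width <- function(d, f_observed) {
  if (any(!is.finite(d)) || any(d <= 0))
    ld_stop("diameter must be positive", "laurdan_validation_error")
  if (any(!is.finite(f_observed)) || any(f_observed <= 0) ||
      any(f_observed > 1))
    ld_stop("f_observed must lie in (0, 1]", "laurdan_validation_error")
  (d / 2) * (1 - sqrt(f_observed))
}

#' Nanodisc geometry record
#'
#' Convenience constructor bundling diameter, boundary width and the
#' implied unperturbed fraction.
#'
#' @param diameter_nm disc diameter (nm), > 0.
#' @param boundary_width_nm rim annulus width (nm), >= 0.
#' @return An object of class `"disc_geometry"` with fields
#'   `diameter_nm`, `boundary_width_nm`, `unperturbed_fraction`.
#' @export
disc_geometry <- function(diameter_nm, boundary_width_nm) {
  structure(list(diameter_nm = as.numeric(diameter_nm),
                 boundary_width_nm = as.numeric(boundary_width_nm),
                 unperturbed_fraction =
                   unperturbed_fraction(diameter_nm, boundary_width_nm)),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat(sprintf("Nanodisc: d = %g nm, boundary w = %g nm, unperturbed fraction = %.3f\n",
              x$diameter_nm, x$boundary_width_nm, x$unperturbed_fraction))
  invisible(x)
}

#' Two-population GP mixture of core and boundary lipids
#'
#' Disc-averaged GP under the assumption that lipids are either
#' unperturbed (core, fraction `f`) or perturbed (rim boundary, fraction
#' `1 - f`): pointwise `f * GP_core + (1 - f) * GP_boundary` on a shared
#' temperature grid.
#'
#' @param f unperturbed fraction in \[0, 1\].
#' @param gp_core_curve,gp_boundary_curve [gp_curve()] objects on
#'   identical temperature grids.
#' @return A [gp_curve()] with the mixed GP (labels from the core curve,
#'   `gp_sd = NA`).
#' @export
two_population_gp <- function(f, gp_core_curve, gp_boundary_curve) {
  stopifnot(inherits(gp_core_curve, "gp_curve"),
            inherits(gp_boundary_curve, "gp_curve"))
  if (!is.finite(f) || f < 0 || f > 1)
    ld_stop("f must lie in [0, 1]", "laurdan_validation_error")
  if (length(gp_core_curve$temperature_C) !=
        length(gp_boundary_curve$temperature_C) ||
      any(abs(gp_core_curve$temperature_C -
                gp_boundary_curve$temperature_C) > 1e-9))
    ld_stop("core and boundary curves are on different temperature grids",
            "laurdan_grid_mismatch_error")
  gp_curve(gp_core_curve$temperature_C,
           f * gp_core_curve$gp_mean +
             (1 - f) * gp_boundary_curve$gp_mean,
           sample_id = gp_core_curve$sample_id,
           lipid = gp_core_curve$lipid,
           assembly = gp_core_curve$assembly)
}

#' Disc-averaged GP under a radial perturbation continuum
#'
#' Models lipid perturbation as a continuum: GP at radius `r` relaxes from
#' the rim value to the bulk value with distance from the disc edge,
#' `GP(r) = gp_bulk + (gp_rim - gp_bulk) * p(R - r)`, and the disc average
#' is the area-weighted integral `(2 / R^2) * int_0^R r GP(r) dr` with
#' `R = d/2`. The default profile `p` is exponential with decay length
#' `decay_length` (adaptive quadrature, relative tolerance 1e-8). A step
#' profile of width `boundary_width` reproduces the two-population model
#' with `f = unperturbed_fraction(d, boundary_width)`; an arbitrary
#' profile can be supplied as a function of the distance from the rim
#' returning values in \[0, 1\].
#'
#' @param d disc diameter (nm), > 0.
#' @param decay_length exponential decay length (nm), > 0 (used by the
#'   exponential profile).
#' @param gp_bulk,gp_rim GP of fully unperturbed and rim lipids.
#' @param profile `"exponential"` (default), `"step"`, or a function
#'   `p(distance_from_rim)`.
#' @param boundary_width step-profile width (nm); required when
#'   `profile = "step"`.
#' @return Disc-averaged GP (scalar).
#' @export
continuum_gp <- function(d, decay_length, gp_bulk, gp_rim,
                         profile = c("exponential", "step"),
                         boundary_width = NULL) {
  if (!is.finite(d) || d <= 0)
    ld_stop("diameter must be positive", "laurdan_validation_error")
  R <- d / 2
  if (is.function(profile)) {
    p <- profile
  } else {
    profile <- match.arg(profile)
    if (profile == "exponential") {
      if (!is.finite(decay_length) || decay_length <= 0)
        ld_stop("decay_length must be positive", "laurdan_validation_error")
      p <- function(dist) exp(-dist / decay_length)
    } else {
      if (is.null(boundary_width))
        ld_stop("step profile needs boundary_width", "laurdan_validation_error")
      # piecewise-constant profile: rim annulus of width w is fully
      # perturbed, interior fully bulk; the area integral is analytic
      f <- unperturbed_fraction(d, boundary_width)
      return(f * gp_bulk + (1 - f) * gp_rim)
    }
  }
  integrand <- function(r) r * (gp_bulk + (gp_rim - gp_bulk) * p(R - r))
  q <- stats::integrate(integrand, 0, R, rel.tol = 1e-8,
                        subdivisions = 500L)
  (2 / R^2) * q$value
}
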