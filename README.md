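# laurdan

Analysis of steady-state Laurdan fluorescence for lipid bilayer order, in
R. Written for membrane biophysicists who record Laurdan emission spectra
along a temperature ramp — in large unilamellar vesicles (LUVs) or in
nanodiscs of various scaffold sizes — and want melting parameters out the
other end, plus geometric models of how much of a nanodisc's bilayer the
scaffold rim perturbs.

## What it computes

Laurdan's emission peaks near 440 nm in an ordered (gel) bilayer and near
490 nm in a disordered (fluid) one. Each spectrum is condensed to the
generalized polarization

```
GP = (I440 − I490) / (I440 + I490),   GP ∈ [−1, 1],
```

higher GP meaning tighter lipid packing. From a GP-versus-temperature
curve, the package forms the negative central-finite-difference derivative
−dGP/dT and reports:

* **T_M** — the main transition temperature, the location of the
  derivative peak;
* **FWHM** — the peak's width at half maximum, a relative cooperativity
  measure (narrower = more cooperative);
* **AUC** — the area under the peak, an enthalpy proxy in GP units (equal,
  up to discretization, to the GP drop across the range);
* **ΔT_M** — the shift of T_M against a reference bilayer, typically an
  LUV of the same lipid.

Around this estimator sit a validated long-CSV spectra reader with scan
averaging and replicate aggregation, a two-state (van't Hoff) synthetic
spectra generator with presets for DMPC/DPPC/DSPC/POPC in LUVs and
11–50 nm nanodiscs, and annulus/continuum models of rim-perturbed boundary
lipids (`unperturbed_fraction()`, `calibrate_boundary_width()`,
`two_population_gp()`, `continuum_gp()`).

## Worked example

Simulate a triplicate temperature-ramp experiment (3 scans per
temperature, 2% detector noise) for DMPC in vesicles and in 11 nm discs,
then run the full pipeline with the LUV as reference:

```r
library(laurdan)

path <- tempfile(fileext = ".csv")
luv  <- simulate_experiment("DMPC", "LUV",      noise_sd_frac = 0.02, seed = 42)
disc <- simulate_experiment("DMPC", "spMSP1D1", t_min = 14, t_max = 44,
                            noise_sd_frac = 0.02, seed = 42)
write_spectra(c(luv, disc), path)

res <- run_pipeline(path, reference = "DMPC_LUV")
res$fits[["DMPC_spMSP1D1"]]
#> Melting analysis: DMPC_spMSP1D1 (DMPC, spMSP1D1)
#>   Tm = 29.00 degC, FWHM = 8.83 degC, AUC = 1.8963 GP units
#>   delta Tm vs DMPC_LUV = +5.00 degC
res$fits[["DMPC_LUV"]]
#> Melting analysis: DMPC_LUV (DMPC, LUV)
#>   Tm = 24.00 degC, FWHM = 2.37 degC, AUC = 1.9009 GP units
#>   delta Tm vs DMPC_LUV = +0.00 degC
```

The disc transition is right-shifted by 5 °C and almost four times broader
(less cooperative) than in vesicles, while the total GP drop (AUC) is
essentially unchanged — the lipids still melt, just less cooperatively.
`coef()`, `summary()`, `plot()` and `residuals()` methods are available on
the fits; note the broad disc transition is scanned over ±15 °C, since
transition detection needs the ramp to reach both plateaus (about 5× the
transition width beyond the midpoint; see the vignette).

Boundary-lipid geometry: what rim-layer width is consistent with reported
unperturbed-lipid percentages of 77/83/90/95% in 11/15/25/50 nm discs?

```r
round(calibrate_boundary_width(c(11, 15, 25, 50), c(0.77, 0.83, 0.90, 0.95)), 3)
#> [1] 0.674 0.667 0.641 0.633     # nm — mutually consistent, ~0.65 nm
unperturbed_fraction(11, 1.5)
#> [1] 0.5289256                   # a fixed 1.5 nm annulus would leave only 53%
```

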