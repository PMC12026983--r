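---
title: "Derivative-based melting analysis of Laurdan GP curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivative-based melting analysis of Laurdan GP curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laurdan)
```

## The measurement and the statistic

Laurdan is a solvatochromic membrane dye whose emission red-shifts as water
penetrates the bilayer: in a tightly packed (gel, ordered) bilayer the
emission peaks near 440 nm, in a loosely packed (liquid-crystalline,
disordered) bilayer near 490 nm. The generalized polarization

$$\mathrm{GP} = \frac{I_{440} - I_{490}}{I_{440} + I_{490}}$$

condenses each emission spectrum into a single packing statistic bounded in
$[-1, 1]$; higher GP means tighter packing. Recording spectra along a
temperature ramp and plotting GP against temperature produces a sigmoidal
melting curve whose descent marks the gel-to-fluid main phase transition.

The package implements the full chain from raw spectra to melting
parameters:

1. **Scan averaging** (`average_scans()`): repeated instrument scans at one
   temperature are averaged pointwise *on the spectra*, before any GP is
   computed. Averaging GP values instead would not commute with the
   ratiometric definition.
2. **GP computation** (`compute_gp()`): intensities are read at the exact
   grid wavelengths 440 and 490 nm. No bandwidth integration and no
   interpolation is performed — an absent channel wavelength is an error.
   Integration windows are an instrument-specific choice we deliberately do
   not guess at; the single-wavelength read is the plain reading of the GP
   definition. Background/blank subtraction is likewise not applied: GP is
   a ratio, and any additive background correction would have to come from
   a measured blank that the input format does not carry.
3. **Replicate aggregation** (`aggregate_replicates()`): mean and sample
   standard deviation (n−1 denominator) across independent replicates on a
   shared temperature grid.
4. **Melting analysis** (`fit_melting()`): described next.

## The estimator

`fit_melting()` forms the negative derivative of GP with respect to
temperature by the **central finite difference**,

$$-\left.\frac{dGP}{dT}\right|_{T_i} =
  -\frac{GP_{i+1} - GP_{i-1}}{T_{i+1} - T_{i-1}},$$

so the transition appears as a positive peak, and reports:

* **Transition temperature `tm_C`** — the temperature of the derivative
  maximum. Ties break toward the lowest temperature, and by default the
  raw grid temperature is reported (no sub-grid interpolation), so results
  on a 1 °C ramp are reproducible integers. `refine = TRUE` optionally
  returns the vertex of a parabola through the peak and its neighbors,
  clamped to the neighbor interval.
* **Cooperativity `fwhm_C`** — the full width at half maximum of the peak,
  with each half-maximum crossing located by linear interpolation between
  the bracketing grid points, using the crossings *nearest* the peak so
  secondary bumps are ignored. A sharper (narrower) peak means a more
  cooperative transition. If the derivative never falls below half maximum
  on one side the peak is truncated by the scan range and the width is
  recorded as `NA` rather than extrapolated.
* **Enthalpy proxy `auc_gp`** — the trapezoidal area under the derivative
  curve. By the fundamental theorem of calculus this equals (up to
  discretization) the total GP drop across the measured range. It is a
  proxy in GP units, not a calorimetric enthalpy.
* **Shift `delta_tm_C`** — `tm_C` minus the `tm_C` of a reference fit
  (conventionally an LUV of the same lipid); positive means right-shifted.

Endpoints of the GP curve are dropped, not estimated with one-sided
stencils: real transition peaks are interior, and one-sided differences
would bias the edges where detection decisions are made. On non-uniform
ramps (coarser steps outside the transition are common) the same two-point
centered stencil over the flanking neighbors is used; it degrades
gracefully to first-order accuracy there and is exact for locally affine
curves everywhere.

### Transition detection

Not every curve has an assayable transition — a lipid melting below the
instrument's range, or a broad multi-component mixture, yields a featureless
derivative. `detect_transition()` accepts a transition when the derivative
maximum (i) is strictly positive, (ii) sits at an interior point of the
derivative grid, and (iii) is at least `prominence_factor` (default 3)
times the median absolute derivative. The threshold is a package invention,
deliberately exposed as a parameter.

A practical consequence worth stating: the median-based baseline needs the
scan range to reach the transition's plateaus. For a logistic transition of
width parameter `k` the default threshold fires reliably once the ramp
extends roughly **5·k beyond the midpoint on each side**. LUV transitions
(`k ≈ 0.4 °C`) detect comfortably on a ±10 °C window; broad nanodisc
transitions (`k ≈ 2.5 °C`) need ±12 °C or more, which is also what an
experimentalist would scan to see both plateaus of a broad transition. The
examples and tests therefore simulate disc samples over ±15 °C.

## The synthetic generator

Because real melting experiments are instrument-bound, the package ships a
generator producing datasets with exactly the statistical structure the
analysis assumes, so every stage can be validated end to end.

**Two-state model** (`two_state_model()`): the ordered fraction follows a
van't Hoff-style logistic, $f(T) = 1/(1 + e^{(T - T_m)/k})$, and the true
GP interpolates between a gel plateau (default 0.55) and a fluid plateau
(default −0.15). The derivative of this sigmoid peaks exactly at $T_m$ and
has FWHM $= 2k\ln(3 + 2\sqrt{2}) \approx 3.53\,k$ — the closed form the
test suite checks convergence against.

**Band model** (`band_model()`): spectra are mixtures of two
peak-normalized Gaussian emission bands at 440 and 490 nm weighted by
$f(T)$, with common width σ = 18 nm and additive Gaussian detector noise
(a stated fraction of the band amplitude), clipped at zero. σ = 18 nm
keeps the cross-talk between the two GP channels at
$e^{-(50/18)^2/2} \approx 2\%$. With this symmetric band pair the GP of a
noise-free rendered spectrum is *exactly linear* in $f$:
$\mathrm{GP} = \frac{1-b}{1+b}(2f-1)$ with $b$ the cross-talk term. The
rendered GP therefore inherits the monotonicity of $f$ and its derivative
peaks exactly at the preset midpoint, which is what makes grid-exact
recovery a fair acceptance check. Note the rendered plateaus (±0.958) are
*not* forced to match the two-state model's GP plateaus; the band mixture
and `gp_truth()` are two views of the same ordered fraction, not the same
curve.

**Acquisition structure** (`simulate_experiment()`): 3 scans × 3
replicates per temperature by default, each (replicate, scan, temperature)
spectrum drawn with a distinct sub-seed derived deterministically from the
master seed — identical calls give byte-identical files.

**Presets** (`list_presets()`): midpoints encode the literature transition
temperatures of the pure lipids in vesicles (DMPC 24, DPPC 41, DSPC 54,
POPC −2 °C) and the observed disc shifts at 11 nm (+5 DMPC, +2 DPPC, 0
DSPC). Midpoints for the intermediate disc sizes, the width parameters
(0.4 °C LUV, 2.5 °C for 11/15 nm discs, 1.5 °C at 25 nm, 0.8 °C at 50 nm)
and the GP plateaus are package choices that encode only the qualitative
orderings reported for such systems — transitions broaden and right-shift
in small discs, and converge to vesicle behavior as disc diameter grows.
They are calibration anchors for the pipeline, not reproductions of any
measured curve.

What the generator does **not** emulate: photobleaching, temperature
drift of quantum yield, Poisson (shot) noise, scatter or inner-filter
effects, excitation-generalized-polarization spectra, and multi-component
lipid mixtures. Passing tests therefore demonstrate the correctness of the
analysis chain under the stated noise model, not robustness to every
instrument artifact.

## Boundary-lipid geometry

Lipids at a nanodisc rim are perturbed by the scaffold. The package models
the disc as a circle of diameter $d$ with a perturbed annulus of width
$w$:

$$f_{\text{unperturbed}} = \left(\frac{d/2 - w}{d/2}\right)^2,$$

clamped to 0 when $w \ge d/2$ (`unperturbed_fraction()`), with the
closed-form inverse $w = (d/2)(1 - \sqrt{f})$
(`calibrate_boundary_width()`). The diameter is the nominal scaffold
diameter (11/15/25/50 nm); no belt-thickness correction is applied because
no lipid-area diameters are available to support one.

A classical fixed boundary width of ~1.5 nm does **not** reproduce the
commonly quoted unperturbed percentages of 77/83/90/95% for 11/15/25/50 nm
discs under this annulus-area reading (it gives ≈53/62/77/88%). Those
percentages are instead mutually consistent with $w \approx
0.63\text{–}0.67$ nm (spread < 10% of the mean) — the test suite asserts
exactly this consistency. The package therefore does not hard-code a
boundary width; it exposes the calibration.

Two mixture predictions are provided: `two_population_gp()` (lipids are
either perturbed or unperturbed) and `continuum_gp()`, which averages
$GP(r) = GP_{\text{bulk}} + (GP_{\text{rim}} - GP_{\text{bulk}})\,
p(R - r)$ over the disc area by adaptive quadrature (relative tolerance
1e-8). The default perturbation profile is exponential in distance from
the rim — the simplest one-parameter monotone choice consistent with the
simulation literature — and is pluggable: a step profile of width $w$
recovers the two-population model exactly, and any user function of
distance from the rim is accepted.

## Numerical choices and degenerate inputs

* Temperatures are grouped at 0.01 °C resolution (Peltier precision);
  duplicate temperatures within one replicate after scan averaging are an
  error, as are duplicate (group, wavelength) rows in input files.
* Wavelength grids are never interpolated; any grid mismatch between scans
  or channels is an error.
* A GP denominator of zero (both channels dark) is a degenerate-spectrum
  error, not a silent `NaN`.
* Derivative curves need ≥3 GP points; flat derivative curves (≥3 equal
  values) raise a no-transition error, while a two-point tie resolves to
  the lower temperature under the tie rule.
* The optional moving-average smoother (odd window) shrinks its window
  symmetrically at the curve ends rather than padding or extrapolating; it
  is off by default because the analysis is designed for raw GP curves.

## Problem sizes

The validation suite runs entirely on synthetic data at the scale of the
real acquisition protocol: 141-point spectra (400–540 nm, 1 nm), 21–31
point temperature ramps at 1 °C, 3 scans × 3 replicates; property checks
use up to 1000 random spectra, 0.01 °C grids for convergence checks, and a
10^6-point Riemann oracle for the continuum quadrature. A full run takes
well under a minute on one core.

## Limitations

* The enthalpy proxy is in GP units; converting to kJ/mol requires
  calorimetry.
* Single-peak analysis only: pretransitions and multi-peak profiles are
  outside scope, and the FWHM deliberately ignores secondary bumps.
* The detection threshold is heuristic; for marginal data inspect the
  derivative curve (`plot()` on the fit) rather than trusting the boolean.
* Grid-resolution `tm_C` is only as fine as the ramp step unless
  `refine = TRUE` is requested.
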