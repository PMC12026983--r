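Package: laurdan
Title: Laurdan Generalized Polarization and Lipid Melting-Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of steady-state Laurdan fluorescence emission spectra
    from lipid vesicles and nanodiscs. Computes generalized polarization (GP)
    from the 440 nm and 490 nm emission channels, averages instrument scans
    and aggregates replicates, and extracts melting parameters from GP
    versus temperature curves by central finite differences: the main
    transition temperature (derivative peak), relative cooperativity (width
    at half maximum) and an enthalpy proxy (area under the derivative peak),
    plus transition-temperature shifts against a reference bilayer.
    Includes geometric models of rim-perturbed boundary lipids in nanodiscs
    (annulus fraction, boundary-width calibration, two-population and
    continuum GP mixtures) and a synthetic two-state spectra generator with
    presets for common phosphatidylcholines, so the whole pipeline can be
    exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
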