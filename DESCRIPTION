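Package: rqbeam
Title: Establishment of IEC 61267 Radiation Qualities and Robustness of
    the Squared Signal-to-Noise Ratio per Air Kerma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational establishment of the IEC 61267 RQR and RQA
    standard radiation qualities from X-ray tube fluence spectra, and
    quantification of the robustness of the squared signal-to-noise ratio
    per air kerma (SNR2_in) under the tolerances the standard permits for
    anode angle, practical peak voltage and half-value layer.  Provides
    spectral air-kerma integration against packaged mass energy-transfer
    coefficients, Beer-Lambert attenuation in aluminium, half-value-layer
    inversion by bracketed root finding, solution of the additional
    filtration that realises a reference half-value layer, IEC validation
    checks (K/K0 band, homogeneity coefficient), corner scans over the
    tolerance box, and GUM Supplement 2 Monte Carlo propagation yielding
    standard uncertainties and probabilistically symmetric coverage
    intervals.  A deterministic synthetic bremsstrahlung generator makes
    the whole pipeline usable offline; an adapter to an external
    tungsten-anode spectrum model is provided for absolute work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
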