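Package: adcdar
Title: Drug-to-Antibody Ratio Determination for Antibody-Drug Conjugates
Version: 0.1.0
Authors@R: person("Maintainer", "adcdar", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for determining the drug-to-antibody ratio (DAR) of
    lysine-linked antibody-drug conjugates from two orthogonal measurements:
    two-wavelength UV spectroscopy and intact-mass (linear-mode MALDI-TOF)
    spectrometry. Includes Beer-Lambert standard-curve fitting of molar
    extinction coefficients, a mass-spectral processing pipeline (baseline
    subtraction, Savitzky-Golay smoothing, envelope centroiding), an
    in-silico tryptic digest with conjugation-blocked lysines, a registry of
    maytansinoid (DM1) linker chemistry, and synthetic-data generators that
    emulate the wet-lab inputs for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
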