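Package: speccult
Title: Cell Concentration Determination from White-Light Absorption Spectral Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring suspension cell cultures by white-light
    absorption spectroscopy. Species absorption spectra (in percent absorption,
    330-860 nm) are described by sums of Gaussian components whose amplitude,
    center and width are parametric functions of cell concentration
    (Beer-Lambert exponential, power or log-linear sub-functions). The package
    calibrates such spectral-shape models from dilution-series spectra
    (iterated constant-fixing of Gaussian coefficients, sub-function family
    selection, global simplex minimization), inverts measured spectra for one
    or several species concentrations via least-squares shape matching using
    the absorbance-additivity mixture law, and evaluates accuracy with
    bias/dispersion descriptors, leave-sets-out cross-validation, exponential
    growth-curve fitting and crosstalk mean-plane analysis. A synthetic-spectra
    generator with cuvette, detector and counter noise models supports
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
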