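Package: lipospec
Title: Lipid Quantification from 1D 1H NMR and In Vivo MRS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and quantification of one-dimensional proton spectra for
    tissue lipid profiling. Implements window integration of high-resolution NMR
    spectra of tissue extracts with absolute quantification of lipid classes
    against external standards (receiver-gain and scan-number corrected), in vivo
    liver MRS measurands (intrahepatic lipid content from the methylene/water
    ratio, a triglyceride glycerol index, fatty-acid composition indices, and a
    water-linewidth iron proxy), a Lorentzian spectrum simulator with analytic
    proton-stoichiometry oracles and two-genotype cohort generation, and the
    accompanying statistical layer (normality-gated two-group tests, fold
    changes, gated correlations, and Pareto-scaled principal component analysis
    of lipid profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
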