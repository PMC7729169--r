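Package: nutrifuzz
Title: Neurofuzzy Modeling of Mineral Nutrition in Plant Tissue Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing mineral-nutrition factorial experiments in
    plant tissue culture. Converts salt-based culture-medium formulations
    (Murashige & Skoog dilution series) into ion molar concentrations to
    avoid ion confounding, runs classical factorial ANOVA with Tukey HSD
    letters and distributional checks, fits additive tensor-product B-spline
    neurofuzzy models with an adaptive-spline-modeling-of-data (ASMOD)
    structure search under structural risk minimization, extracts linguistic
    IF-THEN rules with membership degrees, and ships a synthetic-data
    generator that emulates a 3 genotype x 9 medium x 4 subculture design
    with planted genotype-dependent ion interactions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
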