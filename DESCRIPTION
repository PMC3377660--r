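Package: isobudget
Title: Carbon-13 Pulse-Chase Carbon Budgets for Sediment Core Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing carbon-13 pulse-chase experiments on
    sediment core incubations: conversions between delta-13C, isotope
    ratios and atom fractions; benthic solute flux estimation from
    overlying-water time series; tracer budgets for diatom-derived carbon
    mineralization and PLFA-based bacterial carbon uptake, including
    bacterial growth efficiency; random-intercept linear mixed models with
    exponential variance functions fitted by maximum likelihood or REML,
    with likelihood-ratio backward selection and intraclass correlations;
    Box-Cox/ANOVA/Tukey group comparisons; correlation-based principal
    component fingerprints of proportional tracer uptake into individual
    phospholipid fatty acids; and a synthetic-experiment generator with
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
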