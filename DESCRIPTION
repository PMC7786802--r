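Package: trialgap
Title: Disease Burden and the Global Distribution of Randomised Trial Evidence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how published randomised controlled trial (RCT)
    evidence is distributed across disease areas relative to the global burden of
    disease. Provides a synthetic corpus generator with fully known ground truth
    (article records, validation samples, Global Burden of Disease (GBD) burden
    tables, term-to-category mappings and country tables); term-to-GBD-category
    relevance assignment separating treatment from prevention trials;
    misclassification-adjusted publication counts with bootstrap 95 percent
    prediction intervals and an absolute-error simulation for extracted sample
    sizes; descriptive summaries (category-year counts, participant quantiles,
    sociodemographic-index shares); and a panel regression suite relating log RCT
    counts to log disability-adjusted life years (DALYs), including distributed-lag
    and burden-location models, Hausman fixed-versus-random effects comparison,
    elasticity conversions, expected-versus-observed tables and a
    duplicate-publication sensitivity reanalysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
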