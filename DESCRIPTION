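Package: mutgrowth
Title: Mutation-Growth Rate Trade-Off Analysis for Bacterial Strain Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative linkage of bacterial mutation and growth rates across
    genotypes (genome-reduced, mismatch-repair-deficient mutator, wild type)
    and growth media. Provides fluctuation-test mutation-rate inference via
    the Ma-Sandri-Sarkar maximum-likelihood and P0 estimators, CFU-based
    population sizing, windowed log-linear growth-rate estimation from
    plate-reader optical-density time series, per-medium log-linear
    trade-off model fitting (maximal mutation rate and slope), multiple
    linear regression with interactive or additive genotype coding, and
    medium/genotype classification with linear and radial-basis-function
    support vector machines. A seeded synthetic-data generator emulates
    strain panels, raw fluctuation assays, CFU plates, and growth curves so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
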