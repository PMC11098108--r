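Package: bactaging
Title: Replicative Aging Analysis for Bacterial Single-Cell and Population Growth Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying replicative aging in bacteria from
    mother-machine single-cell lineage traces and plate-reader population
    growth curves. Extracts cell cycles (birth length, exponential elongation
    rate, doubling rate) from length time series, decomposes single-cell
    lifespans into an apparent replicative phase and a post-replicative phase
    using a viability dye, classifies death phenotypes (chromosome loss,
    chromosome retention, filamentation), estimates survival curves by the
    Kaplan-Meier product-limit method, fits the Gompertz mortality law to
    obtain aging rates with bootstrap confidence bounds, extracts growth-curve
    parameters (maximum growth rate, saturation point, area under the
    log-growth curve, exponential-phase duration) with principal-component and
    hierarchical-clustering strain panels, and simulates an age-structured
    population model linking division, replicative arrest and lysis. Includes
    a synthetic-data generator with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    jsonlite
Config/testthat/edition: 3
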