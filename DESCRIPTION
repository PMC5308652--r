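Package: apoptopredict
Title: Predicting Apoptosis-Inducing Treatment Responsiveness from
    Quantitative Protein Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway-informed prediction of glioma cell-line responsiveness
    to temozolomide (TMZ), TRAIL and their combination from quantitative
    apoptosis-protein profiles. Nineteen core apoptosis regulators are
    encoded into eleven functional groups by simple arithmetic rules (sums,
    products, ratios), embedded in a principal-component space with
    Kaiser-criterion retention, and segmented into ordinal response regions
    by linear discriminant analysis. The package provides leave-one-out
    response prediction, a treatment-recommendation tool, Webb
    fractional-product combination-index synergy scoring, in-silico
    Bcl-2/Bcl-xL depletion to predict ABT-737 sensitization, and a
    synthetic-data generator with known ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
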