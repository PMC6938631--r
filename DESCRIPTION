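Package: funcevkit
Title: Calibration and Application of Functional Assay Evidence (PS3/BS3) in
    Clinical Variant Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the ClinGen Sequence Variant Interpretation (SVI)
    recommendations for applying the ACMG/AMP functional-evidence codes PS3 and
    BS3. Provides odds-of-pathogenicity (OddsPath) estimation from classified
    variant controls with the one-added-misclassified-variant adjustment,
    mapping of OddsPath to Bayesian evidence-strength tiers, readout-threshold
    calibration from pooled control readouts, assignment of validation tiers to
    specific assay instances, variant-level evidence application with stacking
    rules, recommendation-driven context warnings (including the 50-nucleotide
    nonsense-mediated-decay boundary rule), seeded fixture generators, and
    readers/writers for controls, assay-instance and evidence-report files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'oddspath.R'
    'calibration.R'
    'policy.R'
    'framework.R'
    'evidence.R'
    'fixtures.R'
    'io.R'
    'report.R'
    'funcevkit-package.R'
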