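Package: gmflow
Title: Gene-Flow Modelling and Simplified Sampling for Adventitious GM
    Content in Maize Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form model of adventitious cross-pollination
    distribution inside conventional maize fields, built on a 1/(d+1)
    border-distance decay kernel applied on the equivalent square of a
    field.  Provides the Self-Protection Index (area/perimeter ratio),
    whole-field GM-content estimators from one to nine pooled samples,
    labeling-threshold calculators (critical index, periphery stripping),
    standard (28-sample) and simplified (9-sample) survey designs with
    their aggregation rules, a stochastic field simulator with cob-level
    dispersion and qPCR measurement error (LOD/LOQ censoring), and a
    decision-support workflow that flags fields against a labeling
    threshold and attributes GM presence to external pollen flow or
    internal origin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
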