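Package: resistdyn
Title: Evolutionary Dynamics of Drug Resistance Under Targeted Combination
    Cancer Therapy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multitype branching-process model of solid-tumor response to
    targeted therapy with one or more drugs. Provides closed-form
    probabilities of pre-existing and acquired resistance and of lesion
    eradication under mono, dual and k-drug regimens (including
    cross-resistance mutations and multi-lesion patients), a hybrid
    exact/deterministic stochastic simulator of pretreatment growth and
    simultaneous or sequential treatment courses with costly resistance and
    failure-cause classification, estimation of net growth and decline rates
    from longitudinal lesion measurements, and synthetic cohort generators
    for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
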