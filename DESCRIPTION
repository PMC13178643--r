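Package: stimdyn
Title: Sex- and Hormone-Dependent Stimulant Pharmacodynamics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three linked analyses of psychostimulant action on the
    dopamine system: kinetic modelling of fast-scan cyclic voltammetry (FSCV)
    dopamine transients with Michaelis-Menten release/uptake fitting, apparent-Km
    concentration series and competitive-inhibition Ki potency estimation;
    balanced-bootstrap differential-expression counting for projection-classified
    (core vs shell) dopamine neurons from single-nucleus count matrices; and
    signal-detection (d-prime) scoring of psychomotor vigilance sessions with
    percent-change-from-baseline dose-response assembly. A synthetic-data module
    generates FSCV traces, negative-binomial count matrices with planted marker
    and sex-effect structure, and trial-by-trial vigilance event logs so that
    every stage of the pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
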