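Package: magnetocapture
Title: Magnetophoretic Capture of SPIO-Labeled Cells from Tube Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic magnetostatics of an axially magnetized cylindrical
    NdFeB permanent magnet (surface-charge model evaluated with Bulirsch
    generalized complete elliptic integrals), the magnetic moment and
    attraction force on superparamagnetic iron oxide (SPIO) labeled
    mesenchymal stem cells, and a Monte-Carlo magnetophoresis simulator of
    cell capture from laminar tube flow with its capture-efficiency (CE)
    statistic. Includes a summary-statistics toolkit (pooled t, one-way
    ANOVA with Fisher LSD post hoc, Pearson correlation) that operates on
    printed mean/SD/n tables or raw replicates, synthetic-data generators
    for labeled-cell populations and group-replicate experiments, and
    packaged fixtures of the in-study summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
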