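Package: pvkit
Title: Pharmacovigilance Signal Detection and Risk Modelling for Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("pvkit", "maintainers", email = "pvkit@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for disproportionality analysis of spontaneous
    adverse-event reports in the FAERS quarterly ASCII dialect: a synthetic
    report generator with planted ground truth, deduplicating ingest with
    SMQ-based case finding, four signal-detection algorithms (ROR, PRR with
    chi-square, BCPNN information component, EBGM relative reporting ratio)
    with joint signal criteria and multiplicity adjustment, demographic
    stratification, Weibull time-to-onset hazard classification, logistic
    risk modelling with nomogram point scaling and ROC evaluation, and
    gene-set intersection with degree-centrality hub ranking on protein
    interaction edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
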