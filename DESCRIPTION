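Package: ddiscreen
Title: Drug-Drug Interaction Signal Screening from Spontaneous Reporting Data
Version: 0.1.0
Authors@R: person("ddiscreen", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Disproportionality screening of drug-drug interaction (DDI)
    signals in spontaneous-reporting-system data such as JADER. Builds 4x2
    contingency tables for (drug, drug, event) triples from report-level
    csv tables, computes the subset reporting odds ratio under the
    either-subset and the stricter both-subsets detection criteria, the
    Omega shrinkage measure, and additive, multiplicative and chi-square
    interaction models; scores signal sets against a surrogate gold
    standard with the usual classification metrics and Cohen's kappa; and
    ships a report-level synthetic-data generator plus a command-line
    front end so the whole pipeline is testable without a database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
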