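Package: ecea
Title: Extended Cost-Effectiveness Analysis for Health Policy Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extended cost-effectiveness analysis (ECEA) of health
    policies. Given a stratified population (for example income quintiles), a
    static disease and cost model, and a policy instrument such as universal
    public finance of a treatment, the package computes per-stratum health
    gains, private out-of-pocket expenditures averted, financial risk
    protection (catastrophic health-cost cases averted, poverty cases averted,
    or a money-metric insurance value based on constant relative risk aversion
    utility), and net implementer costs, together with incremental
    cost-effectiveness ratios and per-budget scalings. Includes a Gamma income
    model calibrated from mean income and the Gini coefficient, a scenario file
    format (YAML/JSON), a synthetic-scenario generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
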