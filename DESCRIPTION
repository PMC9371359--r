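Package: exeCEA
Title: Cost-Effectiveness of Add-On Exenatide in Parkinson's Disease with
    Coexisting Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model for the cost-effectiveness of
    add-on exenatide versus conventional pharmacotherapy in a community cohort
    at risk of Parkinson's disease (PD) and type 2 diabetes mellitus (DM). The
    model propagates a cohort through thirteen health states (normal, DM, four
    Hoehn-Yahr stages of PD with and without DM, and three cause-specific death
    states) over annual cycles, attaches societal-perspective costs and
    utilities, and reports discounted life years, quality-adjusted life years,
    costs, and incremental cost-effectiveness ratios. Includes one-way (tornado)
    sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves and ICER planes, scenario analyses,
    YAML/JSON parameter configs, and an individual-level microsimulation oracle
    for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
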