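Package: cpbsim
Title: Monte Carlo Estimation of Clinically Preventable Burden and Clinic Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Propagates parameter uncertainty through clinically preventable
    burden (CPB) calculations of quality-adjusted life-years (QALYs) saved per
    thousand preventive-health interventions, using Monte Carlo simulation over
    uniform (or variance-matched normal) parameter ranges. A clinic-impact layer
    converts per-intervention QALY rates and annual service volumes into annual
    health (QALYs/year) and economic (dollars/year) impact with analytic
    variance propagation for products of independent variables, including
    totals, return on investment, and prospective service scenarios. Ships a
    birth-cohort influenza-vaccination model, literature QALY-rate tables with
    a fixed coefficient-of-variation fallback, synthetic fixture generators
    with closed-form oracles, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
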