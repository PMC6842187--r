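Package: evtdes
Title: Discrete Event Simulation of Endovascular Thrombectomy Service
    Reconfiguration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level discrete event simulation estimating the clinical
    effectiveness and lifetime cost-effectiveness of reconfiguring English
    endovascular thrombectomy (EVT) provision from 24 to 30 comprehensive
    stroke centres. Includes a synthetic geography and cohort generator
    (quantile-matched onset-to-door sampling, secondary-transfer classes),
    a treatment pathway model, time-dependent 90-day modified Rankin Scale
    outcomes with a linearly declining treatment effect, long-term
    competing-risk deterioration and survival with parametric extrapolation,
    probabilistic sensitivity analysis with copula-correlated cost and
    utility parameters, and reporting of QALYs, costs, net monetary benefit,
    cost-effectiveness acceptability curves and budget impact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
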