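Package: gccea
Title: Cost-Effectiveness Modelling of Endoscopic Gastric Cancer Surveillance
Version: 0.1.0
Authors@R:
    person("GCCEA", "Developers", email = "gccea@example.org", role = c("aut", "cre"))
Description: Markov cohort models for evaluating oesophagogastroduodenoscopy
    (OGD) based gastric cancer prevention strategies in populations with low to
    intermediate risk. Implements five strategies (no intervention, 2-yearly and
    annual surveillance of subjects with precancerous lesions, 2-yearly mass
    screening, and 2-yearly screening combined with annual surveillance),
    computes discounted lifetime costs and quality-adjusted life years, builds
    the incremental cost-effectiveness frontier with extended dominance,
    performs one-way deterministic sensitivity analysis with net-health-benefit
    threshold finding, probabilistic sensitivity analysis with
    method-of-moments distributions and a cost-effectiveness acceptability
    frontier, and validates engine projections against the input
    epidemiological tables with the Mantel-Cox log-rank test. A synthetic
    epidemiology module generates Gompertz-Makeham life tables and exponential
    age-incidence curves so the model runs without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
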