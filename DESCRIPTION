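Package: t2dtr
Title: Reinforcement-Learning Treatment Recommendation for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds visit-level treatment-decision trajectories from
    registry-style electronic medical records of patients with type 2
    diabetes, trains an offline dueling double deep Q-network with
    prioritized experience replay to rank antiglycemic, antihypertensive
    and lipid-lowering treatment actions, gates the ranking through a
    knowledge-driven contraindication filter, and evaluates the resulting
    recommendations retrospectively: short-term goal-attainment comparisons
    between model-concordant and model-nonconcordant visits with propensity
    score inverse-probability weighting, and long-term complication
    analyses of per-patient concordance rates. A synthetic electronic
    health record simulator with treatment-responsive biomarker dynamics,
    confounding by indication and outcome hazards supports end-to-end
    testing, together with a dynamic-programming oracle policy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
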