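# t2dtr — reinforcement-learning treatment recommendation for type 2 diabetes

`t2dtr` learns visit-by-visit treatment policies for type 2 diabetes from
retrospective, registry-style electronic medical records and evaluates
them the way an observational study would. It is aimed at biostatisticians
and clinical-ML researchers who want a complete, testable implementation
of the "knowledge + data" recommendation design: a knowledge-driven
contraindication filter selects the candidate medications, and a
data-driven model ranks them by expected clinical outcome.

The data-driven core is an offline **dueling double deep Q-network** with
prioritized experience replay, written in base R matrix code (forward,
backward, Adam). For a visit state *s* (a 49-dimensional encoding of
demographics, history, disease risks, current drugs, labs) and a
treatment action *a* (one of 13 antiglycemic prescription changes, or one
of the 16/8 antihypertensive/lipid-lowering drug-class subsets), the
network estimates the action value

> Q(s, a) = V(s) + A(s, a) − mean_a′ A(s, a′),

trained on targets r + γ·Q_target(s′, argmax_a Q_eval(s′, a)) with
γ = 0.9, soft target updates (τ = 0.01), and a regularized loss
mean w·[(Q′ − Q)² + λ·max(|Q| − r_reg, 0)] with λ = 0.5, r_reg = 4.
Rewards score the next visit: a·sgn(7 − HbA1c′) − b·Hypo − c·Final·CX
for glycemic control (a = 1, b = 2, c = 4), with analogous forms for
blood pressure (140/90 mmHg) and LDL-c (2.6 mmol/L).

Evaluation is retrospective: visits are split into model-concordant and
model-nonconcordant groups (concordance judged at drug-class level
against the top-ranked recommendation), compared by chi-squared tests and
odds ratios, adjusted by propensity-score inverse-probability weighting
and weighted logistic regression with sandwich standard errors, and
analyzed at the patient level through concordance-rate occurrence curves
and multivariate regression with a gradient-boosted baseline risk score.

Because real diabetes registries cannot be redistributed, the package
bundles a synthetic EHR simulator (registry schema, AR(1)
treatment-responsive biomarkers, confounding by indication, outcome
hazards tied to biomarker control) together with a value-iteration oracle
policy on the simulator's own kernel, so the entire pipeline is testable
end to end against a known optimum.

## Worked example

```r
library(t2dtr)

cfg    <- sim_config(n_patients = 2000)        # synthetic registry
cohort <- simulate_cohort(cfg, seed = 1)
splits <- split_patients(cohort, ratio = 0.8, seed = 1)
train  <- impute_missing(splits$train)
valid  <- impute_missing(splits$validation)

scheme <- fit_scheme(train)                    # 49-dim state encoding
trans  <- build_trajectories(train, "antiglycemic", scheme)
fit    <- train_dqn_ensemble(trans, dqn_config(max_iter = 6000, lr = 3e-4,
                                               patience = 12, seed = 1))

recs    <- recommend_visits(valid$visits, fit$models, scheme, "antiglycemic")
samples <- build_outcome_cohort(valid, recs, outcome_spec("hba1c_control"))
short_term_compare(samples)
```

```
concordant         143 events       60 (41.96%)
nonconcordant     1892 events      185 (9.78%)
unadjusted OR 6.670, chi-squared p 4.08e-30
```

Model-concordant visits reached the HbA1c < 7 % goal far more often than
nonconcordant ones (the simulator plants exactly this structure: the
recommended actions drive HbA1c down, and hazards follow HbA1c). On the
simulator the trained greedy policy can also be scored directly against
the dynamic-programming optimum:

```r
oracle <- oracle_policy(cfg)
evaluate_policy(sim_config(n_patients = 250),
                dqn_gly_policy(fit$models, scheme, valid$visits[1, ]),
                seed = 2)$mean_reward   #  0.783
evaluate_policy(sim_config(n_patients = 250),
                oracle_gly_policy(oracle), seed = 2)$mean_reward  #  0.835
evaluate_policy(sim_config(n_patients = 250), NULL, seed = 2)$mean_reward
                                        # -0.294  (physician behavior policy)
```

The learned policy recovers most of the gap between the confounded
behavior policy and the oracle. A thin command-line wrapper over these
functions is shipped in `inst/cli/t2dtr.R`
(`simulate` / `train` / `recommend` / `evaluate-short` / `evaluate-long` /
`pipeline`).

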