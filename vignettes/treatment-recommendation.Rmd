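---
title: "Offline reinforcement learning for type 2 diabetes treatment recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offline reinforcement learning for type 2 diabetes treatment recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Type 2 diabetes is managed through sequences of outpatient prescriptions —
antiglycemic, antihypertensive and lipid-lowering — adjusted every few
months as the patient's biomarkers (HbA1c, blood pressure, LDL-c) evolve.
Choosing each adjustment to optimize not just the next lab value but the
long-run risk of complications is a sequential decision problem. `t2dtr`
learns such treatment policies from retrospective visit-level electronic
medical records with an offline dueling double deep Q-network (DQN), gates
the learned ranking through a knowledge-driven contraindication filter, and
evaluates the resulting recommendations retrospectively through
concordance-based comparisons.

## Decision model

Each outpatient visit is a decision point. The *state* is a 49-dimensional
encoding of the visit: demographics (age, gender, ethnicity one-hot,
smoking), medical history flags, rule-derived disease risks (e.g.
eGFR < 60, prior severe hypoglycemia, macrovascular history), the drug
classes in use before the visit's prescription decision, and normalized
labs and physical measurements (HbA1c, SBP, DBP, LDL-c, TG, BMI, eGFR,
diabetes duration, number of oral agents). Continuous features are min-max
scaled to [0, 1] with bounds fitted at the 0.5th/99.5th percentiles of the
training data and clipped; the exact composition is fixed by
`fit_scheme()` so that train-time and recommendation-time encodings are
identical.

A deliberate subtlety: registry rows record the prescription *issued at*
the visit, i.e. the outcome of the decision being modelled. All state
encodings therefore lag the prescription columns by one visit within each
patient, so the "previous drugs" features describe the regimen in effect
*before* the decision. Without this shift, the state leaks the action and
every off-policy Q-value query at recommendation time is an
out-of-distribution (state, action) pair — in our experiments this leak
alone destabilized training.

The *action* is the prescription change. Antiglycemic treatment uses 13
change actions (no change; dose up/down of metformin, basal or premixed
insulin; adding one of seven oral-agent classes; switching to one of three
insulin regimens). Antihypertensive and lipid-lowering treatments use
regimen subsets: all 16 subsets of {ACEI/ARB, beta blocker, calcium channel
blocker, diuretic} and all 8 subsets of {statin, fibrate, ezetimibe}. When
a visit shows several simultaneous changes, a documented precedence decides
the single action label: insulin-regimen switch, then oral-agent addition
(lowest canonical index), then dose change (largest relative change), then
no change. Descriptions of this architecture sometimes quote a
14-dimensional output layer; the canonical action table enumerates 13
actions and no 14th is defined, so the network's output width is 13.

The *reward* scores the next visit. For antiglycemic treatment

r = a · sgn(7 − HbA1c′) − b · Hypo − c · Final · CX

with a = 1, b = 2, c = 4: +1 when the next HbA1c is strictly below 7 %
(−1 otherwise, with sgn(0) = −1 so the boundary counts as uncontrolled),
−2 when a severe hypoglycemia admission occurred before the next visit,
and on the patient's final visit −4·CX, where CX is +1 if any complication
or death occurred within the 6-year horizon and −1 otherwise. The
blood-pressure reward replaces the control term with a joint indicator
(SBP < 140 and DBP < 90) and has no hypoglycemia term; the lipid reward
uses LDL-c < 2.6 mmol/L. Rewards therefore range over [−7, +5]
(glycemic) and [−5, +5] (the other two).

## The Q-network and its training

The action-value function is a dueling network: input 49, two hidden
layers of 64 and 32 units with batch normalization and leaky-ReLU, then a
scalar state-value stream and a per-action advantage stream recombined as
Q(s,a) = V(s) + A(s,a) − mean(A). Training is fully offline: the replay
buffer is the fixed set of training transitions, and there is no
exploration. Each iteration samples a prioritized minibatch (priority
|TD error| + 1e-3, exponent α = 0.6, importance exponent β = 0.4), forms
double-DQN targets r + γ · Q_target(s′, argmax_a Q_eval(s′, a)) with
γ = 0.9 (terminal transitions use r alone), takes one Adam step
(learning rate 0.001, batch 256) on the weighted loss

mean(w · [(Q′ − Q)² + λ · max(|Q| − r_reg, 0)])

with λ = 0.5 and r_reg = 4 (the magnitude penalty discourages action
values beyond the largest attainable reward), refreshes the sampled
priorities, and soft-updates the target network with τ = 0.01. Batch
normalization uses minibatch statistics during optimization — including
the target-network passes, so prediction and target see the same
normalization — and frozen statistics at recommendation time; after
training, the inference statistics are recomputed exactly over the
training states rather than relying on the momentum average.

Offline Q-learning on a small fixed buffer can deteriorate after reaching
its optimum: bootstrapped targets amplify estimation noise on rarely
observed (state, action) pairs. Training therefore runs for a *maximum*
number of iterations with block-loss checkpointing: the parameters with
the lowest 500-iteration mean loss are retained, and training stops once
the block loss has not improved for a patience of 8 blocks. For small
cohorts we additionally found a deep ensemble valuable:
`train_dqn_ensemble()` trains several networks from independent
initializations and averages their Q-values at inference, which reduces
the ranking noise that a single offline fit exhibits between actions with
similar values. Gradient norms are clipped at 10 as a guard on the
divergence path.

## Knowledge filter and recommendation

Following the knowledge-plus-data design, a declarative rule engine first
restricts the action set at each visit; the Q-network then ranks the
admissible actions, ties broken toward the lower canonical index (the less
aggressive option). The shipped rules encode renal metformin safety: below
an eGFR of 45 the metformin dose is not increased and metformin is not
started; below 30 every metformin-retaining action is forbidden, leaving
the insulin-switch actions. The full guideline set is deliberately not
reconstructed; rules are data, and users add their own. If a rule
configuration forbids everything, the recommendation falls back to "no
change"/"no drugs" with a warning — conservative inaction is the safest
visible default, and the condition signals a misconfigured rule set.

A physician's prescription is *model-concordant* when the action inferred
from their consecutive prescriptions equals the model's top-ranked action,
judged at drug-class level (any brand name mapping to the same class is
equivalent).

## Retrospective evaluation

Short-term outcomes are visit-level goal attainments 3-6 months after the
decision (HbA1c < 7 %, SBP/DBP < 140/90, LDL-c < 2.6; strict
inequalities) or a severe hypoglycemia admission within 6 months. Visits
are partitioned into model-concordant and nonconcordant groups, compared
by chi-squared test and odds ratio, then adjusted: a main-effects logistic
propensity model yields inverse-probability weights (truncated at the
1st/99th percentiles), and a weighted logistic regression of the outcome
on exposure plus covariates gives the adjusted odds ratio with
heteroskedasticity-consistent (sandwich) standard errors — model-based
errors are invalid under weighting. Stratified analyses split by the
current HbA1c band: low < 7, medium 7-9 (9.0 inclusive), high > 9.

Long-term outcomes are patient-level complication/death occurrences over
up to 6 years. Each patient's concordance rate is the fraction of their
visits that were model-concordant. Patients are binned by rate (width
0.2); the occurrence per bin is fitted with an unweighted straight line
over the bin points. Bins holding fewer than 10 patients are excluded
from the fit: an occurrence estimated from a handful of patients would
otherwise dominate the unweighted least squares. A multivariate logistic
regression relates the outcome to the three per-treatment concordance
rates with a baseline risk score (out-of-fold gradient-boosting
probability, penalization-free logistic fallback) as the confounding
covariate; only patients with all three rates enter.

## The synthetic registry

The registry the method was designed for cannot be shared, so the package
bundles a simulator that emulates its schema and the statistical structure
the method assumes; its role is statistical, not clinical fidelity.
Patients accrue 4-8 visits 3-6 months apart. HbA1c follows an AR(1) pull
toward an untreated set-point of 9 % (rate 0.5 per interval, noise SD
0.35 %) plus an additive per-action effect — so the mean next-visit
difference between two action groups under a randomized policy equals the
configured effect difference exactly. Default effects range from 0 (no
change) through 0.7-1.3 (adding oral agents) to 1.2-1.7 (insulin
regimens); dose up/down move ±0.3-0.4. Severe hypoglycemia risk is
logistic in the action's insulin intensity and the achieved HbA1c below
6.5 %; complication and death hazards are logistic in HbA1c excess above
7 %, with an additional 6-year tail draw after the final visit. Blood
pressure and LDL-c follow analogous treat-to-target dynamics.

The physician behavior policy creates confounding by indication: action
weights scale as exp(0.5 · effect · (HbA1c − 7)) with a 6-fold inertia
weight on "no change" — sicker patients receive more aggressive treatment,
and repeat prescriptions dominate near target, mirroring the "human bias"
toward less complex regimens. A patient's first visit records the
pre-enrollment regimen unchanged, because no earlier prescription exists
to infer a change against.

Because the simulator's glycemic kernel depends only on (HbA1c, action),
the optimal policy is computable: `oracle_policy()` runs value iteration
on a discretized HbA1c grid (0.25 % bins, convergence 1e-6) over the
simulator's own transition and reward model as a continuing discounted
MDP. The terminal complication term is not part of the oracle's Bellman
operator; it affects every compared policy equally in rollout evaluation.
In rollouts all policies — behavior, oracle-greedy, DQN-greedy — choose
among the actions coherent with the current regimen, so comparisons are
under matched constraints.

What passing these tests shows — and what it does not: the pipeline
recovers a near-optimal policy from confounded retrospective data *when
the generating process matches the state representation and the reward is
well-specified*. Real registries violate both in ways the simulator does
not model (unobserved confounders, informative visit timing, measurement
error, non-Markov dynamics), so simulator performance is evidence of
implementation correctness, not of clinical effectiveness.

## Problem sizes and numerical choices

The bundled studies use 2,000 simulated patients (about 10,000
transitions), a training budget of 6,000 iterations with early stopping
(checkpoints typically settle between 1,500 and 5,000), a 3-network
ensemble, a step size of 3e-4 for the simulator-scale cohorts (the 0.001
default suits larger buffers; both are config fields), and rollouts of
250-500 patients; policy values are averaged over 3 seeds. Value
iteration tolerance is 1e-6; ties in recommendation rank break toward the
lower action index; weight truncation and band boundaries are configurable
with the defaults above. Long-term slope studies plant a steep hazard
(slope 1.5 per % HbA1c above 7, base log-odds −4, tail −1) so the
protective signal is identifiable at 500 patients per cohort.

## Known limitations

Unified therapeutic targets (no personalization of the 7 % goal); a
single-action-per-visit model with a documented precedence rather than
combination actions; two shipped knowledge rules rather than a guideline
engine; no off-policy evaluation estimators (weighted doubly-robust,
fitted Q evaluation) — retrospective concordance analyses only; and the
association-not-causation caveat of all retrospective evaluation applies
throughout.
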