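# End-to-end pipeline on the synthetic registry: simulate -> build ->
# train -> recommend -> evaluate. This is the programmatic core behind
# the command-line `pipeline` subcommand.

#' Run the full pipeline on a simulated cohort
#'
#' Simulates a registry-schema cohort, splits it by patient, builds
#' antiglycemic trajectories, trains the dueling double-DQN, produces
#' knowledge-filtered recommendations over the validation visits, runs the
#' short-term HbA1c-control evaluation (unadjusted and IPW-adjusted), and
#' compares the mean per-transition simulator reward of the trained
#' greedy policy against the behavior policy and the dynamic-programming
#' oracle.
#'
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param train_config DQN training configuration. The default scales the
#'   optimization down to the bundled simulator's cohort size (a few
#'   thousand transitions rather than millions of visits): a smaller step
#'   size and block-loss early stopping keep offline bootstrapping on the
#'   small fixed buffer stable.
#' @param n_networks Q-network ensemble size (see
#'   [train_dqn_ensemble()]).
#' @param n_policy_patients patients for the policy-value rollouts.
#' @return List: `fit`, `scheme`, `recommendations`, `short_term`
#'   (`compare`, `adjusted`), `policy_value` (named: behavior, dqn,
#'   oracle), `concordance_pct`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L,
                         train_config = dqn_config(max_iter = 6000L,
                                                   lr = 3e-4,
                                                   patience = 12L,
                                                   seed = seed),
                         n_networks = 3L,
                         n_policy_patients = 250L) {
  cohort <- simulate_cohort(config, seed = seed)
  splits <- split_patients(cohort, ratio = 0.8, seed = seed)
  train <- impute_missing(splits$train)
  valid <- impute_missing(splits$validation)
  scheme <- fit_scheme(train)
  transitions <- build_trajectories(train, "antiglycemic", scheme)
  fit <- train_dqn_ensemble(transitions, train_config,
                            n_networks = n_networks)
  recs <- recommend_visits(valid$visits, fit$models, scheme, "antiglycemic")
  samples <- build_outcome_cohort(valid, recs, outcome_spec("hba1c_control"))
  cmp <- short_term_compare(samples)
  covs <- c("age", "hba1c", "diabetes_duration", "bmi", "egfr")
  adj <- tryCatch({
    w <- propensity_weights(samples, covs)
    weighted_logistic_or(samples, w, covs)
  }, error = function(e) NULL)
  # policy-value rollouts under matched conditions
  rollout_cfg <- config
  rollout_cfg$n_patients <- as.integer(n_policy_patients)
  oracle <- oracle_policy(config)
  template <- valid$visits[1, , drop = FALSE]
  pv <- c(
    behavior = evaluate_policy(rollout_cfg, NULL, seed = seed + 1L)$mean_reward,
    dqn = evaluate_policy(rollout_cfg,
                          dqn_gly_policy(fit$models, scheme, template),
                          seed = seed + 1L)$mean_reward,
    oracle = evaluate_policy(rollout_cfg, oracle_gly_policy(oracle),
                             seed = seed + 1L)$mean_reward)
  list(fit = fit, scheme = scheme, recommendations = recs,
       short_term = list(compare = cmp, adjusted = adj),
       policy_value = pv,
       concordance_pct = 100 * mean(samples$exposure))
}

#' Per-patient long-term concordance analysis on a simulated cohort
#'
#' Computes each patient's antiglycemic concordance rate against a
#' reference policy and the occurrence of any complication/death, and
#' fits the binned occurrence curve.
#'
#' @param cohort a `t2d_cohort`.
#' @param recommendations recommendation table covering the cohort's
#'   visits.
#' @param treatment_type treatment type.
#' @return List: `patients` data frame (`patient_id`, `rate`, `outcome`),
#'   `curve` ([longterm_curves()] result).
#' @export
longterm_concordance_analysis <- function(cohort, recommendations,
                                          treatment_type = "antiglycemic") {
  visits <- cohort$visits
  rxcol <- rx_column(treatment_type)
  rec_key <- paste(recommendations$patient_id, recommendations$visit_date)
  rows <- list(); n_row <- 0L
  for (pid in unique(visits$patient_id)) {
    pv <- visits[visits$patient_id == pid, , drop = FALSE]
    rx <- lapply(pv[[rxcol]], parse_rx, treatment_type = treatment_type)
    flags <- rep(NA, nrow(pv))
    for (i in seq_len(nrow(pv))) {
      rec <- match(paste(pid, pv$visit_date[i]), rec_key)
      if (is.na(rec)) next
      prev_rx <- if (i == 1L) rx[[1L]] else rx[[i - 1L]]
      actual <- tryCatch(infer_action(prev_rx, rx[[i]], treatment_type),
                         error = function(e) NA_integer_)
      if (!is.na(actual)) {
        flags[i] <- actual == recommendations$action[rec]
      }
    }
    if (all(is.na(flags))) next
    ev <- patient_events(cohort$outcomes, pid,
                         c(COMPLICATION_EVENTS, "death"))
    n_row <- n_row + 1L
    rows[[n_row]] <- data.frame(patient_id = pid,
                                rate = concordance_rate(flags),
                                outcome = as.integer(length(ev) > 0))
  }
  patients <- do.call(rbind, rows)
  list(patients = patients,
       curve = longterm_curves(patients$rate, patients$outcome))
}
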