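# Synthetic registry simulator: sequential outpatient visits 3-6 months
# apart with treatment-responsive biomarker dynamics (AR(1) pull toward a
# set-point plus an additive per-action effect), severity-dependent
# physician behavior (confounding by indication), hypoglycemia risk tied
# to insulin use, and complication/death hazards tied to biomarker excess
# above target. A dynamic-programming oracle policy on the simulator's own
# glycemic kernel supports policy-recovery tests.
#
# The dynamics are deliberately stylized so that oracle values are exactly
# computable; the simulator's job is statistical structure, not clinical
# fidelity.

#' Simulator configuration
#'
#' @param n_patients number of patients.
#' @param visits_range inclusive range of visits per patient.
#' @param gap_months integer months between visits (mass on 3-6).
#' @param hba1c_setpoint untreated HbA1c set-point (percent).
#' @param hba1c_kappa AR(1) pull rate toward the set-point per interval.
#' @param hba1c_sd interval noise SD of HbA1c (percent).
#' @param gly_effects length-13 additive HbA1c reduction per antiglycemic
#'   action (percent); index = action index + 1.
#' @param hypo_b0,hypo_insulin,hypo_low logistic coefficients of the
#'   severe-hypoglycemia admission model: intercept, per insulin-intensity
#'   unit of the action, per percent of achieved HbA1c below 6.5.
#' @param cx_b0,cx_slope per-interval complication log-odds: intercept and
#'   slope per percent of HbA1c above 7.
#' @param death_b0 per-interval death log-odds intercept (same slope).
#' @param tail_b0 log-odds intercept of a complication/death over the
#'   6-year horizon after the final visit (same slope).
#' @param behavior_theta severity sensitivity of the physician behavior
#'   policy (log-weight per unit effect x (HbA1c - 7)).
#' @param behavior_inertia multiplicative weight of "no change".
#' @return List of class `t2d_sim_config`.
#' @export
sim_config <- function(n_patients = 2000L,
                       visits_range = c(4L, 8L),
                       gap_months = 3:6,
                       hba1c_setpoint = 9,
                       hba1c_kappa = 0.5,
                       hba1c_sd = 0.35,
                       gly_effects = c(0, 0.4, -0.3, 0.8, 0.8, 1.0, 0.9,
                                       0.9, 0.7, 1.3, 1.2, 1.5, 1.7),
                       hypo_b0 = -5, hypo_insulin = 1.2, hypo_low = 0.8,
                       cx_b0 = -6, cx_slope = 0.35,
                       death_b0 = -7,
                       tail_b0 = -2.5,
                       behavior_theta = 0.5,
                       behavior_inertia = 6) {
  stopifnot(length(gly_effects) == 13L, hba1c_sd > 0,
            hba1c_kappa > 0, hba1c_kappa <= 1, behavior_inertia > 0)
  structure(list(n_patients = as.integer(n_patients),
                 visits_range = as.integer(visits_range),
                 gap_months = as.integer(gap_months),
                 hba1c_setpoint = hba1c_setpoint,
                 hba1c_kappa = hba1c_kappa, hba1c_sd = hba1c_sd,
                 gly_effects = gly_effects,
                 hypo_b0 = hypo_b0, hypo_insulin = hypo_insulin,
                 hypo_low = hypo_low,
                 cx_b0 = cx_b0, cx_slope = cx_slope, death_b0 = death_b0,
                 tail_b0 = tail_b0,
                 behavior_theta = behavior_theta,
                 behavior_inertia = behavior_inertia),
            class = "t2d_sim_config")
}

# insulin intensity of a glycemic action (0 = none, 1 = basal/prandial
# single, 2 = premix or basal+prandial)
action_insulin_intensity <- function(action) {
  ifelse(action == 10L, 1L, ifelse(action %in% c(11L, 12L), 2L, 0L))
}

hypo_prob <- function(config, action, next_hba1c) {
  stats::plogis(config$hypo_b0 +
                  config$hypo_insulin * action_insulin_intensity(action) +
                  config$hypo_low * pmax(0, 6.5 - next_hba1c))
}

cx_prob <- function(config, hba1c, intercept) {
  stats::plogis(intercept + config$cx_slope * pmax(0, hba1c - 7))
}

# next-visit HbA1c mean under the configured kernel
next_hba1c_mean <- function(config, hba1c, action) {
  hba1c + config$hba1c_kappa * (config$hba1c_setpoint - hba1c) -
    config$gly_effects[action + 1L]
}

# coherent glycemic actions given the current prescription
coherent_gly_actions <- function(rx) {
  cls <- rx_classes(rx)
  acts <- 0L
  if (length(intersect(DOSE_ACTION_DRUGS, cls))) acts <- c(acts, 1L, 2L)
  absent <- setdiff(OAD_CLASSES, cls)
  acts <- c(acts, unname(GLY_ADD_INDEX[absent]))
  reg <- insulin_regimen_index(cls)
  for (idx in c(10L, 11L, 12L)) {
    if (!identical(idx, reg)) acts <- c(acts, idx)
  }
  sort(unique(acts))
}

behavior_weights <- function(config, hba1c, actions) {
  w <- exp(config$behavior_theta * config$gly_effects[actions + 1L] *
             (hba1c - 7))
  w[actions == 0L] <- w[actions == 0L] * config$behavior_inertia
  w / sum(w)
}

sample_baseline <- function(config, n) {
  trunc_norm <- function(n, mean, sd, lo, hi) {
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  }
  data.frame(
    age = round(trunc_norm(n, 62, 11, 25, 95), 1),
    gender = sample(c("female", "male"), n, replace = TRUE),
    ethnicity = sample(ETHNICITY_LEVELS, n, replace = TRUE,
                       prob = c(0.69, 0.15, 0.11, 0.05)),
    smoker = stats::rbinom(n, 1L, 0.15),
    diabetes_duration = round(trunc_norm(n, 10, 7, 0.5, 40), 1),
    hba1c = round(trunc_norm(n, 8.5, 1.5, 5, 14), 1),
    sbp = round(trunc_norm(n, 136, 15, 95, 200)),
    dbp = round(trunc_norm(n, 78, 10, 50, 120)),
    ldl_c = round(trunc_norm(n, 2.9, 0.8, 0.8, 6), 2),
    tg = round(trunc_norm(n, 1.7, 0.7, 0.4, 6), 2),
    bmi = round(trunc_norm(n, 27, 4, 16, 45), 1),
    egfr = round(trunc_norm(n, 80, 20, 15, 130)),
    hx_hypertension = stats::rbinom(n, 1L, 0.7),
    hx_hypercholesterolemia = stats::rbinom(n, 1L, 0.8),
    hx_mi = stats::rbinom(n, 1L, 0.08),
    hx_heart_failure = stats::rbinom(n, 1L, 0.05),
    hx_stroke = stats::rbinom(n, 1L, 0.06),
    hx_nephropathy = stats::rbinom(n, 1L, 0.15),
    hx_other_micro = stats::rbinom(n, 1L, 0.2),
    hx_hypoglycemia = stats::rbinom(n, 1L, 0.05),
    stringsAsFactors = FALSE
  )
}

initial_gly_rx <- function(hba1c) {
  u <- stats::runif(1)
  cls <- if (u < 0.2) character(0)
  else if (u < 0.7) "metformin"
  else if (u < 0.9) c("metformin", "su")
  else "basal_insulin"
  prescription("antiglycemic", cls, unname(DEFAULT_DOSES[cls]))
}

#' Simulate a registry-schema cohort
#'
#' Generates sequential visits with the configured dynamics and returns a
#' `t2d_cohort` whose tables conform to the [load_registry()] schema.
#' Antiglycemic actions are drawn from the severity-dependent behavior
#' policy unless `gly_policy` is supplied; antihypertensive and
#' lipid-lowering prescriptions follow simple treat-to-target behavior.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (byte-identical output for equal seeds).
#' @param gly_policy optional `function(visit_row, rx, coherent_actions)`
#'   returning a 0-based glycemic action; `NULL` uses the behavior policy.
#' @param return_truth also return the per-transition ground truth
#'   (chosen actions, rewards, next HbA1c) used by tests and policy
#'   evaluation.
#' @return A `t2d_cohort`; with `return_truth = TRUE`, a list
#'   `(cohort, truth)` where `truth` is a data frame with one row per
#'   (visit, next-visit) transition.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L,
                            gly_policy = NULL, return_truth = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- config$n_patients
  base <- sample_baseline(config, n)
  start_dates <- as.Date("2013-01-01") + sample.int(700L, n, replace = TRUE)
  n_visits <- sample(seq(config$visits_range[1], config$visits_range[2]),
                     n, replace = TRUE)
  nv_max <- sum(n_visits)
  # preallocated visit columns
  v_pid <- character(nv_max); v_date <- numeric(nv_max)
  v_num <- matrix(NA_real_, nv_max, 10,
                  dimnames = list(NULL, c("age", "diabetes_duration",
                                          "hba1c", "sbp", "dbp", "ldl_c",
                                          "tg", "bmi", "egfr", "smoker")))
  v_hx <- matrix(0L, nv_max, length(HX_FLAGS),
                 dimnames = list(NULL, HX_FLAGS))
  v_gender <- character(nv_max); v_eth <- character(nv_max)
  v_rxg <- character(nv_max); v_rxa <- character(nv_max)
  v_rxl <- character(nv_max)
  vrow <- 0L
  # outcome events (rare; appended)
  oc_pid <- character(0); oc_type <- character(0); oc_date <- numeric(0)
  add_event <- function(pid, type, day) {
    oc_pid <<- c(oc_pid, pid); oc_type <<- c(oc_type, type)
    oc_date <<- c(oc_date, day)
  }
  # per-transition ground truth
  t_pid <- character(nv_max); t_idx <- integer(nv_max)
  t_h <- numeric(nv_max); t_act <- integer(nv_max)
  t_hn <- numeric(nv_max); t_hypo <- integer(nv_max)
  trow <- 0L
  for (p in seq_len(n)) {
    pid <- sprintf("P%05d", p)
    b <- base[p, ]
    h <- b$hba1c; sbp <- b$sbp; dbp <- b$dbp; ldl <- b$ldl_c
    egfr <- b$egfr; tg <- b$tg; bmi <- b$bmi
    hx <- as.integer(unlist(b[HX_FLAGS]))
    names(hx) <- HX_FLAGS
    rx_g <- initial_gly_rx(h)
    aht_cls <- AHT_CLASSES[stats::runif(4) < ifelse(b$hx_hypertension == 1,
                                                    0.35, 0.05)]
    lip_cls <- if (stats::runif(1) < 0.5) "statin" else character(0)
    day <- as.numeric(start_dates[p])
    day0 <- day
    dead <- FALSE
    for (t in seq_len(n_visits[p])) {
      # prescriptions chosen at this visit -------------------------------
      # the first visit records the pre-enrollment regimen unchanged (no
      # previous prescription exists to infer a change against)
      coherent <- coherent_gly_actions(rx_g)
      act <- if (t == 1L) {
        0L
      } else if (is.null(gly_policy)) {
        sample(coherent, 1L, prob = behavior_weights(config, h, coherent))
      } else {
        a <- gly_policy(c(b, list(hba1c = h, sbp = sbp, dbp = dbp,
                                  ldl_c = ldl, egfr = egfr, tg = tg,
                                  bmi = bmi)), rx_g, coherent)
        if (!a %in% coherent) coherent[1L] else a
      }
      rx_g_new <- apply_action(rx_g, act, "antiglycemic")
      # treat-to-target behavior for the other two types
      if ((sbp >= 140 || dbp >= 90) && length(aht_cls) < 4L &&
          stats::runif(1) < 0.4) {
        aht_cls <- c(aht_cls, sample(setdiff(AHT_CLASSES, aht_cls), 1L))
      } else if (sbp < 130 && length(aht_cls) > 0L && stats::runif(1) < 0.05) {
        aht_cls <- aht_cls[-sample.int(length(aht_cls), 1L)]
      }
      if (ldl >= 2.6 && stats::runif(1) < 0.4) {
        lip_cls <- union(lip_cls,
                         utils::head(setdiff(LIP_CLASSES, lip_cls), 1L))
      }
      vrow <- vrow + 1L
      v_pid[vrow] <- pid; v_date[vrow] <- day
      v_num[vrow, ] <- c(b$age + (day - day0) / DAYS_PER_YEAR,
                         b$diabetes_duration + (day - day0) / DAYS_PER_YEAR,
                         round(h, 2), round(sbp), round(dbp),
                         round(ldl, 2), round(tg, 2), round(bmi, 1),
                         round(egfr), b$smoker)
      v_hx[vrow, ] <- hx
      v_gender[vrow] <- b$gender; v_eth[vrow] <- b$ethnicity
      v_rxg[vrow] <- format_rx(rx_g_new)
      v_rxa[vrow] <- paste(aht_cls, collapse = ";")
      v_rxl[vrow] <- paste(lip_cls, collapse = ";")
      if (t == n_visits[p]) {
        # horizon tail: complication/death after the final visit
        if (stats::runif(1) < cx_prob(config, h, config$tail_b0)) {
          add_event(pid, sample(c(COMPLICATION_EVENTS, "death"), 1L),
                    day + round(DAYS_PER_YEAR))
        }
        break
      }
      gap <- sample(config$gap_months, 1L)
      # jitter within the month, kept inside the 3-6 month pairing window
      gap_days <- round(months_to_days(gap)) + sample(-10:10, 1L)
      gap_days <- min(floor(months_to_days(6)),
                      max(ceiling(months_to_days(3)), gap_days))
      # biomarker transitions --------------------------------------------
      h_next <- next_hba1c_mean(config, h, act) +
        stats::rnorm(1, 0, config$hba1c_sd)
      h_next <- min(15, max(4, h_next))
      n_aht <- length(aht_cls)
      sbp <- sbp + 0.4 * ((150 - 8 * n_aht) - sbp) + stats::rnorm(1, 0, 6)
      dbp <- dbp + 0.4 * ((86 - 4 * n_aht) - dbp) + stats::rnorm(1, 0, 4)
      lip_drop <- sum(c(statin = 1.0, fibrate = 0.1,
                        ezetimibe = 0.4)[lip_cls])
      ldl <- max(0.5, ldl + 0.4 * ((3.2 - lip_drop) - ldl) +
                   stats::rnorm(1, 0, 0.25))
      egfr <- max(8, egfr - 0.4 + stats::rnorm(1, 0, 1.5))
      tg <- max(0.3, tg + stats::rnorm(1, 0, 0.15))
      bmi <- max(15, bmi + stats::rnorm(1, 0, 0.3))
      # events in (t, t+1] ------------------------------------------------
      hypo <- stats::runif(1) < hypo_prob(config, act, h_next)
      if (hypo) {
        add_event(pid, "hypoglycemia_admission", day + round(gap_days / 2))
        hx["hx_hypoglycemia"] <- 1L
      }
      if (stats::runif(1) < cx_prob(config, h, config$cx_b0)) {
        ev <- sample(COMPLICATION_EVENTS, 1L)
        add_event(pid, ev, day + round(gap_days * 0.75))
        hx[switch(ev, myocardial_infarction = "hx_mi",
                  heart_failure = "hx_heart_failure",
                  stroke = "hx_stroke", nephropathy = "hx_nephropathy",
                  other_microvascular = "hx_other_micro")] <- 1L
      }
      if (stats::runif(1) < cx_prob(config, h, config$death_b0)) {
        add_event(pid, "death", day + round(gap_days * 0.9))
        dead <- TRUE
      }
      trow <- trow + 1L
      t_pid[trow] <- pid; t_idx[trow] <- t
      t_h[trow] <- h; t_act[trow] <- act
      t_hn[trow] <- h_next; t_hypo[trow] <- as.integer(hypo)
      rx_g <- rx_g_new
      h <- h_next
      day <- day + gap_days
      if (dead) break
    }
  }
  keep <- seq_len(vrow)
  visits <- data.frame(
    patient_id = v_pid[keep],
    visit_date = as.Date(v_date[keep], origin = "1970-01-01"),
    age = v_num[keep, "age"], gender = v_gender[keep],
    ethnicity = v_eth[keep], smoker = v_num[keep, "smoker"],
    diabetes_duration = v_num[keep, "diabetes_duration"],
    hba1c = v_num[keep, "hba1c"], sbp = v_num[keep, "sbp"],
    dbp = v_num[keep, "dbp"], ldl_c = v_num[keep, "ldl_c"],
    tg = v_num[keep, "tg"], bmi = v_num[keep, "bmi"],
    egfr = v_num[keep, "egfr"],
    as.data.frame(v_hx[keep, , drop = FALSE]),
    rx_gly = v_rxg[keep], rx_aht = v_rxa[keep], rx_lip = v_rxl[keep],
    stringsAsFactors = FALSE)
  outcomes <- data.frame(
    patient_id = oc_pid, event_type = oc_type,
    event_date = as.Date(oc_date, origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  cohort <- new_cohort(visits, outcomes)
  if (!return_truth) return(cohort)
  tkeep <- seq_len(trow)
  truth <- data.frame(patient_id = t_pid[tkeep], visit_index = t_idx[tkeep],
                      hba1c = t_h[tkeep], action = t_act[tkeep],
                      next_hba1c = t_hn[tkeep], hypo = t_hypo[tkeep],
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort to delimited tables
#'
#' @param cohort a `t2d_cohort`.
#' @param visit_file,outcome_file output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, visit_file, outcome_file) {
  utils::write.csv(cohort$visits, visit_file, row.names = FALSE)
  utils::write.csv(cohort$outcomes, outcome_file, row.names = FALSE)
  invisible(c(visit_file, outcome_file))
}

# ---- oracle ---------------------------------------------------------------

#' Dynamic-programming oracle policy on the simulator's glycemic kernel
#'
#' Value iteration on a discretized HbA1c grid using the simulator's own
#' transition kernel and the glycemic reward's expectation (control term
#' plus expected hypoglycemia penalty) as a continuing discounted MDP.
#' Converged when the sup-norm Bellman residual falls below `tol`.
#'
#' @param config a [sim_config()].
#' @param grid HbA1c discretization grid (bin centers, percent).
#' @param gamma discount factor.
#' @param tol convergence tolerance (sup norm).
#' @param max_iter iteration cap; exceeding it is an error.
#' @param coef reward coefficients.
#' @return List of class `t2d_oracle`: `grid`, `policy` (0-based action
#'   per grid point), `values`, `q` (grid x action matrix).
#' @export
oracle_policy <- function(config = sim_config(),
                          grid = seq(4, 15, by = 0.25),
                          gamma = 0.9, tol = 1e-6, max_iter = 10000L,
                          coef = reward_coefficients()) {
  nb <- length(grid)
  half <- diff(grid)[1] / 2
  edges <- c(-Inf, grid[-nb] + half, Inf)
  n_act <- length(config$gly_effects)
  # P[b, b', a] and expected immediate reward R[b, a]
  P <- array(0, c(nb, nb, n_act))
  R <- matrix(0, nb, n_act)
  for (a in seq_len(n_act)) {
    mu <- next_hba1c_mean(config, grid, a - 1L)
    for (b in seq_len(nb)) {
      pr <- diff(stats::pnorm(edges, mu[b], config$hba1c_sd))
      P[b, , a] <- pr
      ctrl <- coef$a * sgn(coef$hba1c_target - grid)
      pen <- coef$b * hypo_prob(config, a - 1L, grid)
      R[b, a] <- sum(pr * (ctrl - pen))
    }
  }
  V <- rep(0, nb)
  for (it in seq_len(max_iter)) {
    Q <- vapply(seq_len(n_act),
                function(a) R[, a] + gamma * P[, , a] %*% V,
                numeric(nb))
    V_new <- apply(Q, 1L, max)
    if (max(abs(V_new - V)) < tol) {
      V <- V_new
      policy <- max.col(Q, ties.method = "first") - 1L
      return(structure(list(grid = grid, policy = policy, values = V,
                            q = Q, iterations = it),
                       class = "t2d_oracle"))
    }
    V <- V_new
  }
  stop("value iteration did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' @export
print.t2d_oracle <- function(x, ...) {
  cat("<t2d_oracle>", length(x$grid), "HbA1c bins; converged in",
      x$iterations, "sweeps\n")
  invisible(x)
}

oracle_action <- function(oracle, hba1c) {
  oracle$policy[pmax(1L, pmin(length(oracle$grid),
                              round((hba1c - oracle$grid[1]) /
                                      diff(oracle$grid)[1]) + 1L))]
}

#' Glycemic rollout policies for the simulator
#'
#' `oracle_gly_policy()` follows the value-iteration oracle (restricted to
#' coherent actions by oracle Q-value); `dqn_gly_policy()` follows the
#' greedy Q-network policy over coherent actions; `random_gly_policy()`
#' picks uniformly among coherent actions (no confounding).
#'
#' @param oracle a [oracle_policy()] result.
#' @return A policy function for [simulate_cohort()]'s `gly_policy`.
#' @export
oracle_gly_policy <- function(oracle) {
  function(visit, rx, coherent) {
    b <- pmax(1L, pmin(length(oracle$grid),
                       round((visit$hba1c - oracle$grid[1]) /
                               diff(oracle$grid)[1]) + 1L))
    qs <- oracle$q[b, coherent + 1L]
    coherent[order(-qs, coherent)][1L]
  }
}

#' @rdname oracle_gly_policy
#' @param model trained `t2d_qmodel`.
#' @param scheme fitted feature scheme.
#' @param visit_template a one-row visit data frame used to supply the
#'   canonical columns the rollout state lacks.
#' @export
dqn_gly_policy <- function(model, scheme, visit_template) {
  function(visit, rx, coherent) {
    row <- visit_template
    for (f in c("age", "gender", "ethnicity", "smoker", "diabetes_duration",
                "hba1c", "sbp", "dbp", "ldl_c", "tg", "bmi", "egfr",
                HX_FLAGS)) {
      if (!is.null(visit[[f]])) row[[f]] <- visit[[f]]
    }
    row$rx_gly <- format_rx(rx)
    q <- as.vector(q_values(model, encode_state(row, scheme)))
    coherent[order(-q[coherent + 1L], coherent)][1L]
  }
}

#' @rdname oracle_gly_policy
#' @export
random_gly_policy <- function() {
  function(visit, rx, coherent) {
    coherent[sample.int(length(coherent), 1L)]
  }
}

#' Mean per-transition reward of a glycemic policy on the simulator
#'
#' Simulates a cohort under the given policy and averages the glycemic
#' reward over all transitions (control term, hypoglycemia penalty, and
#' terminal complication term via the standard trajectory construction).
#'
#' @param config a [sim_config()].
#' @param gly_policy policy function or `NULL` for the behavior policy.
#' @param seed integer seed.
#' @param coef reward coefficients.
#' @return List: `mean_reward`, `n_transitions`.
#' @export
evaluate_policy <- function(config = sim_config(), gly_policy = NULL,
                            seed = 1L, coef = reward_coefficients()) {
  sim <- simulate_cohort(config, seed = seed, gly_policy = gly_policy,
                         return_truth = TRUE)
  truth <- sim$truth
  # immediate terms from the ground truth; terminal complication term from
  # the outcome table, applied to each patient's last transition
  r <- coef$a * sgn(coef$hba1c_target - truth$next_hba1c) -
    coef$b * truth$hypo
  last <- !duplicated(truth$patient_id, fromLast = TRUE)
  oc <- sim$cohort$outcomes
  cx_pat <- unique(oc$patient_id[oc$event_type %in%
                                   c(COMPLICATION_EVENTS, "death")])
  cx_sign <- ifelse(truth$patient_id %in% cx_pat, 1, -1)
  r <- r - coef$c * as.numeric(last) * cx_sign
  list(mean_reward = mean(r), n_transitions = length(r))
}
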