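# Retrospective evaluation: short-term goal-attainment comparisons between
# model-concordant and model-nonconcordant visits (chi-squared test, odds
# ratios, propensity-score inverse-probability weighting, weighted logistic
# regression with robust standard errors), long-term concordance-rate
# analyses (binned occurrence curves with fitted slopes, multivariate
# regression with a baseline risk-score covariate), and the medication
# pattern histogram.

SHORT_TERM_OUTCOMES <- c("hba1c_control", "bp_control", "ldl_control",
                         "hypoglycemia")

#' Outcome specification
#'
#' Short-term outcomes are visit-level: goal attainment after 3-6 months
#' of therapy (HbA1c < 7 %, SBP/DBP < 140/90 mmHg, LDL-c < 2.6 mmol/L;
#' strict inequalities) or a severe hypoglycemia admission in the next 6
#' months. Long-term outcomes are patient-level complication/death events
#' over up to 6 years.
#'
#' @param name one of `"hba1c_control"`, `"bp_control"`, `"ldl_control"`,
#'   `"hypoglycemia"` or a long-term event type (e.g. `"nephropathy"`,
#'   `"death"`).
#' @param horizon_years horizon for long-term outcomes.
#' @return List of class `t2d_outcome_spec`.
#' @export
outcome_spec <- function(name, horizon_years = 6) {
  type <- if (name %in% SHORT_TERM_OUTCOMES) "short_term" else "long_term"
  if (type == "long_term" && !name %in% c(COMPLICATION_EVENTS, "death")) {
    stop("unknown outcome: ", name, call. = FALSE)
  }
  structure(list(name = name, type = type, horizon_years = horizon_years),
            class = "t2d_outcome_spec")
}

#' Build the visit-level outcome cohort for a short-term outcome
#'
#' Pairs consecutive visits 3-6 months apart, attaches the concordance
#' exposure flag (actual inferred action equals the model's top-1
#' recommendation), the outcome, and current-visit covariates; visits
#' without the outcome information are excluded.
#'
#' @param cohort an imputed `t2d_cohort`.
#' @param recommendations data frame from [recommend_visits()]
#'   (`patient_id`, `visit_date`, `action`).
#' @param spec an [outcome_spec()] (short-term).
#' @param treatment_type treatment type the recommendations address.
#' @param covariates covariate column names to carry along.
#' @param followup_months admissible visit spacing.
#' @return Data frame: `patient_id`, `visit_date`, `exposure` (0/1),
#'   `outcome` (0/1), covariates.
#' @export
build_outcome_cohort <- function(cohort, recommendations, spec,
                                 treatment_type = "antiglycemic",
                                 covariates = c("age", "hba1c", "sbp",
                                                "dbp", "ldl_c", "egfr",
                                                "bmi", "diabetes_duration"),
                                 followup_months = c(3, 6)) {
  stopifnot(inherits(spec, "t2d_outcome_spec"), spec$type == "short_term")
  visits <- cohort$visits
  rxcol <- rx_column(treatment_type)
  win <- months_to_days(followup_months)
  rec_key <- paste(recommendations$patient_id, recommendations$visit_date)
  out <- list(); n_out <- 0L
  for (pid in unique(visits$patient_id)) {
    pv <- visits[visits$patient_id == pid, , drop = FALSE]
    if (nrow(pv) < 2L) next
    hypo_events <- patient_events(cohort$outcomes, pid,
                                  "hypoglycemia_admission")
    rx <- lapply(pv[[rxcol]], parse_rx, treatment_type = treatment_type)
    gaps <- as.numeric(diff(pv$visit_date))
    for (i in which(gaps >= win[1] & gaps <= win[2])) {
      j <- i + 1L
      rec <- match(paste(pid, pv$visit_date[i]), rec_key)
      if (is.na(rec)) next
      outcome <- switch(spec$name,
        hba1c_control = if (is.na(pv$hba1c[j])) NA else
          as.integer(pv$hba1c[j] < 7),
        bp_control = if (is.na(pv$sbp[j]) || is.na(pv$dbp[j])) NA else
          as.integer(pv$sbp[j] < 140 & pv$dbp[j] < 90),
        ldl_control = if (is.na(pv$ldl_c[j])) NA else
          as.integer(pv$ldl_c[j] < 2.6),
        hypoglycemia = as.integer(any(
          hypo_events > pv$visit_date[i] &
            hypo_events <= pv$visit_date[i] + months_to_days(6))))
      if (is.na(outcome)) next  # excluded: no outcome information
      prev_rx <- if (i == 1L) rx[[1L]] else rx[[i - 1L]]
      actual <- tryCatch(infer_action(prev_rx, rx[[i]], treatment_type),
                         error = function(e) NA_integer_)
      if (is.na(actual)) next
      n_out <- n_out + 1L
      row <- data.frame(patient_id = pid, visit_date = pv$visit_date[i],
                        exposure = as.integer(actual ==
                                                recommendations$action[rec]),
                        outcome = outcome, stringsAsFactors = FALSE)
      for (cv in covariates) row[[cv]] <- pv[[cv]][i]
      out[[n_out]] <- row
    }
  }
  if (!n_out) stop("no evaluable visit pairs", call. = FALSE)
  samples <- do.call(rbind, out)
  for (grp in c(0L, 1L)) {
    if (!any(samples$exposure == grp)) {
      stop("empty ", if (grp) "concordant" else "nonconcordant", " group",
           call. = FALSE)
    }
  }
  samples
}

#' Compare a short-term outcome between concordant groups
#'
#' 2x2 table statistics: group sizes, event counts, incidences, the
#' chi-squared test, and the unadjusted odds ratio (cross-ratio, with
#' Haldane 0.5 correction if any cell is zero).
#'
#' @param samples data frame with `exposure` and `outcome` (0/1), or
#'   explicit counts via `counts = c(n1, x1, n0, x0)` (concordant n/events,
#'   nonconcordant n/events).
#' @param counts optional explicit counts (overrides `samples`).
#' @return List of class `t2d_short_term`: `n`, `events`, `incidence`
#'   (percent), `chisq`, `p_value`, `odds_ratio`.
#' @export
short_term_compare <- function(samples = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(samples))
    if (length(unique(samples$exposure)) < 2L) {
      stop("both exposure groups required", call. = FALSE)
    }
    n1 <- sum(samples$exposure == 1); x1 <- sum(samples$outcome[samples$exposure == 1])
    n0 <- sum(samples$exposure == 0); x0 <- sum(samples$outcome[samples$exposure == 0])
  } else {
    n1 <- counts[1]; x1 <- counts[2]; n0 <- counts[3]; x0 <- counts[4]
  }
  tab <- matrix(c(x1, n1 - x1, x0, n0 - x0), 2L, byrow = TRUE,
                dimnames = list(c("concordant", "nonconcordant"),
                                c("event", "no_event")))
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  cells <- as.numeric(tab)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] / cells[3]) / (cells[2] / cells[4])
  structure(list(n = c(concordant = n1, nonconcordant = n0),
                 events = c(concordant = x1, nonconcordant = x0),
                 incidence = c(concordant = 100 * x1 / n1,
                               nonconcordant = 100 * x0 / n0),
                 chisq = unname(cs$statistic), p_value = cs$p.value,
                 odds_ratio = or, table = tab),
            class = "t2d_short_term")
}

#' @export
print.t2d_short_term <- function(x, ...) {
  cat(sprintf("concordant    %8d events %8d (%.2f%%)\n", x$n[1], x$events[1],
              x$incidence[1]))
  cat(sprintf("nonconcordant %8d events %8d (%.2f%%)\n", x$n[2], x$events[2],
              x$incidence[2]))
  cat(sprintf("unadjusted OR %.3f, chi-squared p %.3g\n", x$odds_ratio,
              x$p_value))
  invisible(x)
}

#' Inverse-probability-of-treatment weights from a propensity model
#'
#' Fits a main-effects logistic regression of exposure on the covariates,
#' and weights exposed samples by 1/PS and unexposed by 1/(1-PS). Weights
#' are truncated at configurable percentiles (default 1st/99th).
#'
#' @param samples data frame with `exposure` and the covariates.
#' @param covariates covariate column names.
#' @param truncate_at length-2 percentile pair for weight truncation.
#' @return Numeric weight vector with attribute `ps`.
#' @export
propensity_weights <- function(samples, covariates,
                               truncate_at = c(0.01, 0.99)) {
  f <- stats::as.formula(paste("exposure ~",
                               paste(covariates, collapse = " + ")))
  fit <- stats::glm(f, family = stats::binomial(), data = samples)
  if (!fit$converged) stop("propensity model did not converge", call. = FALSE)
  ps <- stats::fitted(fit)
  w <- ifelse(samples$exposure == 1, 1 / ps, 1 / (1 - ps))
  lim <- stats::quantile(w, truncate_at)
  w <- pmin(lim[2], pmax(lim[1], w))
  attr(w, "ps") <- ps
  w
}

#' Standardized mean differences of covariates between exposure groups
#'
#' @param samples data frame with `exposure` and covariates.
#' @param covariates covariate column names.
#' @param weights optional per-sample weights (default 1).
#' @return Named vector of absolute standardized mean differences.
#' @export
standardized_differences <- function(samples, covariates, weights = NULL) {
  w <- weights %||% rep(1, nrow(samples))
  vapply(covariates, function(cv) {
    x <- samples[[cv]]
    e <- samples$exposure == 1
    wm <- function(x, w) sum(w * x) / sum(w)
    wv <- function(x, w) sum(w * (x - wm(x, w))^2) / sum(w)
    m1 <- wm(x[e], w[e]); m0 <- wm(x[!e], w[!e])
    s <- sqrt((wv(x[e], w[e]) + wv(x[!e], w[!e])) / 2)
    abs(m1 - m0) / s
  }, numeric(1))
}

#' Weighted logistic regression odds ratio with robust standard errors
#'
#' Fits `outcome ~ exposure + covariates` with per-sample weights and
#' reports the exposure odds ratio with a 95% CI and p-value from
#' heteroskedasticity-consistent (sandwich) standard errors, as model-based
#' errors are invalid under inverse-probability weighting.
#'
#' @param samples data frame with `outcome`, `exposure`, covariates.
#' @param weights per-sample weights (default 1: unweighted).
#' @param covariates covariate column names (may be empty).
#' @return List of class `t2d_adjusted_or`: `odds_ratio`, `ci` (length 2),
#'   `p_value`, `coef` (exposure log-odds), `se`.
#' @export
weighted_logistic_or <- function(samples, weights = NULL,
                                 covariates = character(0)) {
  w <- weights %||% rep(1, nrow(samples))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  rhs <- paste(c("exposure", covariates), collapse = " + ")
  f <- stats::as.formula(paste("outcome ~", rhs))
  dat <- samples
  dat$.w <- w
  fit <- suppressWarnings(
    stats::glm(f, family = stats::quasibinomial(), data = dat, weights = .w))
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("separation suspected in weighted logistic model; consider ",
         "penalization", call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  b <- stats::coef(fit)[["exposure"]]
  se <- sqrt(vc["exposure", "exposure"])
  z <- b / se
  structure(list(odds_ratio = exp(b),
                 ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 coef = b, se = se),
            class = "t2d_adjusted_or")
}

#' @export
print.t2d_adjusted_or <- function(x, ...) {
  cat(sprintf("adjusted OR %.3f (95%% CI %.3f-%.3f), p %.3g\n",
              x$odds_ratio, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' HbA1c band of a visit
#'
#' Bands: low (< 7 %), medium (7-9 %, 9.0 assigned to medium), high
#' (> 9 %).
#'
#' @param hba1c numeric vector.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
hba1c_band <- function(hba1c) {
  factor(ifelse(hba1c < 7, "low", ifelse(hba1c <= 9, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Stratified short-term analysis by current HbA1c band
#'
#' Runs the compare / weight / regress pipeline within each band; empty
#' strata are reported as absent.
#'
#' @param samples outcome cohort from [build_outcome_cohort()].
#' @param covariates covariates for weighting and regression.
#' @param strata factor of strata (default: [hba1c_band()] of `hba1c`).
#' @return Named list of per-stratum lists (`compare`, `adjusted`).
#' @export
stratified_analysis <- function(samples, covariates,
                                strata = hba1c_band(samples$hba1c)) {
  out <- list()
  for (lev in levels(strata)) {
    s <- samples[which(strata == lev), , drop = FALSE]
    if (nrow(s) == 0L || length(unique(s$exposure)) < 2L) next
    cmp <- short_term_compare(s)
    adj <- tryCatch({
      w <- propensity_weights(s, covariates)
      weighted_logistic_or(s, w, covariates)
    }, error = function(e) NULL)
    out[[lev]] <- list(compare = cmp, adjusted = adj)
  }
  out
}

#' Per-patient concordance rate
#'
#' @param flags logical/0-1 vector of per-visit concordance flags
#'   (`NA`s are dropped).
#' @return The exact ratio of concordant visits.
#' @export
concordance_rate <- function(flags) {
  flags <- flags[!is.na(flags)]
  if (!length(flags)) stop("no visits with a concordance flag", call. = FALSE)
  mean(as.numeric(flags))
}

#' Binned long-term occurrence curve and fitted slope
#'
#' Groups patients into concordance-rate bins (default width 0.2; the last
#' bin is closed above), computes the outcome occurrence per bin, and fits
#' a straight line by ordinary least squares over the non-empty bin points
#' (bin centers as x).
#'
#' @param rates per-patient concordance rates in [0, 1].
#' @param outcomes per-patient 0/1 outcome indicator.
#' @param bin_width bin width (default 0.2, "every 20% as a group").
#' @param min_bin_n bins with fewer patients are reported in `bins` but
#'   excluded from the straight-line fit: occurrence estimates from a
#'   handful of patients would dominate the unweighted least squares.
#' @return List: `bins` data frame (`center`, `n`, `occurrence`), `slope`,
#'   `intercept`.
#' @export
longterm_curves <- function(rates, outcomes, bin_width = 0.2,
                            min_bin_n = 10L) {
  stopifnot(length(rates) == length(outcomes),
            all(rates >= 0 & rates <= 1))
  edges <- seq(0, 1, by = bin_width)
  bin <- pmin(findInterval(rates, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  centers <- edges[-length(edges)] + bin_width / 2
  df <- data.frame(center = centers,
                   n = tabulate(bin, nbins = length(centers)))
  df$occurrence <- vapply(seq_along(centers), function(b) {
    if (df$n[b] == 0L) NA_real_ else mean(outcomes[bin == b])
  }, numeric(1))
  pts <- df[!is.na(df$occurrence) & df$n >= min_bin_n, , drop = FALSE]
  if (nrow(pts) < 2L) stop("fewer than 2 usable bins; slope undefined",
                           call. = FALSE)
  fit <- stats::lm(occurrence ~ center, data = pts)
  list(bins = df, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Multivariate regression of a long-term outcome on concordance rates
#'
#' Logistic regression of the outcome on the three per-patient
#' concordance rates with the baseline risk score as covariate. Only
#' patients with all three rates (and a risk score) are included.
#'
#' @param data data frame with columns `rate_gly`, `rate_aht`, `rate_lip`,
#'   `risk_score`, `outcome`.
#' @return List of class `t2d_longterm_fit`: `coefficients` data frame
#'   (`term`, `estimate`, `se`, `p_value`), `n`.
#' @export
longterm_regression <- function(data) {
  need <- c("rate_gly", "rate_aht", "rate_lip", "risk_score", "outcome")
  stopifnot(all(need %in% names(data)))
  data <- data[stats::complete.cases(data[need]), , drop = FALSE]
  fit <- stats::glm(outcome ~ rate_gly + rate_aht + rate_lip + risk_score,
                    family = stats::binomial(), data = data)
  if (any(abs(stats::coef(fit)[-1]) > 20, na.rm = TRUE)) {
    stop("separation suspected in long-term regression", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], p_value = sm[, 4],
                              row.names = NULL),
    n = nrow(data)), class = "t2d_longterm_fit")
}

#' Baseline risk score from gradient boosting
#'
#' Fits a gradient-boosted binary classifier (xgboost) of the outcome on
#' baseline features and returns out-of-fold predicted probabilities as
#' the per-patient risk score. A penalized-free logistic fallback is
#' available via `method = "logistic"`.
#'
#' @param features numeric matrix/data frame of baseline features.
#' @param outcome 0/1 outcome vector.
#' @param method `"xgboost"` (default) or `"logistic"`.
#' @param nfold cross-validation folds for out-of-fold scores.
#' @param nrounds boosting rounds.
#' @param seed integer seed.
#' @return Numeric vector of risk scores in [0, 1].
#' @export
risk_score_model <- function(features, outcome, method = c("xgboost",
                                                           "logistic"),
                             nfold = 5L, nrounds = 50L, seed = 1L) {
  method <- match.arg(method)
  outcome <- as.numeric(outcome)
  if (length(unique(outcome)) < 2L) {
    stop("degenerate outcome: all one class", call. = FALSE)
  }
  X <- as.matrix(features)
  n <- nrow(X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfold), n))
  scores <- numeric(n)
  for (k in seq_len(nfold)) {
    tr <- fold != k
    if (method == "xgboost") {
      dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                  label = outcome[tr], nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3L,
                      eta = 0.2, nthread = 1L),
        data = dtr, nrounds = nrounds, verbose = 0L)
      scores[!tr] <- predict(fit, xgboost::xgb.DMatrix(
        X[!tr, , drop = FALSE], nthread = 1L))
    } else {
      df <- as.data.frame(X)
      df$.y <- outcome
      fit <- stats::glm(.y ~ ., family = stats::binomial(), data = df[tr, ])
      scores[!tr] <- stats::predict(fit, newdata = df[!tr, ],
                                    type = "response")
    }
  }
  pmin(1, pmax(0, scores))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC, used to check risk-score discrimination.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Medication-pattern histogram
#'
#' For each HbA1c band, counts visits per (number of distinct OAD
#' classes, insulin intensity) cell. Insulin intensity: 0 none, 1 single
#' basal or prandial insulin, 2 premixed or basal+prandial combination.
#'
#' @param visits visit data frame with `hba1c` and `rx_gly`.
#' @return Long-format data frame: `band`, `n_oad`, `insulin`, `count`.
#' @export
medication_pattern_histogram <- function(visits) {
  if (inherits(visits, "t2d_cohort")) visits <- visits$visits
  band <- hba1c_band(visits$hba1c)
  cls <- lapply(visits$rx_gly, rx_class_vec,
                treatment_type = "antiglycemic")
  n_oad <- vapply(cls, function(x) length(intersect(x, OAD_CLASSES)),
                  integer(1))
  insulin <- vapply(cls, function(x) {
    ins <- intersect(x, INSULIN_CLASSES)
    if (length(ins) == 0L) 0L
    else if ("premix_insulin" %in% ins || length(ins) >= 2L) 2L
    else 1L
  }, integer(1))
  out <- as.data.frame(table(band = band, n_oad = n_oad, insulin = insulin),
                       stringsAsFactors = FALSE)
  names(out)[4] <- "count"
  out$n_oad <- as.integer(out$n_oad)
  out$insulin <- as.integer(out$insulin)
  out
}

#' Simulate confounded exposure/outcome samples with a planted effect
#'
#' Generates visit-level samples where three covariates drive both the
#' exposure (confounding by indication) and the outcome, and the
#' conditional exposure odds ratio is exactly `true_or`. Used to check
#' that inverse-probability weighting plus covariate-adjusted weighted
#' logistic regression recovers the planted effect where the naive
#' comparison does not.
#'
#' @param n number of samples.
#' @param true_or planted conditional odds ratio of the exposure.
#' @param confounding strength of the shared covariate effects.
#' @param seed integer seed.
#' @return Data frame: `exposure`, `outcome`, `x1`, `x2`, `x3`.
#' @export
simulate_confounded_samples <- function(n, true_or = 1.5, confounding = 0.8,
                                        seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rbinom(n, 1, 0.4)
  lp_exp <- confounding * (x1 + 0.7 * x2 + 0.5 * x3) - 0.2
  exposure <- stats::rbinom(n, 1, stats::plogis(lp_exp))
  lp_out <- -0.5 + log(true_or) * exposure +
    confounding * (0.8 * x1 + 0.6 * x2 - 0.5 * x3)
  outcome <- stats::rbinom(n, 1, stats::plogis(lp_out))
  data.frame(exposure = exposure, outcome = outcome,
             x1 = x1, x2 = x2, x3 = x3)
}
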