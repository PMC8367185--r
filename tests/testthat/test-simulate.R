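test_that("simulation is byte-identical given the seed", {
  cfg <- sim_config(n_patients = 30)
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$visits, c_$visits))
})

test_that("simulated tables satisfy the cohort invariants", {
  co <- simulate_cohort(sim_config(n_patients = 80), seed = 3)
  v <- co$visits
  expect_false(any(duplicated(paste(v$patient_id, v$visit_date))))
  for (f in c("hba1c", "sbp", "dbp", "ldl_c", "egfr", "bmi")) {
    expect_true(all(v[[f]] > 0))
  }
  # visit spacing lies in the 3-6 month pairing window
  gaps <- unlist(tapply(as.numeric(v$visit_date), v$patient_id, diff))
  expect_true(all(gaps >= 3 * 30.4375 - 1 & gaps <= 6 * 30.4375 + 1))
  expect_true(all(co$outcomes$event_type %in%
                    c("hypoglycemia_admission", "myocardial_infarction",
                      "heart_failure", "stroke", "nephropathy",
                      "other_microvascular", "death")))
  # at most one death per patient
  d <- co$outcomes[co$outcomes$event_type == "death", ]
  expect_false(any(duplicated(d$patient_id)))
  # round trip through the registry reader preserves the schema
  paths <- write_tiny_csv(v, co$outcomes)
  of <- tempfile(fileext = ".csv")
  utils::write.csv(co$outcomes, of, row.names = FALSE)
  rt <- load_registry(paths$visit, of)
  expect_equal(nrow(rt$visits), nrow(v))
  expect_equal(sort(rt$visits$hba1c), sort(v$hba1c))
})

test_that("configured action effects appear in next-visit biomarker means", {
  # under a randomized policy there is no confounding, so the mean
  # next-visit HbA1c difference between action groups equals the
  # configured effect difference
  cfg <- sim_config(n_patients = 1500)
  sim <- simulate_cohort(cfg, seed = 21, gly_policy = random_gly_policy(),
                         return_truth = TRUE)
  tr <- sim$truth[sim$truth$visit_index > 1, ]
  base <- tr$next_hba1c - (tr$hba1c + cfg$hba1c_kappa *
                             (cfg$hba1c_setpoint - tr$hba1c))
  grp5 <- base[tr$action == 5L]   # adding metformin: effect -1.0
  grp0 <- base[tr$action == 0L]   # no change: effect 0
  diff_hat <- mean(grp5) - mean(grp0)
  se <- sqrt(var(grp5) / length(grp5) + var(grp0) / length(grp0))
  expect_lt(abs(diff_hat - (-1.0)), 3 * se)
})

test_that("zero hazards produce no complication or death events", {
  cfg <- sim_config(n_patients = 60, cx_b0 = -Inf, death_b0 = -Inf,
                    tail_b0 = -Inf, hypo_b0 = -Inf)
  co <- simulate_cohort(cfg, seed = 5)
  expect_equal(nrow(co$outcomes), 0L)
})

test_that("event incidence increases monotonically with the hazard slope", {
  inc <- vapply(c(0.1, 0.5, 1.2), function(sl) {
    co <- simulate_cohort(sim_config(n_patients = 250, cx_slope = sl),
                          seed = 31)
    ev <- co$outcomes$event_type %in% c("myocardial_infarction",
                                        "heart_failure", "stroke",
                                        "nephropathy", "other_microvascular",
                                        "death")
    length(unique(co$outcomes$patient_id[ev])) / 250
  }, numeric(1))
  expect_true(all(diff(inc) > 0))
})

test_that("value iteration oracle picks dominant actions and honors gamma", {
  # one action strictly dominates every reward component
  effects <- rep(0, 13); effects[6] <- 2.5
  cfg <- sim_config(gly_effects = effects, hypo_b0 = -30)
  orc <- oracle_policy(cfg)
  expect_true(all(orc$policy == 5L))
  # gamma = 0 reduces to maximizing the immediate expected reward
  cfg2 <- sim_config()
  orc0 <- oracle_policy(cfg2, gamma = 0)
  grid <- orc0$grid
  for (b in c(10L, 25L, 40L)) {
    imm <- vapply(0:12, function(a) {
      mu <- t2dtr:::next_hba1c_mean(cfg2, grid[b], a)
      half <- diff(grid)[1] / 2
      edges <- c(-Inf, grid[-length(grid)] + half, Inf)
      pr <- diff(stats::pnorm(edges, mu, cfg2$hba1c_sd))
      sum(pr * (sgn(7 - grid) - 2 * t2dtr:::hypo_prob(cfg2, a, grid)))
    }, numeric(1))
    expect_equal(orc0$policy[b], which.max(imm) - 1L)
  }
})

test_that("oracle values match an independent value iteration on a tiny grid", {
  cfg <- sim_config()
  grid <- c(5, 8, 11)
  orc <- oracle_policy(cfg, grid = grid, gamma = 0.8)
  # independent reconstruction of the discretized MDP and Bellman solve
  half <- diff(grid)[1] / 2
  edges <- c(-Inf, grid[-3] + half, Inf)
  P <- array(0, c(3, 3, 13)); R <- matrix(0, 3, 13)
  ins <- c(rep(0, 10), 1, 2, 2)  # insulin intensity per action
  for (a in 1:13) {
    p_hypo <- stats::plogis(cfg$hypo_b0 + cfg$hypo_insulin * ins[a] +
                              cfg$hypo_low * pmax(0, 6.5 - grid))
    for (b in 1:3) {
      mu <- grid[b] + cfg$hba1c_kappa * (cfg$hba1c_setpoint - grid[b]) -
        cfg$gly_effects[a]
      pr <- diff(stats::pnorm(edges, mu, cfg$hba1c_sd))
      P[b, , a] <- pr
      R[b, a] <- sum(pr * (ifelse(grid < 7, 1, -1) - 2 * p_hypo))
    }
  }
  V <- rep(0, 3)
  for (i in 1:5000) {
    Q <- sapply(1:13, function(a) R[, a] + 0.8 * P[, , a] %*% V)
    Vn <- apply(Q, 1, max)
    if (max(abs(Vn - V)) < 1e-10) break
    V <- Vn
  }
  expect_equal(orc$values, V, tolerance = 1e-5)
})

test_that("behavior policy intensifies with severity (confounding)", {
  cfg <- sim_config(n_patients = 800)
  sim <- simulate_cohort(cfg, seed = 13, return_truth = TRUE)
  tr <- sim$truth[sim$truth$visit_index > 1, ]
  pot <- cfg$gly_effects[tr$action + 1L]
  # mean chosen potency is higher for uncontrolled patients
  expect_gt(mean(pot[tr$hba1c > 9]), mean(pot[tr$hba1c < 7]) + 0.2)
})
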