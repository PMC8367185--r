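test_that("load_registry reads clean tables and orders visits by date", {
  vs <- tiny_visit_df()
  vs <- vs[c(4, 1, 5, 2, 6, 3), ]  # shuffled on disk
  paths <- write_tiny_csv(vs)
  co <- load_registry(paths$visit)
  expect_s3_class(co, "t2d_cohort")
  expect_equal(length(unique(co$visits$patient_id)), 2L)
  expect_equal(nrow(co$visits), 6L)
  for (pid in c("A", "B")) {
    d <- co$visits$visit_date[co$visits$patient_id == pid]
    expect_true(all(diff(d) > 0))
  }
})

test_that("malformed numeric cells become missing values, row retained", {
  vs <- tiny_visit_df()
  vs$hba1c <- as.character(vs$hba1c)
  vs$hba1c[2] <- "abc"
  paths <- write_tiny_csv(vs)
  co <- load_registry(paths$visit)
  expect_equal(nrow(co$visits), 6L)
  expect_true(is.na(co$visits$hba1c[co$visits$patient_id == "A"][2]))
})

test_that("schema violations are reported precisely", {
  vs <- tiny_visit_df()
  paths <- write_tiny_csv(rbind(vs, vs[1, ]))
  expect_error(load_registry(paths$visit), "duplicate")
  vs2 <- tiny_visit_df()
  names(vs2)[names(vs2) == "patient_id"] <- "subject"
  paths2 <- write_tiny_csv(vs2)
  expect_error(load_registry(paths2$visit), "patient_id")
  # but a schema mapping fixes it
  co <- load_registry(paths2$visit, schema = c(patient_id = "subject"))
  expect_equal(nrow(co$visits), 6L)
  vs3 <- tiny_visit_df()
  vs3$visit_date <- as.character(vs3$visit_date)
  vs3$visit_date[3] <- "not-a-date"
  paths3 <- write_tiny_csv(vs3)
  expect_error(load_registry(paths3$visit), "row")
})

test_that("imputation carries forward within one year, then uses the median", {
  vs <- tiny_visit_df()
  # A: missing at visit 2 (4 months after an observed 8.2) -> LOCF
  vs$hba1c[2] <- NA
  # B: missing at a visit 14 months after the only observation -> median
  vs$visit_date[6] <- as.Date("2015-05-01")
  vs$hba1c[5] <- NA
  vs$hba1c[6] <- NA
  co <- structure(list(visits = vs,
                       outcomes = tiny_cohort()$outcomes),
                  class = "t2d_cohort")
  imp <- impute_missing(co)
  a <- imp$visits[imp$visits$patient_id == "A", ]
  expect_equal(a$hba1c[2], 8.2)
  expect_match(a$imputed_fields[2], "hba1c=locf")
  b <- imp$visits[imp$visits$patient_id == "B", ]
  expect_equal(b$hba1c[2], 9.5)  # 4 months after the observed 9.5 -> LOCF
  # visit 3 is 15 months after the last *observed* value -> median of all
  # observed values across patients: median(8.2, 7.1, 9.5) = 8.2
  expect_equal(b$hba1c[3], 8.2)
  expect_match(b$imputed_fields[3], "hba1c=median")
})

test_that("imputation is idempotent and the identity on complete data", {
  co <- tiny_cohort()
  expect_equal(impute_missing(co)$visits["hba1c"], co$visits["hba1c"])
  vs <- tiny_visit_df(); vs$ldl_c[3] <- NA
  co2 <- structure(list(visits = vs, outcomes = co$outcomes),
                   class = "t2d_cohort")
  once <- impute_missing(co2)
  twice <- impute_missing(once)
  expect_equal(twice$visits[names(twice$visits) != "imputed_fields"],
               once$visits[names(once$visits) != "imputed_fields"])
  expect_error(impute_missing(structure(
    list(visits = transform(tiny_visit_df(), tg = NA_real_),
         outcomes = co$outcomes), class = "t2d_cohort")), "median")
})

test_that("trajectory pairing follows the 3-6 month window", {
  co <- impute_missing(tiny_cohort())
  sch <- fit_scheme(co)
  tr <- build_trajectories(co, "antiglycemic", sch)
  # both patients have visits 4 months apart: 2 transitions each,
  # the later one terminal
  expect_equal(length(tr$reward), 4L)
  expect_equal(sum(tr$terminal), 2L)
  expect_true(all(tr$action >= 0 & tr$action < 13))
  expect_true(all(is.na(tr$next_state[tr$terminal, 1])))
  expect_true(all(!is.na(tr$next_state[!tr$terminal, 1])))
  # squeezing the visits inside 3 months removes all pairs
  vs <- tiny_visit_df()
  vs$visit_date <- rep(as.Date(c("2014-01-01", "2014-02-01", "2014-03-01")),
                       2)
  co2 <- impute_missing(structure(list(visits = vs, outcomes = co$outcomes),
                                  class = "t2d_cohort"))
  expect_warning(tr2 <- build_trajectories(co2, "antiglycemic", sch),
                 "no transitions")
  expect_length(tr2$reward, 0L)
})

test_that("terminal rewards carry the horizon complication term", {
  oc <- data.frame(patient_id = "A", event_type = "myocardial_infarction",
                   event_date = as.Date("2016-01-01"))
  co <- impute_missing(tiny_cohort(oc))
  sch <- fit_scheme(co)
  tr <- build_trajectories(co, "antiglycemic", sch)
  # A's terminal transition: next HbA1c 7.1 >= 7 -> -1, plus MI within
  # 6 years of the final visit -> -4
  rA <- tr$reward[tr$patient_id == "A" & tr$terminal]
  expect_equal(rA, -1 - 4)
  # B has no events: -1 (HbA1c 8.4) + 4
  rB <- tr$reward[tr$patient_id == "B" & tr$terminal]
  expect_equal(rB, -1 + 4)
})

test_that("visits after death or the censoring complication are excluded", {
  oc <- data.frame(patient_id = c("A", "B"),
                   event_type = c("death", "nephropathy"),
                   event_date = as.Date(c("2014-06-01", "2014-07-01")))
  co <- impute_missing(tiny_cohort(oc))
  sch <- fit_scheme(co)
  tr <- build_trajectories(co, "antiglycemic", sch)
  # A's visit after death (2014-09-01) is dropped -> one terminal pair
  expect_equal(sum(tr$patient_id == "A"), 1L)
  trc <- build_trajectories(co, "antiglycemic", sch,
                            censor_event = "nephropathy")
  # B's 2014-10-01 visit falls after first nephropathy -> one pair left
  expect_equal(sum(trc$patient_id == "B"), 1L)
})

test_that("patient-level split is exact, disjoint and seeded", {
  co <- simulate_cohort(sim_config(n_patients = 10L, visits_range = c(2L, 3L)),
                        seed = 9)
  sp <- split_patients(co, ratio = 0.8, seed = 4)
  ids <- function(x) unique(x$visits$patient_id)
  expect_length(ids(sp$train), 8L)
  expect_length(ids(sp$validation), 2L)
  expect_length(intersect(ids(sp$train), ids(sp$validation)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$validation)), ids(co))
  sp2 <- split_patients(co, ratio = 0.8, seed = 4)
  expect_identical(ids(sp$train), ids(sp2$train))
  co1 <- structure(list(visits = tiny_visit_df()[1:3, ],
                        outcomes = co$outcomes), class = "t2d_cohort")
  expect_error(split_patients(co1, seed = 1), "single")
})
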