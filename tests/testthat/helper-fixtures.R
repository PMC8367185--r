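# Shared fixtures built in code.

# a small deterministic visit table with two patients
tiny_visit_df <- function() {
  data.frame(
    patient_id = rep(c("A", "B"), each = 3),
    visit_date = as.Date(c("2014-01-01", "2014-05-01", "2014-09-01",
                           "2014-02-01", "2014-06-01", "2014-10-01")),
    age = c(60, 60.3, 60.7, 55, 55.3, 55.7),
    gender = rep(c("female", "male"), each = 3),
    ethnicity = c("Chinese", "Chinese", "Chinese", "Malay", "Malay", "Malay"),
    smoker = 0,
    diabetes_duration = c(5, 5.3, 5.7, 12, 12.3, 12.7),
    hba1c = c(8.2, 7.8, 7.1, 9.5, 9.0, 8.4),
    sbp = c(135, 138, 132, 150, 146, 141),
    dbp = c(80, 82, 78, 92, 88, 86),
    ldl_c = c(2.8, 2.5, 2.4, 3.1, 2.9, 2.7),
    tg = c(1.5, 1.6, 1.4, 2.0, 1.9, 1.8),
    bmi = c(26, 26.1, 26.0, 31, 30.8, 30.5),
    egfr = c(85, 84, 83, 55, 52, 50),
    hx_hypertension = c(0, 0, 0, 1, 1, 1),
    hx_hypercholesterolemia = 1,
    hx_mi = 0, hx_heart_failure = 0, hx_stroke = c(0, 0, 0, 1, 1, 1),
    hx_nephropathy = 0, hx_other_micro = 0, hx_hypoglycemia = 0,
    rx_gly = c("metformin:1000", "metformin:1000", "metformin:1000;su:40",
               "metformin:2000", "metformin:2000;basal_insulin:20",
               "metformin:2000;basal_insulin:20"),
    rx_aht = c("", "", "", "A;C", "A;C", "A;C;D"),
    rx_lip = c("statin:20", "statin:20", "statin:20", "", "statin:20",
               "statin:20"),
    stringsAsFactors = FALSE
  )
}

tiny_cohort <- function(outcomes = NULL) {
  oc <- outcomes %||% data.frame(patient_id = character(0),
                                 event_type = character(0),
                                 event_date = as.Date(character(0)))
  structure(list(visits = tiny_visit_df(), outcomes = oc),
            class = "t2d_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a cohort to temp CSVs and return the paths
write_tiny_csv <- function(visits = tiny_visit_df(), outcomes = NULL) {
  vf <- tempfile(fileext = ".csv")
  utils::write.csv(visits, vf, row.names = FALSE)
  of <- NULL
  if (!is.null(outcomes)) {
    of <- tempfile(fileext = ".csv")
    utils::write.csv(outcomes, of, row.names = FALSE)
  }
  list(visit = vf, outcome = of)
}

# a feature scheme fitted on a moderately sized simulated cohort, reused
# across tests (fitting is cheap on a small cohort)
small_sim_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- impute_missing(simulate_cohort(sim_config(n_patients = 60),
                                           seed = 42))
      cache <<- fit_scheme(co)
    }
    cache
  }
})
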