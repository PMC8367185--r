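# Registry-style cohort handling: loading delimited visit/outcome tables,
# the missing-data strategy (last observation carried forward within one
# year, then population median), and construction of per-treatment
# reinforcement-learning trajectories.

# Canonical visit columns; the schema argument of load_registry maps file
# columns onto these.
VISIT_COLUMNS <- c("patient_id", "visit_date", "age", "gender", "ethnicity",
                   "smoker", "diabetes_duration", "hba1c", "sbp", "dbp",
                   "ldl_c", "tg", "bmi", "egfr", HX_FLAGS,
                   "rx_gly", "rx_aht", "rx_lip")
LAB_FIELDS <- c("hba1c", "sbp", "dbp", "ldl_c", "tg", "bmi", "egfr")
NUMERIC_VISIT_FIELDS <- c("age", "smoker", "diabetes_duration", LAB_FIELDS,
                          HX_FLAGS)

new_cohort <- function(visits, outcomes) {
  structure(list(visits = visits, outcomes = outcomes), class = "t2d_cohort")
}

#' @export
print.t2d_cohort <- function(x, ...) {
  cat("<t2d_cohort>", length(unique(x$visits$patient_id)), "patients,",
      nrow(x$visits), "visits,", nrow(x$outcomes), "outcome events\n")
  invisible(x)
}

#' Load registry-style visit and outcome tables
#'
#' Reads two comma-delimited UTF-8 tables with header rows: one row per
#' outpatient visit and one row per dated outcome event. Malformed numeric
#' cells are treated as missing values (the row is retained); visits are
#' sorted by date within patient.
#'
#' @param visit_table path to the visit table (CSV).
#' @param outcome_table path to the outcome table (CSV) with columns
#'   `patient_id`, `event_type`, `event_date`; may be `NULL` for none.
#' @param schema named character vector mapping canonical column names to
#'   file column names, for files whose headers differ from the canonical
#'   schema; `NULL` means headers are already canonical.
#' @return A `t2d_cohort`: list with `visits` (data frame, ordered by
#'   patient and date) and `outcomes` (data frame).
#' @export
load_registry <- function(visit_table, outcome_table = NULL, schema = NULL) {
  visits <- utils::read.csv(visit_table, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!is.null(schema)) {
    hit <- match(unname(schema), names(visits))
    names(visits)[hit[!is.na(hit)]] <- names(schema)[!is.na(hit)]
  }
  missing_cols <- setdiff(c("patient_id", "visit_date"), names(visits))
  if (length(missing_cols)) {
    stop("visit table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(VISIT_COLUMNS, names(visits))) visits[[col]] <- NA
  dates <- as.Date(visits$visit_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(visits$visit_date))
  if (length(bad)) {
    stop("unparseable visit_date at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  visits$visit_date <- dates
  # numeric coercion: parse errors become missing values
  for (col in NUMERIC_VISIT_FIELDS) {
    visits[[col]] <- suppressWarnings(as.numeric(visits[[col]]))
  }
  for (col in LAB_FIELDS) {
    visits[[col]][!is.na(visits[[col]]) & visits[[col]] <= 0] <- NA
  }
  key <- paste(visits$patient_id, visits$visit_date)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, visit_date): ", key[duplicated(key)][1L],
         call. = FALSE)
  }
  visits <- visits[order(visits$patient_id, visits$visit_date), , drop = FALSE]
  rownames(visits) <- NULL
  outcomes <- if (is.null(outcome_table)) {
    data.frame(patient_id = character(0), event_type = character(0),
               event_date = as.Date(character(0)))
  } else {
    oc <- utils::read.csv(outcome_table, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- setdiff(c("patient_id", "event_type", "event_date"), names(oc))
    if (length(need)) stop("outcome table lacks column(s): ",
                           paste(need, collapse = ", "), call. = FALSE)
    oc$event_date <- as.Date(oc$event_date)
    if (any(is.na(oc$event_date))) stop("unparseable event_date",
                                        call. = FALSE)
    dk <- oc$event_type == "death"
    if (any(duplicated(oc$patient_id[dk]))) {
      stop("more than one death event for a patient", call. = FALSE)
    }
    oc
  }
  new_cohort(visits, outcomes)
}

#' Impute missing labs and physical measurements
#'
#' For each missing lab/physical-measurement field, carries forward the
#' closest preceding observation of the same patient within the lookback
#' window (default 1 year); values still missing are imputed with the
#' median of the observed values of that field over all patients. The
#' `imputed_fields` column records, per visit, which fields were filled
#' and from which source (`field=locf` or `field=median`).
#'
#' @param cohort a `t2d_cohort` with ordered visits.
#' @param lookback_days lookback window for carrying forward, in days.
#' @return The cohort with imputed visit fields.
#' @export
impute_missing <- function(cohort, lookback_days = DAYS_PER_YEAR) {
  visits <- cohort$visits
  medians <- lapply(LAB_FIELDS, function(f) {
    x <- visits[[f]][!is.na(visits[[f]])]
    if (!length(x)) stop("field '", f, "' is missing for every patient; ",
                         "no median definable", call. = FALSE)
    stats::median(x)
  })
  names(medians) <- LAB_FIELDS
  imputed <- rep("", nrow(visits))
  pid <- visits$patient_id
  starts <- which(!duplicated(pid))
  ends <- c(starts[-1L] - 1L, nrow(visits))
  for (f in LAB_FIELDS) {
    x <- visits[[f]]
    miss <- is.na(x)
    if (!any(miss)) next
    d <- as.numeric(visits$visit_date)
    for (g in seq_along(starts)) {
      idx <- starts[g]:ends[g]
      xi <- x[idx]
      if (!anyNA(xi)) next
      last_val <- NA_real_; last_day <- -Inf
      for (k in seq_along(idx)) {
        if (is.na(xi[k])) {
          if (!is.na(last_val) && d[idx[k]] - last_day <= lookback_days) {
            xi[k] <- last_val
            imputed[idx[k]] <- paste0(imputed[idx[k]], f, "=locf;")
          } else {
            xi[k] <- medians[[f]]
            imputed[idx[k]] <- paste0(imputed[idx[k]], f, "=median;")
          }
          # carried-forward values are not themselves carry-forward sources
        } else {
          last_val <- xi[k]; last_day <- d[idx[k]]
        }
      }
      x[idx] <- xi
    }
    visits[[f]] <- x
  }
  prev <- cohort$visits$imputed_fields
  visits$imputed_fields <- if (is.null(prev)) imputed else {
    ifelse(nzchar(imputed), paste0(prev, imputed), prev)
  }
  new_cohort(visits, cohort$outcomes)
}

rx_column <- function(treatment_type) {
  switch(treatment_type, antiglycemic = "rx_gly",
         antihypertensive = "rx_aht", lipid_lowering = "rx_lip")
}

# Replace each visit's prescription columns by the previous visit's (within
# patient; the first visit keeps its own). A visit row records the
# prescription *issued at* the visit; the state the recommendation model
# conditions on must carry the drugs in use *before* that decision, so all
# state encodings go through this lag.
lag_rx_within_patient <- function(visits) {
  for (col in c("rx_gly", "rx_aht", "rx_lip")) {
    x <- visits[[col]]
    lagged <- c(x[1], x[-length(x)])
    first <- !duplicated(visits$patient_id)
    lagged[first] <- x[first]
    visits[[col]] <- lagged
  }
  visits
}

patient_events <- function(outcomes, pid, types) {
  outcomes$event_date[outcomes$patient_id == pid &
                        outcomes$event_type %in% types]
}

#' Build reinforcement-learning trajectories for one treatment type
#'
#' Pairs consecutive visits whose spacing lies in the follow-up window
#' (default 3-6 months) into transitions (state, action, reward,
#' next state). The last qualifying pair of each patient is terminal: its
#' reward includes the complication/death term evaluated over the horizon
#' (default 6 years) after the final visit. Visits after a patient's death
#' are dropped; in long-term mode (`censor_event` set) visits after the
#' first occurrence of that complication are dropped as well. Visits
#' lacking the treatment-type prescription record are excluded, and
#' patients with fewer than two qualifying visits contribute nothing.
#'
#' @param cohort an imputed `t2d_cohort`.
#' @param treatment_type treatment type.
#' @param scheme fitted feature scheme used to encode states.
#' @param followup_months numeric length-2: admissible visit spacing, months.
#' @param horizon_years horizon for the terminal complication term.
#' @param censor_event optional complication event type; visits after its
#'   first occurrence are removed (long-term evaluation mode).
#' @param coef reward coefficients, see [reward_coefficients()].
#' @return Object of class `t2d_transitions`: list of parallel fields
#'   `state` (matrix), `action`, `reward`, `next_state` (matrix; `NA` rows
#'   on terminals), `terminal`, `patient_id`, `visit_date`.
#' @export
build_trajectories <- function(cohort, treatment_type, scheme,
                               followup_months = c(3, 6),
                               horizon_years = 6,
                               censor_event = NULL,
                               coef = reward_coefficients()) {
  check_treatment_type(treatment_type)
  visits <- cohort$visits
  outcomes <- cohort$outcomes
  rxcol <- rx_column(treatment_type)
  visits <- visits[!is.na(visits[[rxcol]]), , drop = FALSE]
  win <- months_to_days(followup_months)
  horizon <- years_to_days(horizon_years)
  # states carry the drugs in use before each visit's prescription decision
  enc <- encode_state(lag_rx_within_patient(visits), scheme)
  space <- enumerate_actions(treatment_type)

  rows <- list(); n_out <- 0L
  pid_all <- visits$patient_id
  idx_by_pid <- split(seq_along(pid_all), pid_all)
  oc_by_pid <- split(seq_len(nrow(outcomes)), outcomes$patient_id)
  pevents <- function(pid, types) {
    i <- oc_by_pid[[pid]]
    if (is.null(i)) return(as.Date(character(0)))
    outcomes$event_date[i][outcomes$event_type[i] %in% types]
  }
  for (pid in names(idx_by_pid)) {
    idx <- idx_by_pid[[pid]]
    pv <- visits[idx, , drop = FALSE]
    death <- pevents(pid, "death")
    if (length(death)) {
      keep <- pv$visit_date <= min(death)
      pv <- pv[keep, , drop = FALSE]; idx <- idx[keep]
    }
    if (!is.null(censor_event)) {
      ev <- pevents(pid, censor_event)
      if (length(ev)) {
        keep <- pv$visit_date <= min(ev)
        pv <- pv[keep, , drop = FALSE]; idx <- idx[keep]
      }
    }
    if (nrow(pv) < 2L) next
    gaps <- as.numeric(diff(pv$visit_date))
    ok <- which(gaps >= win[1] & gaps <= win[2])
    if (!length(ok)) next
    cx_events <- pevents(pid, c(COMPLICATION_EVENTS, "death"))
    hypo_events <- pevents(pid, "hypoglycemia_admission")
    rx <- lapply(pv[[rxcol]], parse_rx, treatment_type = treatment_type)
    last_pair <- ok[length(ok)]
    for (i in ok) {
      j <- i + 1L
      prev_rx <- if (i == 1L) rx[[1L]] else rx[[i - 1L]]
      act <- infer_action(prev_rx, rx[[i]], treatment_type)
      is_final <- as.integer(i == last_pair)
      cx_sign <- -1L
      if (is_final == 1L && length(cx_events)) {
        hit <- cx_events > pv$visit_date[j] - 1 &
          cx_events <= pv$visit_date[j] + horizon
        if (any(hit)) cx_sign <- 1L
      }
      hypo <- as.integer(any(hypo_events > pv$visit_date[i] &
                               hypo_events <= pv$visit_date[j]))
      r <- reward(treatment_type,
                  list(next_hba1c = pv$hba1c[j], next_sbp = pv$sbp[j],
                       next_dbp = pv$dbp[j], next_ldl = pv$ldl_c[j],
                       hypo_before_next = hypo, is_final = is_final,
                       cx_sign = cx_sign),
                  coef)
      n_out <- n_out + 1L
      rows[[n_out]] <- list(si = idx[i], sj = if (is_final) NA_integer_ else idx[j],
                            action = act, reward = r,
                            terminal = is_final == 1L,
                            patient_id = pid, visit_date = pv$visit_date[i])
    }
  }
  if (!n_out) {
    warning("no transitions produced for ", treatment_type, call. = FALSE)
  }
  si <- vapply(rows, `[[`, integer(1), "si")
  sj <- vapply(rows, `[[`, integer(1), "sj")
  next_state <- matrix(NA_real_, n_out, ncol(enc),
                       dimnames = list(NULL, colnames(enc)))
  if (n_out) next_state[!is.na(sj), ] <- enc[sj[!is.na(sj)], , drop = FALSE]
  structure(list(
    state = enc[si, , drop = FALSE],
    action = vapply(rows, `[[`, integer(1), "action"),
    reward = vapply(rows, `[[`, numeric(1), "reward"),
    next_state = next_state,
    terminal = vapply(rows, `[[`, logical(1), "terminal"),
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    visit_date = as.Date(vapply(rows, function(r) as.numeric(r$visit_date),
                                numeric(1)), origin = "1970-01-01"),
    treatment_type = treatment_type, arity = space$arity
  ), class = "t2d_transitions")
}

#' @export
print.t2d_transitions <- function(x, ...) {
  cat("<t2d_transitions>", length(x$action), "transitions (",
      sum(x$terminal), "terminal ),", x$treatment_type, "\n")
  invisible(x)
}

#' @export
as.data.frame.t2d_transitions <- function(x, ...) {
  st <- as.data.frame(x$state)
  names(st) <- paste0("s_", names(st))
  ns <- as.data.frame(x$next_state)
  names(ns) <- paste0("ns_", names(ns))
  cbind(data.frame(patient_id = x$patient_id,
                   visit_date = x$visit_date,
                   action = x$action, reward = x$reward,
                   terminal = x$terminal), st, ns)
}

#' Split a cohort at the patient level
#'
#' @param cohort a `t2d_cohort`.
#' @param ratio fraction of patients assigned to the training split.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return List with `train` and `validation` cohorts (disjoint patients).
#' @export
split_patients <- function(cohort, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  ids <- unique(cohort$visits$patient_id)
  if (length(ids) < 2L) stop("cannot split a single-patient cohort",
                             call. = FALSE)
  n_train <- max(1L, min(length(ids) - 1L, floor(length(ids) * ratio)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_ids <- sample(ids, n_train)
  subset_cohort <- function(keep) {
    new_cohort(cohort$visits[cohort$visits$patient_id %in% keep, , drop = FALSE],
               cohort$outcomes[cohort$outcomes$patient_id %in% keep, , drop = FALSE])
  }
  list(train = subset_cohort(train_ids),
       validation = subset_cohort(setdiff(ids, train_ids)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
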