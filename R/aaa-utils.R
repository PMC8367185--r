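# Shared constants and small helpers.

# Days per month used for all interval arithmetic (Gregorian mean month).
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

months_to_days <- function(m) m * DAYS_PER_MONTH
years_to_days <- function(y) y * DAYS_PER_YEAR

TREATMENT_TYPES <- c("antiglycemic", "antihypertensive", "lipid_lowering")

#' @keywords internal
check_treatment_type <- function(treatment_type) {
  if (!is.character(treatment_type) || length(treatment_type) != 1L ||
      !treatment_type %in% TREATMENT_TYPES) {
    stop("unknown treatment_type; must be one of: ",
         paste(TREATMENT_TYPES, collapse = ", "), call. = FALSE)
  }
  treatment_type
}

# Event types recorded in the outcome table.
COMPLICATION_EVENTS <- c("myocardial_infarction", "heart_failure", "stroke",
                         "nephropathy", "other_microvascular")
EVENT_TYPES <- c("hypoglycemia_admission", COMPLICATION_EVENTS, "death")

`%||%` <- function(a, b) if (is.null(a)) b else a

# medical-history flag columns of the canonical visit schema
HX_FLAGS <- c("hx_hypertension", "hx_hypercholesterolemia", "hx_mi",
              "hx_heart_failure", "hx_stroke", "hx_nephropathy",
              "hx_other_micro", "hx_hypoglycemia")
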