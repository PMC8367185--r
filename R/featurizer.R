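# State encoding: a PatientVisit row -> fixed-length numeric vector.
#
# The default scheme spans demographics, medical history, rule-derived
# disease risks, current drugs by class, and labs/physical measurements,
# for a total encoded width of 49. Continuous features are min-max scaled
# to [0,1] with bounds fitted on training-data percentiles (0.5th/99.5th)
# and clipped; binary features are 0/1; ethnicity is one-hot with an
# explicit "Other" level.

ETHNICITY_LEVELS <- c("Chinese", "Malay", "Indian", "Other")

CONTINUOUS_FEATURES <- c("age", "diabetes_duration", "hba1c", "sbp", "dbp",
                         "ldl_c", "tg", "bmi", "egfr", "n_oad")

DRUG_FLAG_CLASSES <- list(
  antiglycemic = GLY_CLASSES,
  antihypertensive = AHT_CLASSES,
  lipid_lowering = LIP_CLASSES
)

# rule-derived risk indicators
RISK_FLAGS <- c("risk_egfr_lt60", "risk_egfr_lt30", "risk_prior_hypo",
                "risk_macrovascular", "risk_microvascular",
                "risk_hba1c_gt9", "risk_bp_uncontrolled", "risk_ldl_high")

# Derive the full feature frame (one row per visit) from canonical visit
# columns; prescriptions are expanded to per-class indicators.
visit_feature_frame <- function(visits) {
  rx_flags <- lapply(names(DRUG_FLAG_CLASSES), function(tt) {
    col <- switch(tt, antiglycemic = "rx_gly", antihypertensive = "rx_aht",
                  lipid_lowering = "rx_lip")
    cls_list <- lapply(visits[[col]], rx_class_vec, treatment_type = tt)
    out <- sapply(DRUG_FLAG_CLASSES[[tt]], function(cl)
      vapply(cls_list, function(x) as.integer(cl %in% x), integer(1)))
    out <- matrix(out, nrow = nrow(visits),
                  dimnames = list(NULL, paste0("drug_", DRUG_FLAG_CLASSES[[tt]])))
    out
  })
  rx_flags <- do.call(cbind, rx_flags)
  n_oad <- rowSums(rx_flags[, paste0("drug_", OAD_CLASSES), drop = FALSE])
  data.frame(
    age = visits$age,
    gender_female = as.integer(visits$gender %in% c("female", "F", "1", 1)),
    ethnicity = ifelse(visits$ethnicity %in% ETHNICITY_LEVELS,
                       visits$ethnicity, "Other"),
    smoker = as.integer(visits$smoker > 0),
    diabetes_duration = visits$diabetes_duration,
    hba1c = visits$hba1c, sbp = visits$sbp, dbp = visits$dbp,
    ldl_c = visits$ldl_c, tg = visits$tg, bmi = visits$bmi,
    egfr = visits$egfr,
    visits[HX_FLAGS],
    risk_egfr_lt60 = as.integer(visits$egfr < 60),
    risk_egfr_lt30 = as.integer(visits$egfr < 30),
    risk_prior_hypo = as.integer(visits$hx_hypoglycemia > 0),
    risk_macrovascular = as.integer(visits$hx_mi | visits$hx_heart_failure |
                                      visits$hx_stroke),
    risk_microvascular = as.integer(visits$hx_nephropathy |
                                      visits$hx_other_micro),
    risk_hba1c_gt9 = as.integer(visits$hba1c > 9),
    risk_bp_uncontrolled = as.integer(visits$sbp >= 140 | visits$dbp >= 90),
    risk_ldl_high = as.integer(visits$ldl_c >= 2.6),
    rx_flags,
    n_oad = n_oad,
    stringsAsFactors = FALSE
  )
}

#' Fit the state-encoding scheme on a training cohort
#'
#' Fixes the feature order and fits per-continuous-feature normalization
#' bounds as the 0.5th/99.5th percentiles of the (imputed) training data.
#'
#' @param cohort a `t2d_cohort` (see [load_registry()]), imputed.
#' @return Object of class `t2d_feature_scheme`; its `width` is 49.
#' @export
fit_scheme <- function(cohort) {
  visits <- if (inherits(cohort, "t2d_cohort")) cohort$visits else cohort
  if (is.null(visits) || nrow(visits) == 0L) {
    stop("cannot fit a feature scheme on an empty cohort", call. = FALSE)
  }
  ff <- visit_feature_frame(visits)
  bounds <- lapply(CONTINUOUS_FEATURES, function(f) {
    x <- ff[[f]][!is.na(ff[[f]])]
    if (!length(x)) stop("feature '", f, "' has no observed values",
                         call. = FALSE)
    q <- unname(stats::quantile(x, c(0.005, 0.995), type = 7))
    if (q[1] >= q[2]) {
      stop("degenerate normalization bounds for constant feature '", f, "'",
           call. = FALSE)
    }
    q
  })
  names(bounds) <- CONTINUOUS_FEATURES
  binary <- setdiff(names(ff), c(CONTINUOUS_FEATURES, "ethnicity"))
  feature_names <- c(
    "age", "gender_female", paste0("ethnicity_", ETHNICITY_LEVELS), "smoker",
    "diabetes_duration", HX_FLAGS, RISK_FLAGS,
    paste0("drug_", unlist(DRUG_FLAG_CLASSES, use.names = FALSE)),
    "hba1c", "sbp", "dbp", "ldl_c", "tg", "bmi", "egfr", "n_oad")
  scheme <- structure(list(bounds = bounds, binary = binary,
                           feature_names = feature_names,
                           width = length(feature_names)),
                      class = "t2d_feature_scheme")
  stopifnot(scheme$width == 49L)
  scheme
}

#' @export
print.t2d_feature_scheme <- function(x, ...) {
  cat("<t2d_feature_scheme> width", x$width, "(",
      length(x$bounds), "continuous,", length(x$binary), "binary, 1 one-hot",
      ")\n")
  invisible(x)
}

scale01 <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))

#' Encode visits into state vectors
#'
#' @param visits a visit data frame (canonical columns) or a `t2d_cohort`.
#' @param scheme a fitted [fit_scheme()] object.
#' @return Numeric matrix, one row per visit, `scheme$width` (= 49) columns.
#' @export
encode_state <- function(visits, scheme) {
  if (inherits(visits, "t2d_cohort")) visits <- visits$visits
  ff <- visit_feature_frame(visits)
  n <- nrow(ff)
  out <- matrix(0, n, scheme$width,
                dimnames = list(NULL, scheme$feature_names))
  for (f in names(scheme$bounds)) {
    if (any(is.na(ff[[f]]))) {
      stop("encode_state: missing values in '", f,
           "'; impute the cohort first", call. = FALSE)
    }
    out[, f] <- scale01(ff[[f]], scheme$bounds[[f]][1], scheme$bounds[[f]][2])
  }
  for (f in scheme$binary) out[, f] <- ff[[f]]
  for (lev in ETHNICITY_LEVELS) {
    out[, paste0("ethnicity_", lev)] <- as.integer(ff$ethnicity == lev)
  }
  out
}
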