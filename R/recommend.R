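# Knowledge + data "two-wheel drive" recommendation: a declarative rule
# engine first restricts the action set (renal dosing, contraindications),
# then the Q-network ranks the admissible actions.

#' Declare a knowledge rule
#'
#' A rule fires when `field <op> threshold` holds at the visit (and, if
#' `requires_class` is given, that drug class is in the current
#' prescription of the rule's treatment type). A firing rule forbids
#' and/or force-includes action indices.
#'
#' @param id short identifier.
#' @param treatment_type treatment type the rule applies to.
#' @param field visit column compared (e.g. `"egfr"`).
#' @param op one of `"<"`, `"<="`, `">"`, `">="`.
#' @param threshold numeric comparison value.
#' @param forbid,force integer vectors of 0-based action indices.
#' @param requires_class optional drug class that must be currently
#'   prescribed for the rule to fire.
#' @param note free-text provenance note.
#' @return List of class `t2d_knowledge_rule`.
#' @export
knowledge_rule <- function(id, treatment_type, field, op, threshold,
                           forbid = integer(0), force = integer(0),
                           requires_class = NULL, note = "") {
  check_treatment_type(treatment_type)
  stopifnot(op %in% c("<", "<=", ">", ">="))
  arity <- enumerate_actions(treatment_type)$arity
  if (any(c(forbid, force) < 0L) || any(c(forbid, force) >= arity)) {
    stop("rule references action indices outside [0, ", arity - 1L, "]",
         call. = FALSE)
  }
  structure(list(id = id, treatment_type = treatment_type, field = field,
                 op = op, threshold = threshold,
                 forbid = as.integer(forbid), force = as.integer(force),
                 requires_class = requires_class, note = note),
            class = "t2d_knowledge_rule")
}

#' Default knowledge rules
#'
#' The shipped set encodes the renal metformin rules: with eGFR below 45
#' the metformin dose must not be increased and metformin must not be
#' started; below 30 metformin is discontinued, leaving only the
#' insulin-switch actions for patients on metformin.
#'
#' @return List of `t2d_knowledge_rule`s.
#' @export
default_rules <- function() {
  list(
    knowledge_rule("metformin_no_uptitrate_egfr45", "antiglycemic",
                   "egfr", "<", 45, forbid = 1L,
                   requires_class = "metformin",
                   note = "no metformin dose increase when eGFR < 45"),
    knowledge_rule("metformin_no_start_egfr45", "antiglycemic",
                   "egfr", "<", 45, forbid = 5L,
                   note = "do not start metformin when eGFR < 45"),
    knowledge_rule("metformin_stop_egfr30", "antiglycemic",
                   "egfr", "<", 30, forbid = 0:9,
                   requires_class = "metformin",
                   note = "discontinue metformin when eGFR < 30")
  )
}

rule_fires <- function(rule, visit) {
  val <- visit[[rule$field]]
  if (is.null(val) || is.na(val)) return(FALSE)
  hit <- switch(rule$op,
                "<" = val < rule$threshold, "<=" = val <= rule$threshold,
                ">" = val > rule$threshold, ">=" = val >= rule$threshold)
  if (hit && !is.null(rule$requires_class)) {
    rx <- parse_rx(visit[[rx_column(rule$treatment_type)]],
                   rule$treatment_type)
    hit <- rule$requires_class %in% rx_classes(rx)
  }
  isTRUE(hit)
}

#' Admissible actions at a visit
#'
#' Starts from the full action set and applies every firing rule's
#' forbid/force effects; forbidding and force-including the same index is
#' a configuration error.
#'
#' @param visit one visit row (data frame row or named list).
#' @param treatment_type treatment type.
#' @param rules list of [knowledge_rule()]s (default [default_rules()]).
#' @return Sorted integer vector of admissible 0-based action indices.
#' @export
knowledge_filter <- function(visit, treatment_type,
                             rules = default_rules()) {
  check_treatment_type(treatment_type)
  arity <- enumerate_actions(treatment_type)$arity
  rules <- Filter(function(r) r$treatment_type == treatment_type, rules)
  forbidden <- integer(0); forced <- integer(0)
  for (r in rules) {
    if (rule_fires(r, visit)) {
      forbidden <- union(forbidden, r$forbid)
      forced <- union(forced, r$force)
    }
  }
  clash <- intersect(forbidden, forced)
  if (length(clash)) {
    stop("contradictory rules: action(s) ", paste(clash, collapse = ", "),
         " both forbidden and forced", call. = FALSE)
  }
  sort(union(setdiff(seq_len(arity) - 1L, forbidden), forced))
}

#' Rank treatment actions for a visit
#'
#' Encodes the visit, computes Q-values over all actions, restricts to the
#' admissible set from [knowledge_filter()], and returns the top `k`
#' actions by Q (ties broken toward the lower action index). If every
#' action is forbidden the recommendation falls back to action 0 (no
#' change / no drugs) with a warning.
#'
#' @param visit one visit row; its prescription columns are read as the
#'   drugs currently in use (the regimen in effect before this decision).
#'   For registry tables whose rows record the prescription issued at the
#'   visit, use [recommend_visits()], which lags them internally.
#' @param model trained `t2d_qmodel` (or a list of them; Q-values are
#'   averaged).
#' @param scheme fitted feature scheme.
#' @param treatment_type treatment type.
#' @param rules knowledge rules.
#' @param k number of candidates to return.
#' @return List of class `t2d_recommendation`: `candidates` data frame
#'   (`action`, `label`, `q_value`), `top1`, `treatment_type`.
#' @export
recommend <- function(visit, model, scheme, treatment_type,
                      rules = default_rules(), k = 3L) {
  space <- enumerate_actions(treatment_type)
  q <- as.vector(q_values(model, encode_state(as.data.frame(visit), scheme)))
  admissible <- knowledge_filter(visit, treatment_type, rules)
  if (length(admissible) == 0L) {
    warning("all actions forbidden; falling back to action 0", call. = FALSE)
    admissible <- 0L
  }
  ord <- admissible[order(-q[admissible + 1L], admissible)]
  top <- utils::head(ord, k)
  structure(list(
    candidates = data.frame(action = top, label = space$labels[top + 1L],
                            q_value = q[top + 1L]),
    top1 = top[1L], treatment_type = treatment_type,
    admissible = admissible), class = "t2d_recommendation")
}

#' @export
print.t2d_recommendation <- function(x, ...) {
  cat("<t2d_recommendation>", x$treatment_type, "\n")
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Model concordance of an actual prescription pair
#'
#' TRUE iff the action inferred from the physician's consecutive
#' prescriptions equals the model's top-ranked action. Concordance is at
#' drug-class level, so brand names mapping to the same class are
#' equivalent. Returns `NA` when the actual action is uninferable
#' (excluded sample), never a silent FALSE.
#'
#' @param recommendation a [recommend()] result (or a bare action index).
#' @param prev,cur the actual consecutive `t2d_prescription`s.
#' @return logical (or `NA`).
#' @export
concordance <- function(recommendation, prev, cur) {
  top1 <- if (inherits(recommendation, "t2d_recommendation")) {
    recommendation$top1
  } else as.integer(recommendation)
  tt <- if (inherits(recommendation, "t2d_recommendation")) {
    recommendation$treatment_type
  } else prev$treatment_type
  actual <- tryCatch(infer_action(prev, cur, tt), error = function(e) NA_integer_)
  if (is.na(actual)) return(NA)
  identical(as.integer(actual), as.integer(top1))
}

#' Batch recommendations over a visit table
#'
#' @param visits visit data frame (canonical columns, imputed).
#' @param model,scheme,treatment_type,rules,k as in [recommend()].
#' @return Data frame: `patient_id`, `visit_date`, `action` (top-1),
#'   `label`, `q_value`.
#' @export
recommend_visits <- function(visits, model, scheme, treatment_type,
                             rules = default_rules(), k = 1L) {
  if (inherits(visits, "t2d_cohort")) visits <- visits$visits
  # registry rows record the prescription issued at the visit; condition
  # the model (and the rules) on the drugs in use before that decision
  lagged <- lag_rx_within_patient(visits)
  enc <- encode_state(lagged, scheme)
  q <- q_values(model, enc)
  space <- enumerate_actions(treatment_type)
  top <- integer(nrow(visits))
  for (i in seq_len(nrow(visits))) {
    admissible <- knowledge_filter(lagged[i, ], treatment_type, rules)
    if (length(admissible) == 0L) admissible <- 0L
    qi <- q[i, admissible + 1L]
    top[i] <- admissible[order(-qi, admissible)][1L]
  }
  data.frame(patient_id = visits$patient_id, visit_date = visits$visit_date,
             action = top, label = space$labels[top + 1L],
             q_value = q[cbind(seq_len(nrow(visits)), top + 1L)])
}
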