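# Clinical reward functions for the three treatment types.
#
# Each transition's reward scores the *next* visit: did the biomarker reach
# its control target, did a severe hypoglycemia admission occur in between
# (antiglycemic only), and -- on a patient's final visit -- did any
# complication or death occur over the long-term horizon.

#' Default reward coefficients and control targets
#'
#' Coefficients weight the three reward components: `a` the biomarker
#' control term, `b` the hypoglycemia penalty (antiglycemic only), `c` the
#' terminal complication/death term. Control targets are the standard
#' therapeutic goals: HbA1c < 7 %, SBP/DBP < 140/90 mmHg, LDL-c < 2.6 mmol/L.
#'
#' @param a weight of the control term (default 1).
#' @param b weight of the hypoglycemia penalty (default 2).
#' @param c_ weight of the terminal complication term (default 4).
#' @param hba1c_target glycemic target in percent (default 7).
#' @param sbp_target,dbp_target blood-pressure targets in mmHg (140/90).
#' @param ldl_target LDL-c target in mmol/L (default 2.6).
#' @return A list of class `t2d_reward_coef`.
#' @export
reward_coefficients <- function(a = 1, b = 2, c_ = 4,
                                hba1c_target = 7,
                                sbp_target = 140, dbp_target = 90,
                                ldl_target = 2.6) {
  stopifnot(a > 0, b > 0, c_ > 0)
  structure(list(a = a, b = b, c = c_,
                 hba1c_target = hba1c_target,
                 sbp_target = sbp_target, dbp_target = dbp_target,
                 ldl_target = ldl_target),
            class = "t2d_reward_coef")
}

#' Strict sign function
#'
#' Returns +1 for strictly positive arguments and -1 otherwise, so that a
#' biomarker sitting exactly on its target counts as uncontrolled (the
#' control goals are strict inequalities, e.g. HbA1c < 7 %).
#'
#' @param x numeric vector, finite.
#' @return integer vector of +1 / -1.
#' @export
sgn <- function(x) {
  if (any(!is.finite(x))) stop("sgn: non-finite input", call. = FALSE)
  ifelse(x > 0, 1L, -1L)
}

check_reward_field <- function(value, name) {
  if (is.null(value) || length(value) == 0L || any(is.na(value))) {
    stop("reward: required field '", name, "' is missing", call. = FALSE)
  }
  value
}

#' Per-transition reward
#'
#' Computes the reward of a transition from next-visit outcomes. All
#' arguments are vectorized.
#'
#' For antiglycemic treatment:
#' `a * sgn(target - HbA1c') - b * Hypo - c * Final * CX`,
#' where `Hypo` is 1 if a severe hypoglycemia admission occurred before the
#' next visit, `Final` is 1 on a patient's last visit, and `CX` is +1 if any
#' complication or death occurred over the horizon, -1 otherwise (its term
#' contributes 0 on non-final visits). Blood pressure uses a joint control
#' term (+a iff SBP < 140 and DBP < 90, else -a) and the same terminal term;
#' lipid-lowering uses `a * sgn(2.6 - LDL')` and the terminal term.
#'
#' @param treatment_type one of `"antiglycemic"`, `"antihypertensive"`,
#'   `"lipid_lowering"`.
#' @param inputs list with the fields the treatment type needs:
#'   `next_hba1c`, `hypo_before_next` (0/1) for antiglycemic; `next_sbp`,
#'   `next_dbp` for antihypertensive; `next_ldl` for lipid-lowering; and
#'   always `is_final` (0/1) and `cx_sign` (-1/+1).
#' @param coef a [reward_coefficients()] object.
#' @return numeric vector of rewards.
#' @export
reward <- function(treatment_type, inputs, coef = reward_coefficients()) {
  check_treatment_type(treatment_type)
  final <- check_reward_field(inputs$is_final, "is_final")
  cx <- inputs$cx_sign
  # cx only matters on final visits; allow it absent/NA there
  cx <- ifelse(final == 0, -1L, cx)
  check_reward_field(cx, "cx_sign")
  if (!all(cx %in% c(-1L, 1L))) stop("cx_sign must be -1 or +1", call. = FALSE)
  terminal_term <- -coef$c * final * cx
  switch(treatment_type,
    antiglycemic = {
      hba1c <- check_reward_field(inputs$next_hba1c, "next_hba1c")
      hypo <- check_reward_field(inputs$hypo_before_next, "hypo_before_next")
      coef$a * sgn(coef$hba1c_target - hba1c) - coef$b * hypo + terminal_term
    },
    antihypertensive = {
      sbp <- check_reward_field(inputs$next_sbp, "next_sbp")
      dbp <- check_reward_field(inputs$next_dbp, "next_dbp")
      controlled <- (sbp < coef$sbp_target) & (dbp < coef$dbp_target)
      coef$a * ifelse(controlled, 1, -1) + terminal_term
    },
    lipid_lowering = {
      ldl <- check_reward_field(inputs$next_ldl, "next_ldl")
      coef$a * sgn(coef$ldl_target - ldl) + terminal_term
    }
  )
}
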