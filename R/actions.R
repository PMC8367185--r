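# Canonical action spaces for the three treatment types, action inference
# from consecutive prescriptions, and action application.
#
# Antiglycemic actions are *changes* relative to the previous prescription
# (delta semantics); antihypertensive and lipid-lowering actions name the
# drug-class subset currently in use (regimen-subset semantics). Action
# indices are 0-based to match the canonical tables.

OAD_CLASSES <- c("agi", "dpp4", "metformin", "sglt2", "su", "tzd", "glp1")
INSULIN_CLASSES <- c("basal_insulin", "prandial_insulin", "premix_insulin")
GLY_CLASSES <- c(OAD_CLASSES, INSULIN_CLASSES)
AHT_CLASSES <- c("A", "B", "C", "D")
LIP_CLASSES <- c("statin", "fibrate", "ezetimibe")

# Table 1 row order: the "Adding <OAD>" block is alphabetical by class name.
GLY_ACTION_LABELS <- c(
  "No prescription change",                          # 0
  "Increase drug dosage",                            # 1
  "Decrease drug dosage",                            # 2
  "Adding alpha-glucosidase inhibitor",              # 3
  "Adding dipeptidyl peptidase-4 inhibitor",         # 4
  "Adding metformin",                                # 5
  "Adding sodium glucose cotransporter-2 inhibitor", # 6
  "Adding sulfonylurea",                             # 7
  "Adding thiazolidinedione",                        # 8
  "Adding glucagon-like peptide-1 receptor agonist", # 9
  "Using basal insulin",                             # 10
  "Using premix insulin",                            # 11
  "Using basal and prandial insulins"                # 12
)
# index of "Adding <class>" per OAD class (table order)
GLY_ADD_INDEX <- c(agi = 3L, dpp4 = 4L, metformin = 5L, sglt2 = 6L,
                   su = 7L, tzd = 8L, glp1 = 9L)
# insulin regimen named by each "Using ..." action
GLY_INSULIN_REGIMENS <- list(
  `10` = "basal_insulin",
  `11` = "premix_insulin",
  `12` = c("basal_insulin", "prandial_insulin")
)

# Printed row order: singletons, pairs, triples, full set.
AHT_SUBSETS <- list(
  character(0), "A", "B", "C", "D",
  c("A", "B"), c("A", "C"), c("A", "D"), c("B", "C"), c("B", "D"),
  c("C", "D"), c("A", "B", "C"), c("A", "B", "D"), c("A", "C", "D"),
  c("B", "C", "D"), c("A", "B", "C", "D")
)
LIP_SUBSETS <- list(
  character(0), "statin", "fibrate", "ezetimibe",
  c("statin", "fibrate"), c("statin", "ezetimibe"),
  c("fibrate", "ezetimibe"), c("statin", "fibrate", "ezetimibe")
)

subset_label <- function(classes, none = "No drugs") {
  if (length(classes) == 0L) return(none)
  paste("Using", paste(classes, collapse = " and "))
}

#' Canonical action space of a treatment type
#'
#' Antiglycemic treatment has 13 prescription-change actions (no change,
#' dose up/down of metformin/basal/premixed insulin, adding one of seven
#' OAD classes, or switching to one of three insulin regimens).
#' Antihypertensive treatment enumerates all 16 subsets of the classes
#' A (ACE inhibitor / ARB), B (beta blocker), C (calcium channel blocker),
#' D (diuretic); lipid-lowering all 8 subsets of statin/fibrate/ezetimibe.
#'
#' @param treatment_type one of the three treatment types.
#' @return An object of class `t2d_action_space` with elements
#'   `treatment_type`, `labels`, `arity` and `semantics`
#'   (`"delta"` or `"regimen_subset"`).
#' @export
enumerate_actions <- function(treatment_type) {
  check_treatment_type(treatment_type)
  out <- switch(treatment_type,
    antiglycemic = list(labels = GLY_ACTION_LABELS, semantics = "delta",
                        subsets = NULL),
    antihypertensive = list(
      labels = vapply(AHT_SUBSETS, subset_label, character(1)),
      semantics = "regimen_subset", subsets = AHT_SUBSETS),
    lipid_lowering = list(
      labels = vapply(LIP_SUBSETS, subset_label, character(1)),
      semantics = "regimen_subset", subsets = LIP_SUBSETS)
  )
  structure(list(treatment_type = treatment_type, labels = out$labels,
                 arity = length(out$labels), semantics = out$semantics,
                 subsets = out$subsets),
            class = "t2d_action_space")
}

#' @export
print.t2d_action_space <- function(x, ...) {
  cat("<t2d_action_space> ", x$treatment_type, " (", x$semantics, "), arity ",
      x$arity, "\n", sep = "")
  for (i in seq_along(x$labels)) cat(sprintf("%3d  %s\n", i - 1L, x$labels[i]))
  invisible(x)
}

# ---- prescriptions ---------------------------------------------------------

# A small brand/generic-name lexicon; concordance is defined at drug-class
# level so any name mapping to the same class is equivalent.
DRUG_NAME_CLASS <- c(
  acarbose = "agi", voglibose = "agi",
  sitagliptin = "dpp4", linagliptin = "dpp4", vildagliptin = "dpp4",
  glucophage = "metformin",
  empagliflozin = "sglt2", dapagliflozin = "sglt2", canagliflozin = "sglt2",
  glipizide = "su", gliclazide = "su", glibenclamide = "su",
  pioglitazone = "tzd", rosiglitazone = "tzd",
  liraglutide = "glp1", dulaglutide = "glp1", semaglutide = "glp1",
  glargine = "basal_insulin", detemir = "basal_insulin",
  degludec = "basal_insulin",
  aspart = "prandial_insulin", lispro = "prandial_insulin",
  mixtard = "premix_insulin", novomix = "premix_insulin",
  enalapril = "A", lisinopril = "A", losartan = "A", valsartan = "A",
  atenolol = "B", bisoprolol = "B", carvedilol = "B",
  amlodipine = "C", nifedipine = "C",
  hydrochlorothiazide = "D", frusemide = "D", indapamide = "D",
  atorvastatin = "statin", simvastatin = "statin", rosuvastatin = "statin",
  fenofibrate = "fibrate", gemfibrozil = "fibrate"
)

treatment_classes <- function(treatment_type) {
  switch(treatment_type,
         antiglycemic = GLY_CLASSES,
         antihypertensive = AHT_CLASSES,
         lipid_lowering = LIP_CLASSES)
}

#' Construct a prescription
#'
#' @param treatment_type treatment type of the prescription.
#' @param classes character vector of drug classes (or known drug names,
#'   which are mapped to their class).
#' @param doses numeric daily doses, recycled; `NA` means unrecorded.
#' @return Object of class `t2d_prescription`: list with `treatment_type`
#'   and an `items` data frame (`drug_class`, `drug_name`, `daily_dose`).
#' @export
prescription <- function(treatment_type, classes = character(0), doses = NA_real_) {
  check_treatment_type(treatment_type)
  vocab <- treatment_classes(treatment_type)
  names_in <- classes
  cls <- ifelse(classes %in% vocab, classes,
                unname(DRUG_NAME_CLASS[tolower(classes)]))
  if (length(cls) && any(is.na(cls) | !cls %in% vocab)) {
    bad <- names_in[is.na(cls) | !cls %in% vocab]
    stop("unrecognized drug class/name for ", treatment_type, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cls)) stop("duplicate drug class in prescription",
                               call. = FALSE)
  doses <- rep_len(as.numeric(doses), length(cls))
  if (any(!is.na(doses) & doses < 0)) stop("daily_dose must be non-negative",
                                           call. = FALSE)
  items <- structure(list(drug_class = as.character(cls),
                          drug_name = as.character(names_in),
                          daily_dose = doses),
                     class = "data.frame",
                     row.names = seq_along(cls))
  structure(list(treatment_type = treatment_type, items = items),
            class = "t2d_prescription")
}

rx_classes <- function(rx) rx$items$drug_class

# fast path: drug classes of a prescription string, skipping object
# construction (used when encoding whole visit tables)
rx_class_vec <- function(string, treatment_type) {
  if (is.na(string) || !nzchar(string)) return(character(0))
  cls <- sub(":.*$", "", strsplit(string, ";", fixed = TRUE)[[1]])
  vocab <- treatment_classes(treatment_type)
  out <- ifelse(cls %in% vocab, cls, unname(DRUG_NAME_CLASS[tolower(cls)]))
  if (any(is.na(out))) {
    stop("unrecognized drug class/name: ",
         paste(cls[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

rx_dose <- function(rx, class) {
  i <- match(class, rx$items$drug_class)
  if (is.na(i)) NA_real_ else rx$items$daily_dose[i]
}

#' Serialize / parse prescriptions for delimited tables
#'
#' The text codec is `class:dose` items joined by `;` (dose optional), e.g.
#' `"metformin:1000;su:40"` or `"A;C"`. An empty string is an empty
#' prescription ("no drugs"); drug names from the built-in lexicon are
#' accepted and mapped to their class.
#'
#' @param rx a `t2d_prescription`.
#' @return `format_rx()` a single string; `parse_rx()` a `t2d_prescription`.
#' @export
format_rx <- function(rx) {
  it <- rx$items
  if (nrow(it) == 0L) return("")
  paste(ifelse(is.na(it$daily_dose), it$drug_class,
               paste0(it$drug_class, ":", it$daily_dose)), collapse = ";")
}

#' @rdname format_rx
#' @param string prescription string.
#' @param treatment_type treatment type the string encodes.
#' @export
parse_rx <- function(string, treatment_type) {
  if (is.na(string) || !nzchar(string)) {
    return(prescription(treatment_type))
  }
  parts <- strsplit(strsplit(string, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  classes <- vapply(parts, `[`, character(1), 1L)
  doses <- vapply(parts, function(p) {
    if (length(p) > 1L) suppressWarnings(as.numeric(p[2L])) else NA_real_
  }, numeric(1))
  prescription(treatment_type, classes, doses)
}

# ---- inference -------------------------------------------------------------

# Map an insulin-class set to the "Using ..." action index it names, or NA.
INSULIN_REGIMEN_SIG <- c("basal_insulin" = 10L, "premix_insulin" = 11L,
                         "basal_insulin+prandial_insulin" = 12L)
insulin_regimen_index <- function(classes) {
  ins <- classes[classes %in% INSULIN_CLASSES]
  if (!length(ins)) return(NA_integer_)
  idx <- INSULIN_REGIMEN_SIG[paste(sort.int(ins), collapse = "+")]
  if (is.na(idx)) NA_integer_ else unname(idx)
}

# precomputed canonical subset signatures for regimen-subset inference
AHT_SUBSET_SIG <- vapply(AHT_SUBSETS,
                         function(s) paste(sort.int(s), collapse = "+"),
                         character(1))
LIP_SUBSET_SIG <- vapply(LIP_SUBSETS,
                         function(s) paste(sort.int(s), collapse = "+"),
                         character(1))

# Drugs whose dose changes are themselves actions.
DOSE_ACTION_DRUGS <- c("metformin", "basal_insulin", "premix_insulin")

#' Infer the action taken between two consecutive prescriptions
#'
#' Delta semantics (antiglycemic), with precedence: switch to an insulin
#' regimen > adding an OAD class (lowest canonical index if several) >
#' dose change of metformin / basal insulin / premixed insulin (largest
#' relative change decides increase vs decrease) > no change. Subset
#' semantics (antihypertensive, lipid-lowering): the index of the current
#' drug-class set in the canonical subset ordering; `prev` is ignored.
#'
#' @param prev,cur `t2d_prescription` objects of the same treatment type.
#' @param treatment_type treatment type.
#' @return 0-based action index (integer).
#' @export
infer_action <- function(prev, cur, treatment_type) {
  check_treatment_type(treatment_type)
  if (treatment_type != "antiglycemic") {
    sig <- paste(sort.int(rx_classes(cur)), collapse = "+")
    i <- match(sig, if (treatment_type == "antihypertensive")
      AHT_SUBSET_SIG else LIP_SUBSET_SIG)
    if (is.na(i)) stop("prescription does not map to a canonical subset",
                       call. = FALSE)
    return(i - 1L)
  }
  prev_cls <- rx_classes(prev); cur_cls <- rx_classes(cur)
  # 1. insulin regimen switch
  reg_cur <- insulin_regimen_index(cur_cls)
  reg_prev <- insulin_regimen_index(prev_cls)
  ins_changed <- !setequal(intersect(cur_cls, INSULIN_CLASSES),
                           intersect(prev_cls, INSULIN_CLASSES))
  if (!is.na(reg_cur) && ins_changed && !identical(reg_cur, reg_prev)) {
    return(reg_cur)
  }
  # 2. newly added OAD class
  added <- intersect(setdiff(cur_cls, prev_cls), OAD_CLASSES)
  if (length(added)) return(min(GLY_ADD_INDEX[added]))
  # 3. dose change of the three named drugs
  common <- intersect(intersect(prev_cls, cur_cls), DOSE_ACTION_DRUGS)
  if (length(common)) {
    prev_d <- vapply(common, function(cl) rx_dose(prev, cl), numeric(1))
    cur_d <- vapply(common, function(cl) rx_dose(cur, cl), numeric(1))
    ok <- !is.na(prev_d) & !is.na(cur_d) & prev_d > 0
    rel <- (cur_d[ok] - prev_d[ok]) / prev_d[ok]
    rel <- rel[rel != 0]
    if (length(rel)) {
      top <- rel[which.max(abs(rel))]
      return(if (top > 0) 1L else 2L)
    }
  }
  0L
}

# Default doses used when an action introduces a drug class.
DEFAULT_DOSES <- c(agi = 50, dpp4 = 100, metformin = 1000, sglt2 = 10,
                   su = 40, tzd = 15, glp1 = 1.8,
                   basal_insulin = 20, prandial_insulin = 12,
                   premix_insulin = 30)
DOSE_STEP <- 0.5  # relative step for dose increase/decrease actions

#' Apply an action to a prescription
#'
#' Inverse of [infer_action()] for coherent pairs: delta actions modify the
#' previous antiglycemic prescription (dose step, class addition at default
#' dose, or switch to the named insulin regimen, discontinuing oral drugs);
#' subset actions return the named drug-class set at default doses.
#'
#' @param prev previous `t2d_prescription`.
#' @param action 0-based action index.
#' @param treatment_type treatment type.
#' @return The resulting `t2d_prescription`.
#' @export
apply_action <- function(prev, action, treatment_type) {
  check_treatment_type(treatment_type)
  space <- enumerate_actions(treatment_type)
  action <- as.integer(action)
  if (is.na(action) || action < 0L || action >= space$arity) {
    stop("action index out of range [0, ", space$arity - 1L, "]",
         call. = FALSE)
  }
  if (space$semantics == "regimen_subset") {
    cls <- space$subsets[[action + 1L]]
    return(prescription(treatment_type, cls, unname(DEFAULT_DOSES[cls])))
  }
  cls <- rx_classes(prev)
  if (action == 0L) return(prev)
  if (action %in% c(1L, 2L)) {
    target <- intersect(DOSE_ACTION_DRUGS, cls)
    if (!length(target)) {
      stop("dose-change action with none of metformin/basal/premix insulin ",
           "prescribed", call. = FALSE)
    }
    target <- target[1L]
    out <- prev
    i <- match(target, out$items$drug_class)
    mult <- if (action == 1L) 1 + DOSE_STEP else 1 - DOSE_STEP
    dose <- out$items$daily_dose[i]
    if (is.na(dose)) dose <- DEFAULT_DOSES[[target]]
    out$items$daily_dose[i] <- dose * mult
    return(out)
  }
  if (action %in% GLY_ADD_INDEX) {
    add_cls <- names(GLY_ADD_INDEX)[match(action, GLY_ADD_INDEX)]
    if (add_cls %in% cls) {
      stop("incoherent action: 'Adding ", add_cls, "' but class already ",
           "prescribed", call. = FALSE)
    }
    return(prescription(treatment_type, c(cls, add_cls),
                        c(prev$items$daily_dose, DEFAULT_DOSES[[add_cls]])))
  }
  # insulin regimen switch: regimen replaces the whole prescription
  reg <- GLY_INSULIN_REGIMENS[[as.character(action)]]
  prescription(treatment_type, reg, unname(DEFAULT_DOSES[reg]))
}

#' Is (prev, action) a coherent pair?
#'
#' Coherent means [apply_action()] succeeds and the resulting prescription
#' change is the one the action names (so [infer_action()] round-trips).
#'
#' @inheritParams apply_action
#' @return logical.
#' @export
is_coherent_action <- function(prev, action, treatment_type) {
  cur <- tryCatch(apply_action(prev, action, treatment_type),
                  error = function(e) NULL)
  if (is.null(cur)) return(FALSE)
  identical(infer_action(prev, cur, treatment_type), as.integer(action))
}
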