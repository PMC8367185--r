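test_that("canonical action spaces match the published tables", {
  gly <- enumerate_actions("antiglycemic")
  expect_equal(gly$arity, 13L)
  expect_equal(gly$labels[1], "No prescription change")
  expect_equal(gly$labels[13], "Using basal and prandial insulins")
  expect_equal(gly$labels[6], "Adding metformin")

  aht <- enumerate_actions("antihypertensive")
  expect_equal(aht$arity, 16L)
  expect_equal(aht$labels[1], "No drugs")
  expect_equal(aht$subsets[[7]], c("A", "C"))   # index 6
  expect_equal(aht$subsets[[16]], c("A", "B", "C", "D"))

  lip <- enumerate_actions("lipid_lowering")
  expect_equal(lip$arity, 8L)
  expect_equal(lip$subsets[[8]], c("statin", "fibrate", "ezetimibe"))
  # subset spaces are exactly the power sets of their vocabularies
  sig <- function(s) paste(sort(s), collapse = "+")
  expect_equal(sort(vapply(aht$subsets, sig, character(1))),
               sort(vapply(0:15, function(m) {
                 sig(c("A", "B", "C", "D")[bitwAnd(m, c(1, 2, 4, 8)) > 0])
               }, character(1))))
  expect_error(enumerate_actions("antifungal"), "unknown treatment_type")
})

test_that("action inference follows the documented semantics", {
  tt <- "antiglycemic"
  met1000 <- prescription(tt, "metformin", 1000)
  expect_identical(infer_action(met1000, met1000, tt), 0L)
  expect_identical(infer_action(prescription(tt, "metformin", 500),
                                met1000, tt), 1L)
  expect_identical(infer_action(met1000,
                                prescription(tt, "metformin", 500), tt), 2L)
  expect_identical(infer_action(met1000,
                                prescription(tt, c("metformin", "su"),
                                             c(1000, 40)), tt), 7L)
  expect_identical(infer_action(met1000,
                                prescription(tt, "basal_insulin", 20), tt),
                   10L)
  # subset semantics ignore the previous prescription
  expect_identical(infer_action(prescription("antihypertensive", "B"),
                                prescription("antihypertensive",
                                             c("A", "C")),
                                "antihypertensive"), 6L)
  expect_identical(infer_action(prescription("lipid_lowering"),
                                prescription("lipid_lowering",
                                             c("statin", "fibrate",
                                               "ezetimibe")),
                                "lipid_lowering"), 7L)
})

test_that("precedence resolves simultaneous changes deterministically", {
  tt <- "antiglycemic"
  prev <- prescription(tt, "metformin", 1000)
  # insulin switch + OAD addition + dose change in one step: switch wins
  cur <- prescription(tt, c("basal_insulin"), 20)
  expect_identical(infer_action(prev, cur, tt), 10L)
  # two OADs added: lowest canonical index wins (AGI=3 < TZD=8)
  cur2 <- prescription(tt, c("metformin", "agi", "tzd"), c(1000, 50, 15))
  expect_identical(infer_action(prev, cur2, tt), 3L)
  # mixed-direction dose changes: largest relative change decides
  prev3 <- prescription(tt, c("metformin", "basal_insulin"), c(1000, 20))
  cur3 <- prescription(tt, c("metformin", "basal_insulin"), c(900, 40))
  expect_identical(infer_action(prev3, cur3, tt), 1L)  # +100% beats -10%
})

test_that("apply_action implements the labels and flags incoherent adds", {
  tt <- "antiglycemic"
  prev <- prescription(tt, "metformin", 1000)
  expect_true("su" %in% rx_classes(apply_action(prev, 7, tt)))
  expect_error(apply_action(prev, 5, tt), "already")
  expect_equal(rx_classes(apply_action(prev, 12, tt)),
               c("basal_insulin", "prandial_insulin"))
  # "No drugs" subset action empties the prescription
  expect_length(rx_classes(apply_action(prescription("antihypertensive",
                                                     c("A", "B")),
                                        0, "antihypertensive")), 0)
  expect_error(apply_action(prev, 13, tt), "out of range")
})

test_that("infer and apply round-trip over coherent pairs", {
  tt <- "antiglycemic"
  prevs <- list(
    prescription(tt),
    prescription(tt, "metformin", 1000),
    prescription(tt, c("metformin", "su"), c(1000, 40)),
    prescription(tt, "basal_insulin", 20),
    prescription(tt, c("metformin", "basal_insulin"), c(2000, 30)),
    prescription(tt, c("agi", "dpp4", "metformin", "sglt2", "su", "tzd",
                       "glp1"), 1),
    prescription(tt, "premix_insulin", 30),
    prescription(tt, c("basal_insulin", "prandial_insulin"), c(20, 12))
  )
  n_checked <- 0L
  for (prev in prevs) {
    for (a in 0:12) {
      if (!is_coherent_action(prev, a, tt)) next
      cur <- apply_action(prev, a, tt)
      expect_identical(infer_action(prev, cur, tt), a)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 40)  # the fixture family exercises most actions
  # subset semantics: every index round-trips from any previous state
  for (tt2 in c("antihypertensive", "lipid_lowering")) {
    prev <- prescription(tt2)
    for (a in seq_len(enumerate_actions(tt2)$arity) - 1L) {
      expect_identical(infer_action(prev, apply_action(prev, a, tt2), tt2),
                       a)
    }
  }
})

test_that("prescription codec round-trips and maps drug names to classes", {
  tt <- "antiglycemic"
  rx <- parse_rx("acarbose:50;metformin:1000", tt)
  expect_setequal(rx_classes(rx), c("agi", "metformin"))
  expect_equal(format_rx(parse_rx("A;C", "antihypertensive")), "A;C")
  expect_equal(rx_classes(parse_rx("", tt)), character(0))
  expect_error(parse_rx("unobtainium:1", tt), "unrecognized")
  rt <- parse_rx(format_rx(rx), tt)
  expect_setequal(rx_classes(rt), rx_classes(rx))
})
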