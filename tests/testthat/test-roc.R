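test_that("cut-off sweep enumerates every observed operating point in order", {
  curve <- roc_curve(c(4, 2, 3, 1), c("case", "case", "control", "control"))
  expect_equal(curve$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(curve$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(curve$cutoff, c(4, 3, 2, 1, -Inf))
  # counts at each point are consistent with the strict > rule
  expect_equal(curve$tp + curve$fn, rep(2L, 5))
  expect_equal(curve$fp + curve$tn, rep(2L, 5))
  expect_equal(curve$sensitivity, curve$tpr)
  expect_equal(curve$specificity, 1 - curve$fpr)
  expect_equal(auc(curve), 0.75)
})

test_that("curve endpoints and monotonicity hold on random instances", {
  withr::local_seed(101)
  for (i in 1:50) {
    inst <- random_instance(p_na = 0.1)
    if (sum(!is.na(inst$scores) & inst$labels == "case") == 0 ||
        sum(!is.na(inst$scores) & inst$labels == "control") == 0) next
    curve <- roc_curve(inst$scores, inst$labels)
    expect_equal(curve$tpr[1], 0)
    expect_equal(curve$fpr[1], 0)
    expect_equal(curve$tpr[nrow(curve)], 1)
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_true(all(diff(curve$tpr) >= 0))
    expect_true(all(diff(curve$fpr) >= 0))
    expect_equal(as.data.frame(curve)[c("cutoff", "fpr", "tpr")],
                 enumerate_points(inst$scores, inst$labels),
                 ignore_attr = TRUE)
  }
})

test_that("separable and degenerate scores give the expected curves", {
  lab <- rep(c("case", "control"), each = 3)
  sep <- roc_curve(c(10, 11, 12, 1, 2, 3), lab)
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_equal(auc(sep), 1.0)

  flat <- roc_curve(rep(2, 6), lab)
  expect_equal(nrow(flat), 2L)
  expect_equal(flat$tpr, c(0, 1))
  expect_equal(auc(flat), 0.5)
})

test_that("missing scores are excluded and degenerate labels error", {
  lab <- rep(c("case", "control"), each = 2)
  curve <- roc_curve(c(4, NA, 3, 1), lab)
  expect_equal(attr(curve, "n_case"), 1L)
  expect_equal(attr(curve, "n_control"), 2L)
  expect_error(roc_curve(c(NA, NA, 3, 1), lab), "degenerate labels")
  expect_error(roc_curve(c(1, 2), c("case", "case")), "degenerate labels")
  expect_error(roc_curve(c(1, 2), c("case", "CFS")), "labels must be")
})

test_that("trapezoidal AUC equals the all-pairs Mann-Whitney probability", {
  withr::local_seed(2024)
  for (i in 1:60) {
    inst <- random_instance()
    expect_equal(auc(roc_curve(inst$scores, inst$labels)),
                 mw_auc(inst$scores, inst$labels))
  }
})

test_that("AUC is invariant to monotone transforms and flips with direction", {
  withr::local_seed(77)
  scores <- 2^rnorm(40)  # RQ-like, tie-free
  labels <- rep(c("case", "control"), 20)
  a <- auc(roc_curve(scores, labels))
  expect_equal(auc(roc_curve(log2(scores), labels)), a)
  expect_equal(auc(roc_curve(-scores, labels, "less_is_positive")), a)
  # delta-Ct convention: lower value calls positive
  expect_equal(auc(roc_curve(-log2(scores), labels, "less_is_positive")), a)
  swapped <- ifelse(labels == "case", "control", "case")
  expect_equal(auc(roc_curve(scores, swapped)), 1 - a)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(321)
  for (i in 1:10) {
    inst <- random_instance()
    ref <- pROC::roc(response = inst$labels, predictor = inst$scores,
                     levels = c("control", "case"), direction = "<",
                     quiet = TRUE)
    expect_equal(auc(roc_curve(inst$scores, inst$labels)),
                 as.numeric(pROC::auc(ref)))
  }
})

test_that("FPR-constrained cut-off maximises TPR and is most conservative", {
  withr::local_seed(55)
  for (i in 1:40) {
    inst <- random_instance()
    curve <- roc_curve(inst$scores, inst$labels)
    target <- sample(c(0, 0.05, 0.1, 0.25, 0.5), 1)
    pick <- cutoff_at_fpr(curve, target)
    pts <- enumerate_points(inst$scores, inst$labels)
    admissible <- pts[pts$fpr <= target, ]
    expect_lte(pick$achieved_fpr, target)
    expect_equal(pick$achieved_tpr, max(admissible$tpr))
    # most conservative = largest cut-off among the TPR-maximising points
    expect_equal(pick$cutoff,
                 max(admissible$cutoff[admissible$tpr == pick$achieved_tpr]))
  }
})

test_that("a 5% target with 20 controls admits at most one false positive", {
  withr::local_seed(9)
  scores <- c(rnorm(15, 1.5), rnorm(20))
  labels <- rep(c("case", "control"), c(15, 20))
  pick <- cutoff_at_fpr(roc_curve(scores, labels), 0.05)
  expect_lte(sum(scores[labels == "control"] > pick$cutoff), 1L)
})

test_that("cut-off selection handles separable and inverted score patterns", {
  lab <- rep(c("case", "control"), each = 3)
  sep <- cutoff_at_fpr(roc_curve(c(10, 11, 12, 1, 2, 3), lab), 0)
  expect_equal(sep$achieved_fpr, 0)
  expect_equal(sep$achieved_tpr, 1)
  expect_gte(sep$cutoff, 3)   # at or above the highest control
  expect_lt(sep$cutoff, 10)   # below the lowest case

  # cases all below controls: nothing beats the all-negative point
  inv <- cutoff_at_fpr(roc_curve(c(1, 2, 3, 10, 11, 12), lab), 0.1)
  expect_equal(inv$achieved_tpr, 0)
  expect_equal(inv$achieved_fpr, 0)
  expect_equal(inv$cutoff, 12)

  expect_error(cutoff_at_fpr(roc_curve(c(1, 2, 3, 10, 11, 12), lab), 1),
               "in \\[0, 1\\)")
})

test_that("ROC curves export to TSV with counts at every cut-off", {
  curve <- roc_curve(c(4, 2, 3, 1), c("case", "case", "control", "control"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roc_curve(curve, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 5L)
  expect_equal(back$tp / (back$tp + back$fn), curve$tpr)
})
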