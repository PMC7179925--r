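test_that("confusion tallies match hand counts", {
  cc <- confusion_counts(c(1, 1, 1, 1), c(1, 1, 1, 1), positive = 1)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 4L, FP = 0L, TN = 0L, FN = 0L))
  cc2 <- confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1), positive = 1)
  expect_equal(cc2$TP + cc2$TN, 0)
  cc3 <- confusion_counts(c(1, 1, 1, 0, 0, 0), c(1, 0, 1, 0, 0, 1),
                          positive = 1)
  expect_equal(unlist(cc3[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 1L, TN = 2L, FN = 1L))
  expect_error(confusion_counts(1:3, 1:2), "equal length")
})

test_that("metric suite reproduces published confusion-derived cells", {
  r <- compute_metrics(confusion_counts_raw(52, 10, 24, 16))
  expect_equal(round(r$sensitivity, 2), 76.47)
  expect_equal(round(r$precision, 2), 0.84)
  expect_equal(round(r$specificity, 2), 70.59)
  expect_equal(round(r$accuracy, 2), 74.51)
  expect_equal(round(r$mcc, 2), 0.45)
  expect_equal(round(r$f1$micro, 2), 0.75)

  r2 <- compute_metrics(confusion_counts_raw(12, 0, 3, 5))
  expect_equal(round(r2$sensitivity, 2), 70.59)
  expect_equal(r2$specificity, 100)
  expect_equal(r2$accuracy, 75)
  expect_equal(round(r2$mcc, 2), 0.51)

  perfect <- compute_metrics(confusion_counts_raw(5, 0, 5, 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1$micro, 1)
})

test_that("MCC conventions: symmetry and zero for constant predictions", {
  r <- compute_metrics(confusion_counts_raw(30, 10, 25, 5))
  # simultaneous class-and-prediction swap leaves MCC unchanged
  r_swap <- compute_metrics(confusion_counts_raw(25, 5, 30, 10))
  expect_equal(r$mcc, r_swap$mcc)
  # constant predictions: a zero marginal factor -> MCC 0
  expect_equal(compute_metrics(confusion_counts_raw(35, 35, 0, 0))$mcc, 0)
  expect_equal(compute_metrics(confusion_counts_raw(0, 0, 35, 35))$mcc, 0)
  expect_true(all(abs(r$mcc) <= 1))
  # zero denominators report undefined with a reason, not NaN
  r0 <- compute_metrics(confusion_counts_raw(0, 0, 5, 3))
  expect_true(any(grepl("precision", r0$undefined)))
  expect_true(is.na(r0$precision))
})

test_that("F1 aggregation: micro equals accuracy for complete binary confusion", {
  agg <- compute_metrics(confusion_counts_raw(52, 10, 24, 16))$f1
  expect_equal(agg$micro, (52 + 24) / 102)
  expect_equal(round(agg$micro, 2), 0.75)
  expect_gte(max(agg$per_class), agg$macro)
  expect_lte(min(agg$per_class), agg$macro)
  perfect <- f1_aggregate(list(a = confusion_counts_raw(7, 0, 0, 0)))
  expect_equal(perfect$macro, 1)
  expect_equal(perfect$weighted, 1)
  expect_equal(perfect$micro, 1)
  expect_error(f1_aggregate(list()), "empty")
})

test_that("AUROC: trapezoid and rank formulations agree; ties count half", {
  expect_equal(roc_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auroc(c(0.9, 0.7, 0.7, 0.3), c(1, 1, 0, 0)), 0.875)
  set.seed(33)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    sc <- round(runif(n), sample(1:3, 1))   # induce ties
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lb) || all(lb)) next
    expect_equal(roc_auroc(sc, lb, method = "trapezoid"),
                 roc_auroc(sc, lb, method = "rank"), tolerance = 1e-12)
  }
  expect_error(roc_auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  for (i in 1:20) {
    sc <- rnorm(50)
    lb <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(lb) || all(lb)) next
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
      response = lb, predictor = sc, levels = c(FALSE, TRUE),
      direction = "<", quiet = TRUE))))
    expect_equal(roc_auroc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("bootstrap AUROC CI is reproducible and collapses for separation", {
  sc <- c(rnorm(200, 3), rnorm(200, -3))
  lb <- rep(c(TRUE, FALSE), each = 200)
  ci <- bootstrap_auroc_ci(sc, lb, reps = 200, seed = 8)
  expect_identical(ci, bootstrap_auroc_ci(sc, lb, reps = 200, seed = 8))
  expect_gt(ci[1], 0.99)
  set.seed(2)
  sc2 <- rnorm(60); lb2 <- rep(c(TRUE, FALSE), 30)
  ci2 <- bootstrap_auroc_ci(sc2, lb2, reps = 200, seed = 1)
  expect_lt(ci2[1], roc_auroc(sc2, lb2))
  expect_gt(ci2[2], roc_auroc(sc2, lb2))
  expect_error(bootstrap_auroc_ci(sc2, lb2, reps = 10), "reps")
})

test_that("PPV/NPV tables use dual cut-offs with flagged empty call sets", {
  sc <- c(0.95, 0.9, 0.85, 0.2, 0.1, 0.05)
  lb <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  tab <- ppv_npv_table(sc, lb, c(1.0, 0.9, 0.8))
  expect_equal(tab$n_pred_pos, c(0, 2, 3))
  expect_equal(tab$ppv, c(0, 100, 200 / 3))
  expect_true(tab$empty_pos[1])
  expect_equal(tab$n_pred_neg, c(0, 2, 3))
  expect_equal(tab$npv, c(0, 100, 200 / 3))
  # positive calls never increase with the threshold
  tab2 <- ppv_npv_table(runif(50), runif(50) > 0.5, seq(1, 0, -0.1))
  expect_true(all(diff(tab2$n_pred_pos) >= 0))  # descending thresholds
  expect_error(ppv_npv_table(sc, lb, 1.5), "thresholds")
})
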