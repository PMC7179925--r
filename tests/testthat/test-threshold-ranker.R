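test_that("threshold models match the worked examples", {
  m <- fit_threshold_model(c(5, 4, 3), c(1, 2, 0))
  expect_equal(m$direction, "positive_high")
  expect_equal(m$threshold, 3)
  expect_equal(m$point_auroc, 1.0)
  expect_equal(m$confusion_at_threshold$TP, 3)
  expect_equal(m$point_auroc,
               (m$confusion_at_threshold$TP / 3 +
                  m$confusion_at_threshold$TN / 3) / 2)

  # both t=2 and t=3 reach 0.75; the smallest maximizer wins
  m2 <- fit_threshold_model(c(3, 2), c(2, 1))
  expect_equal(m2$point_auroc, 0.75)
  expect_equal(m2$threshold, 2)

  m3 <- fit_threshold_model(c(1, 1), c(1, 1))
  expect_equal(m3$point_auroc, 0.5)
  expect_true(m3$degenerate)

  expect_error(fit_threshold_model(numeric(0), 1), "non-empty")
  expect_error(fit_threshold_model(c(1, NA), c(1, 2)), "finite")
})

test_that("threshold sweep equals the exhaustive cut-position oracle", {
  set.seed(101)
  for (i in 1:200) {
    np <- sample(2:25, 1); nn <- sample(2:25, 1)
    vp <- round(rnorm(np, sample(0:2, 1)), sample(0:2, 1))
    vn <- round(rnorm(nn), sample(0:2, 1))
    m <- fit_threshold_model(vp, vn)
    expect_equal(m$point_auroc, oracle_point_auroc(vp, vn),
                 info = sprintf("instance %d", i))
    expect_gte(m$point_auroc, 0.5)
    expect_lte(m$point_auroc, 1)
    # threshold lies among the observed values
    expect_true(m$threshold %in% c(vp, vn))
  }
})

test_that("point AUROC is invariant to monotone transforms and label swap", {
  set.seed(202)
  for (i in 1:60) {
    vp <- rnorm(12, 1); vn <- rnorm(9)
    m <- fit_threshold_model(vp, vn)
    # positive affine transform: AUROC unchanged, threshold mapped
    tr <- function(v) 2.5 * v + 1
    mt <- fit_threshold_model(tr(vp), tr(vn))
    expect_equal(mt$point_auroc, m$point_auroc)
    expect_equal(mt$threshold, tr(m$threshold))
    # label swap flips direction, preserves AUROC
    ms <- fit_threshold_model(vn, vp)
    expect_equal(ms$point_auroc, m$point_auroc)
    expect_false(ms$direction == m$direction)
  }
})

test_that("ranking orders transcripts by AUROC and recovers planted markers", {
  we <- generate_worked_example()
  rk <- rank_features(we$matrix, we$labels, p_values = FALSE)
  expect_s3_class(rk, "ranked_features")
  expect_equal(rk$transcript_id, c("A", "C", "B", "D"))
  expect_equal(rk$point_auroc, c(1, 1, 5 / 6, 0.5))
  expect_equal(rk$direction[rk$transcript_id == "C"], "negative_high")
  expect_true(rk$degenerate[rk$transcript_id == "D"])

  # planted informative transcripts rank at the top
  cfg <- simulation_config(n_transcripts = 200, n_informative = 5,
                           class_sizes = c(normal = 0, early = 100,
                                           late = 50),
                           effect_size_sd = 2, seed = 9)
  ds <- generate_dataset(cfg)
  lg <- log2_transform(ds$matrix)
  rk2 <- rank_features(lg, ds$labels, p_values = FALSE)
  expect_true(all(ds$truth$transcript_id %in% head(rk2$transcript_id, 10)))

  # permuting sample order leaves the table unchanged
  perm <- sample(ncol(lg$values))
  rk3 <- rank_features(subset_matrix(lg, samples = perm), ds$labels,
                       p_values = FALSE)
  expect_equal(rk3, rk2)
})

test_that("AUROC-cutoff panels honor the inclusive boundary", {
  we <- generate_worked_example()
  rk <- rank_features(we$matrix, we$labels, p_values = FALSE)
  # boundary inclusive at the 5/6 row
  p1 <- select_by_auroc(rk, 5 / 6)
  expect_equal(p1$transcript_ids, c("A", "C", "B"))
  p2 <- select_by_auroc(rk, 0.9)
  expect_equal(p2$transcript_ids, c("A", "C"))
  p3 <- select_by_auroc(rk, 0.5)
  expect_equal(length(p3), 4)
  expect_error(select_by_auroc(rk, 1.2), "cutoff")
  # empty panels are allowed and flagged
  rk_weak <- rk[rk$transcript_id %in% c("B", "D"), , drop = FALSE]
  class(rk_weak) <- class(rk)
  p_empty <- select_by_auroc(rk_weak, 0.99)
  expect_length(p_empty, 0)
  expect_true(p_empty$parameters$empty)
  # monotone: higher cutoff panels nest in lower cutoff panels
  expect_true(all(p2$transcript_ids %in% p1$transcript_ids))
})

test_that("wilcoxon rank test matches exact enumeration and BH bounds", {
  x <- em(rbind(c(4, 5, 6, 1, 2, 3),
                c(1, 2, 3, 1, 2, 3),
                c(10, 20, 30, 1, 2, 3),
                c(7, 7, 7, 7, 7, 7)))
  lab <- labels_for(x, c(rep("early", 3), rep("late", 3)))
  wt <- wilcoxon_rank_test(x, lab)
  expect_equal(wt$p_value[1], 0.1)  # 2 / choose(6,3)
  expect_equal(wt$p_value[3], 0.1)
  expect_equal(wt$p_value[4], 1)    # identical pooled values
  expect_true(all(wt$adjusted_p >= wt$p_value - 1e-12))
  expect_true(all(wt$adjusted_p <= 1))
  expect_equal(wt$adjusted_p, p.adjust(wt$p_value, "BH"))
  expect_error(wilcoxon_rank_test(x, labels_for(x, rep("early", 6))),
               "both classes")
})
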