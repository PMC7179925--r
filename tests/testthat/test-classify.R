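# Small planted dataset shared by the classifier tests.
make_planted <- function(seed = 3, n_transcripts = 60, n_informative = 8,
                         sizes = c(normal = 16, early = 40, late = 30),
                         effect = 2.5) {
  generate_dataset(simulation_config(
    n_transcripts = n_transcripts, n_informative = n_informative,
    class_sizes = sizes, effect_size_sd = effect, dropout_rate = 0.02,
    seed = seed))
}
small_grid <- grid_spec(gamma_values = c(0.01, 0.1), cost_values = c(1, 5),
                        folds = 5, seed = 1)

test_that("grid search is deterministic and recovers separable data", {
  ds <- make_planted()
  lg <- log2_transform(ds$matrix)
  panel <- ds$truth$transcript_id
  al <- align_features(lg, panel)$matrix
  z <- apply_zscore(al, fit_zscore(al))
  keep <- ds$labels$class != "normal"
  zs <- subset_matrix(z, samples = which(keep))
  g1 <- grid_search_cv(zs, ds$labels, small_grid)
  g2 <- grid_search_cv(zs, ds$labels, small_grid)
  expect_identical(g1$table, g2$table)
  expect_gte(max(g1$table$cv_accuracy), 0.95)
  # single-cell grid returns that cell
  g3 <- grid_search_cv(zs, ds$labels,
                       grid_spec(gamma_values = 0.5, cost_values = 2,
                                 folds = 5))
  expect_equal(c(g3$best_gamma, g3$best_cost), c(0.5, 2))
})

test_that("binary training reaches perfect training accuracy on separable data", {
  ds <- make_planted()
  mod <- train_binary(ds$matrix, ds$labels, ds$truth$transcript_id,
                      small_grid)
  pred <- predict(mod, ds$matrix)
  keep <- ds$labels$class != "normal"
  expect_gte(mean(pred[keep] == ds$labels$class[keep]), 0.97)
  expect_s3_class(mod, "stage_model")
  expect_true(mod$decision_threshold >= 0 && mod$decision_threshold <= 1)
  expect_error(train_binary(ds$matrix, ds$labels, c("NOPE1"), small_grid),
               "missing")
})

test_that("scores respect threshold monotonicity and the inclusive boundary", {
  ds <- make_planted(seed = 5)
  mod <- train_binary(ds$matrix, ds$labels, ds$truth$transcript_id,
                      small_grid)
  s <- predict_scores(mod, ds$matrix)
  expect_true(all(s >= 0 & s <= 1))
  # raising the threshold never increases positive calls
  n_pos <- vapply(seq(0, 1, 0.1),
                  function(t) sum(predict(mod, ds$matrix,
                                          threshold = t) == "early"),
                  numeric(1))
  expect_true(all(diff(n_pos) <= 0))
  # score exactly at threshold is called positive
  thr <- as.numeric(s[1])
  p_at <- predict(mod, ds$matrix, threshold = thr)
  expect_equal(unname(p_at[1]), "early")
  # prediction is invariant to sample order and extra non-panel rows
  perm <- rev(seq_along(ds$matrix$sample_ids))
  s_perm <- predict_scores(mod, subset_matrix(ds$matrix, samples = perm))
  expect_equal(as.numeric(s_perm), as.numeric(s[perm]))
  # all-zero FPKM input scores without error
  zero <- expression_matrix(
    matrix(0, nrow(ds$matrix$values), 2,
           dimnames = list(ds$matrix$transcript_ids, c("Z1", "Z2"))),
    "fpkm")
  sz <- predict_scores(mod, zero)
  expect_true(all(is.finite(sz) & sz >= 0 & sz <= 1))
  # an extreme sample (|z| > 6 somewhere) is flagged out-of-distribution
  extreme <- expression_matrix(
    matrix(1e9, nrow(ds$matrix$values), 1,
           dimnames = list(ds$matrix$transcript_ids, "X1")),
    "fpkm")
  expect_true(all(attr(predict_scores(mod, extreme), "ood")))
})

test_that("decision threshold balances recall and specificity", {
  t1 <- choose_decision_threshold(c(0.9, 0.8, 0.2, 0.1),
                                  c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.numeric(t1), 0.8)
  # inverted labels still minimize |recall - specificity|
  t2 <- choose_decision_threshold(c(0.9, 0.8, 0.2, 0.1),
                                  c(FALSE, FALSE, TRUE, TRUE))
  sc <- c(0.9, 0.8, 0.2, 0.1); lb <- c(FALSE, FALSE, TRUE, TRUE)
  rec <- sum(sc >= t2 & lb) / sum(lb)
  spc <- sum(sc < t2 & !lb) / sum(!lb)
  diffs <- vapply(sort(unique(sc)), function(t)
    abs(sum(sc >= t & lb) / sum(lb) - sum(sc < t & !lb) / sum(!lb)),
    numeric(1))
  expect_equal(abs(rec - spc), min(diffs))
  # constant scores: degenerate flag
  t3 <- choose_decision_threshold(rep(0.6, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(t3), 0.5)
  expect_true(attr(t3, "degenerate"))
  expect_error(choose_decision_threshold(1:3, c(TRUE, TRUE, TRUE)),
               "both classes")
})

test_that("one-vs-rest multiclass separates three planted classes", {
  ds <- make_planted(seed = 7, sizes = c(normal = 20, early = 40, late = 30))
  split <- stratified_split(log2_transform(ds$matrix), ds$labels, 0.75,
                            seed = 2)
  mod <- train_multiclass_ovr(split$train$matrix, split$train$labels,
                              ds$truth$transcript_id,
                              grid_spec(gamma_values = 0.1, cost_values = 1,
                                        folds = 5))
  sc <- predict(mod, split$validation$matrix, type = "score")
  expect_equal(ncol(sc), 3)
  pred <- predict(mod, split$validation$matrix)
  expect_equal(unname(pred),
               unname(colnames(sc)[max.col(sc, ties.method = "first")]))
  expect_gte(mean(pred == split$validation$labels$class), 0.9)
  expect_error(
    train_multiclass_ovr(split$train$matrix, split$train$labels,
                         ds$truth$transcript_id,
                         grid_spec(gamma_values = 0.1, cost_values = 1,
                                   folds = 30)),
    "fewer samples than folds")
})

test_that("cross-validation tests each sample once and pools the confusion", {
  ds <- make_planted(seed = 9, sizes = c(normal = 0, early = 30, late = 24))
  cv <- cross_validate(ds$matrix, ds$labels, ds$truth$transcript_id,
                       folds = 6, seed = 4)
  cc <- cv$pooled$counts
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 54)
  expect_equal(sort(unique(cv$fold_id)), 1:6)
  expect_equal(as.integer(table(cv$fold_id)), rep(9L, 6))
  # rerun identical
  cv2 <- cross_validate(ds$matrix, ds$labels, ds$truth$transcript_id,
                        folds = 6, seed = 4)
  expect_identical(cv$scores, cv2$scores)
  # LOO has n singleton folds
  sub <- subset_matrix(ds$matrix, samples = c(1:10, 31:40))
  cvl <- cross_validate(sub, ds$labels, ds$truth$transcript_id,
                        folds = "loo", seed = 4)
  expect_equal(length(unique(cvl$fold_id)), 20)
  expect_error(cross_validate(sub, ds$labels, ds$truth$transcript_id,
                              folds = 30), "folds")
})

test_that("model archives are plain text and reproduce predictions exactly", {
  ds <- make_planted(seed = 11)
  mod <- train_binary(ds$matrix, ds$labels, ds$truth$transcript_id,
                      grid_spec(gamma_values = 0.1, cost_values = 1,
                                folds = 5))
  d <- tempfile("model")
  write_stage_model(mod, d)
  files <- list.files(d)
  expect_setequal(files, c("manifest.json", "panel.tsv", "stats.tsv",
                           "classifier_binary.txt"))
  # all files are readable text
  for (f in files)
    expect_no_error(readLines(file.path(d, f), warn = FALSE))
  mod2 <- read_stage_model(d)
  s1 <- predict_scores(mod, ds$matrix)
  s2 <- predict_scores(mod2, ds$matrix)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_equal(mod2$classes, mod$classes)
  expect_equal(mod2$decision_threshold, mod$decision_threshold)
})
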