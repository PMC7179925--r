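test_that("MDL discretization accepts informative splits and rejects noise", {
  # perfectly separated classes: one cut between 2 and 3
  cuts <- mdl_discretize(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_length(cuts, 1)
  expect_gt(cuts, 2)
  expect_lte(cuts, 3)
  expect_equal(discretize_values(c(1, 2, 3, 4), cuts), c(1L, 1L, 2L, 2L))
  # zero gain: no cuts
  expect_length(mdl_discretize(c(1, 2, 3, 4), c(1, 1, 1, 1)), 0)
  # interleaved labels at small n: gain below the MDL penalty
  expect_length(mdl_discretize(1:8, rep(c(0, 1), 4)), 0)
  expect_error(mdl_discretize(1:3, 1:2), "mismatch")
})

test_that("symmetrical uncertainty matches hand-computed entropies", {
  expect_equal(symmetrical_uncertainty(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_equal(symmetrical_uncertainty(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # joint counts {{2,0},{1,1}}: SU = 2*0.3113/1.8113
  su <- symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 0, 0, 1))
  i_xy <- 1 + (-0.75 * log2(0.75) - 0.25 * log2(0.25)) - 1.5
  expect_equal(su, 2 * i_xy / (1 + (-0.75 * log2(0.75) - 0.25 * log2(0.25))))
  expect_equal(round(su, 4), 0.3437)
  # symmetry and range on random discrete pairs
  set.seed(5)
  for (i in 1:25) {
    x <- sample(1:3, 30, replace = TRUE)
    y <- sample(1:2, 30, replace = TRUE)
    expect_equal(symmetrical_uncertainty(x, y), symmetrical_uncertainty(y, x))
    expect_gte(symmetrical_uncertainty(x, y), 0)
    expect_lte(symmetrical_uncertainty(x, y), 1)
  }
  expect_equal(symmetrical_uncertainty(rep(1, 4), rep(2, 4)), 0)
})

test_that("FCBF keeps relevant features, prunes duplicates, matches the reference", {
  set.seed(31)
  n <- 60
  y <- rep(c("early", "late"), each = n / 2)
  informative <- function(delta) rnorm(n) + ifelse(y == "early", delta, 0)
  f1 <- informative(3); f2 <- informative(2.5); f3 <- informative(2)
  vals <- rbind(F1 = f1, F2 = f2, F3 = f3,
                DUP = f1,                      # byte-identical duplicate
                N1 = rnorm(n), N2 = rnorm(n))
  x <- em(vals)
  lab <- labels_for(x, y)
  panel <- fcbf_select(x, lab)
  # a feature identical to a kept one never survives alongside it
  expect_false(all(c("F1", "DUP") %in% panel$transcript_ids))
  expect_true(any(c("F1", "DUP") %in% panel$transcript_ids))
  # pure-noise features discretize to one bin and are never selected
  expect_false(any(c("N1", "N2") %in% panel$transcript_ids))

  # agreement with an independent implementation of the published filter
  cls <- ifelse(y == "early", "early", "late")
  disc <- list(); su_class <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    cuts <- mdl_discretize(vals[i, ], cls)
    if (length(cuts)) {
      disc[[i]] <- discretize_values(vals[i, ], cuts)
      su_class[i] <- symmetrical_uncertainty(disc[[i]], cls)
    } else disc[i] <- list(NULL)
  }
  ref <- oracle_fcbf(disc, cls, su_class, rownames(vals))
  expect_equal(sort(panel$transcript_ids), sort(ref))
  expect_error(fcbf_select(x, lab, su_threshold = 2), "su_threshold")
})

test_that("ANOVA-F selection matches t-squared and hand-computed tables", {
  # classes {1,2,3} vs {4,5,6}: F = t^2 = 13.5
  x <- em(rbind(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 1) + 0))
  lab <- labels_for(x, c(rep("early", 3), rep("late", 3)))
  p <- anova_f_select(x, lab, 2)
  expect_equal(p$scores[1], 13.5)
  expect_equal(p$transcript_ids[1], "T001")
  # two-class F equals squared pooled t on random instances
  set.seed(77)
  for (i in 1:20) {
    v <- matrix(rnorm(30), 1, 30)
    xx <- em(v)
    ll <- labels_for(xx, rep(c("early", "late"), each = 15))
    f <- anova_f_select(xx, ll, 1)$scores
    t2 <- t.test(v[1:15], v[16:30], var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-9)
  }
  # a constant feature never outranks a separated one
  expect_equal(anova_f_select(x, lab, 1)$transcript_ids, "T001")
  expect_error(anova_f_select(x, lab, 3), "exceeds")
})

test_that("L1 margin selection keeps signal, shrinks with penalty, empties at infinity", {
  set.seed(13)
  n <- 60
  y <- rep(c("early", "late"), each = n / 2)
  sig <- ifelse(y == "early", 1.5, -1.5) + rnorm(n, 0, 0.3)
  vals <- rbind(SIG = sig, matrix(rnorm(5 * n), 5,
                                  dimnames = list(paste0("N", 1:5), NULL)))
  x <- em(vals)
  z <- apply_zscore(x, fit_zscore(x))
  lab <- labels_for(x, y)
  p_strong <- l1_linear_select(z, lab, 20)
  expect_true("SIG" %in% p_strong$transcript_ids)
  expect_lte(length(p_strong), 3)
  # panel size non-increasing along the penalty path
  sizes <- vapply(c(0.01, 0.1, 1, 10, 100, 1e4),
                  function(l) length(l1_linear_select(z, lab, l)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # huge penalty: all weights at zero
  expect_length(l1_linear_select(z, lab, 1e6), 0)
  expect_error(l1_linear_select(z, labels_for(x, rep("early", n)), 1),
               "both classes")
  # bisection helper hits a requested size when attainable
  p_target <- l1_select_size(z, lab, 1)
  expect_equal(length(p_target), 1)
})

test_that("subset search finds predictive masks deterministically", {
  set.seed(17)
  n <- 40
  y <- rep(c("early", "late"), each = n / 2)
  key <- ifelse(y == "early", 2, -2) + rnorm(n, 0, 0.2)
  vals <- rbind(KEY = key,
                matrix(rnorm(4 * n), 4, dimnames = list(paste0("N", 1:4), NULL)))
  x <- em(vals)
  lab <- labels_for(x, y)
  pool <- rownames(vals)
  p <- subset_search_select(x, lab, pool, iterations = 8, seed = 3,
                            folds = 5, pop_size = 10)
  expect_true("KEY" %in% p$transcript_ids)
  expect_gt(attr(p, "fitness"), 0.9)
  # determinism: same seed, same mask and trace
  p2 <- subset_search_select(x, lab, pool, iterations = 8, seed = 3,
                             folds = 5, pop_size = 10)
  expect_identical(p$transcript_ids, p2$transcript_ids)
  expect_identical(attr(p, "fitness_trace"), attr(p2, "fitness_trace"))
  # iterations = 1 returns the best of the initial population
  p1 <- subset_search_select(x, lab, pool, iterations = 1, seed = 3,
                             folds = 5, pop_size = 10)
  expect_length(attr(p1, "fitness_trace"), 1)
  expect_error(subset_search_select(x, lab, character(0), 5), "empty")
})

test_that("panels serialize with provenance and round-trip", {
  p <- feature_panel(c("TB", "TA"), method = "anova_f",
                     parameters = list(k = 2), scores = c(5.2, 1.1))
  f <- tempfile()
  write_panel(p, f)
  q <- read_panel(f)
  expect_equal(q$transcript_ids, p$transcript_ids)
  expect_equal(q$method, "anova_f")
  expect_equal(q$parameters$k, 2)
  expect_equal(q$scores, p$scores)
  expect_error(feature_panel(c("A", "A")), "duplicate")
})
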