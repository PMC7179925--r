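# Independent oracles and fixture builders used across the suite.

# Brute-force threshold-model oracle: exhaustively scans every half-open
# cut position (below the minimum, between each adjacent pair of distinct
# values, above the maximum) for the "assign the higher-mean class iff
# value >= cut" rule and returns the maximum balanced accuracy
# (sensitivity + specificity)/2. Independent of the package's sweep.
oracle_point_auroc <- function(vp, vn) {
  positive_high <- mean(vp) >= mean(vn)
  all_v <- sort(unique(c(vp, vn)))
  cuts <- c(min(all_v) - 1, all_v, max(all_v) + 1)
  if (length(all_v) > 1)
    cuts <- c(cuts, (utils::head(all_v, -1) + utils::tail(all_v, -1)) / 2)
  best <- 0
  for (ct in cuts) {
    if (positive_high) {
      sens <- mean(vp >= ct)
      spec <- mean(vn < ct)
    } else {
      sens <- mean(vp < ct)
      spec <- mean(vn >= ct)
    }
    best <- max(best, (sens + spec) / 2)
  }
  best
}

# Reference implementation of the published fast correlation-based
# filter: order features by class-SU descending; repeatedly take the
# first remaining feature and delete every remaining feature it
# predominates (SU(Fp, Fq) >= SU(Fq, class)). Works on already
# discretized features.
oracle_fcbf <- function(disc_list, y, su_class, ids, su_threshold = 0) {
  cand <- which(su_class > 0 & su_class >= su_threshold)
  remaining <- cand[order(-su_class[cand], ids[cand])]
  kept <- integer(0)
  while (length(remaining) > 0) {
    p <- remaining[1]
    kept <- c(kept, p)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      drop <- vapply(remaining, function(q)
        symmetrical_uncertainty(disc_list[[p]], disc_list[[q]]) >=
          su_class[q], logical(1))
      remaining <- remaining[!drop]
    }
  }
  ids[kept]
}

# Build a score/label vector realizing a cumulative PPV/NPV call table.
# `thresholds` descending; pos_total/pos_correct = cumulative positive
# calls (score >= t) and correct ones; neg_total/neg_correct = cumulative
# negative calls (score <= 1 - t); n_pos/n_neg = class sizes. Samples not
# called at the loosest threshold sit at score 0.5.
scores_from_cumulative <- function(thresholds, pos_total, pos_correct,
                                   neg_total, neg_correct, n_pos, n_neg) {
  stopifnot(!is.unsorted(rev(thresholds)))
  scores <- numeric(0); labels <- logical(0)
  add <- function(s, n_p, n_n) {
    scores <<- c(scores, rep(s, n_p + n_n))
    labels <<- c(labels, rep(TRUE, n_p), rep(FALSE, n_n))
  }
  prev_t <- prev_c <- 0
  for (i in seq_along(thresholds)) {
    inc_t <- pos_total[i] - prev_t
    inc_c <- pos_correct[i] - prev_c
    stopifnot(inc_t >= 0, inc_c >= 0, inc_c <= inc_t)
    s <- if (i == 1) {
      if (thresholds[1] == 1) 1 else (thresholds[1] + 1) / 2
    } else (thresholds[i] + thresholds[i - 1]) / 2
    if (inc_t > 0) add(s, inc_c, inc_t - inc_c)
    prev_t <- pos_total[i]; prev_c <- pos_correct[i]
  }
  prev_t <- prev_c <- 0
  for (i in seq_along(thresholds)) {
    u <- 1 - thresholds[i]
    inc_t <- neg_total[i] - prev_t
    inc_c <- neg_correct[i] - prev_c
    stopifnot(inc_t >= 0, inc_c >= 0, inc_c <= inc_t)
    if (inc_t > 0) add(u, inc_t - inc_c, inc_c)
    prev_t <- neg_total[i]; prev_c <- neg_correct[i]
  }
  rem_pos <- n_pos - sum(labels)
  rem_neg <- n_neg - sum(!labels)
  stopifnot(rem_pos >= 0, rem_neg >= 0)
  add(0.5, rem_pos, rem_neg)
  list(scores = scores, labels = labels)
}

# Small helper: expression matrix straight from a numeric matrix.
em <- function(values, scale = "log2", prefix = "T") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("%s%03d", prefix, seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expression_matrix(values, scale)
}

labels_for <- function(x, classes) sample_labels(x$sample_ids, classes)

# tolerance matching the number of printed decimals
tol_printed <- function(x) {
  s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, trim = TRUE)))
  0.51 * 10^(-nchar(s))
}
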