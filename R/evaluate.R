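# Confusion-matrix metric suite: sensitivity/specificity/accuracy (in %),
# MCC, precision/recall/F1 (fractions) with per-class, macro, weighted and
# micro aggregation, rank-based AUROC with bootstrap CI, and PPV/NPV
# threshold tables.

#' Build confusion counts from raw tallies
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts_raw <- function(tp, fp, tn, fn) {
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Tally a 2x2 confusion matrix
#'
#' @param labels,predictions Vectors of equal length; values compared
#'   against `positive`.
#' @param positive The positive class value.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(labels, predictions, positive = TRUE) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  lp <- labels == positive
  pp <- predictions == positive
  confusion_counts_raw(sum(lp & pp), sum(!lp & pp),
                       sum(!lp & !pp), sum(lp & !pp))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Compute the confusion-matrix metric suite
#'
#' Sensitivity/recall, specificity and accuracy are percentages;
#' precision, recall (fraction) and F1 variants are fractions; MCC uses
#' the standard four-factor denominator and is defined as 0 when any
#' marginal factor is 0 (constant predictions or constant labels). Ratios
#' with a zero denominator are reported as `NA` with the reason recorded
#' in `undefined`.
#'
#' @param c A `confusion_counts` object.
#' @return A list of class `metric_report`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$TP; fp <- c$FP; tn <- c$TN; fn <- c$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  undefined <- character(0)
  sens <- .safe_ratio(tp, tp + fn)
  if (is.na(sens)) undefined <- c(undefined, "sensitivity: no positive labels")
  spec <- .safe_ratio(tn, tn + fp)
  if (is.na(spec)) undefined <- c(undefined, "specificity: no negative labels")
  prec <- .safe_ratio(tp, tp + fp)
  if (is.na(prec)) undefined <- c(undefined, "precision: no positive calls")
  acc <- (tp + tn) / total
  mcc_den_factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(mcc_den_factors == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(mcc_den_factors)))
  f1_pos <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  # negative-class view for aggregation
  prec_n <- .safe_ratio(tn, tn + fn)
  rec_n <- .safe_ratio(tn, tn + fp)
  f1_neg <- if (is.na(prec_n) || is.na(rec_n) || (prec_n + rec_n) == 0) NA_real_ else
    2 * prec_n * rec_n / (prec_n + rec_n)
  agg <- f1_aggregate(list(
    positive = confusion_counts_raw(tp, fp, tn, fn),
    negative = confusion_counts_raw(tn, fn, tp, fp)))
  structure(list(
    counts = c, sensitivity = sens * 100, specificity = spec * 100,
    accuracy = acc * 100, precision = prec, recall = sens, mcc = mcc,
    f1 = agg, undefined = undefined), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Sens %.2f%%  Spec %.2f%%  Acc %.2f%%  Prec %.3f  MCC %.3f  micro-F1 %.3f\n",
    x$sensitivity, x$specificity, x$accuracy, x$precision, x$mcc,
    x$f1$micro))
  if (!is.null(x$auroc))
    cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f)\n", x$auroc,
                x$auroc_ci[1], x$auroc_ci[2]))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = "; "), "\n")
  invisible(x)
}

#' Aggregate per-class F1 scores
#'
#' `macro` is the unweighted mean of per-class F1, `weighted` the
#' support-weighted mean, and `micro` the F1 of the summed counts -- which
#' for a complete binary confusion equals the accuracy.
#'
#' @param per_class_confusions Named list of `confusion_counts`, one per
#'   class (each class taken as its own positive).
#' @return List with `per_class`, `macro`, `weighted`, `micro`.
#' @export
f1_aggregate <- function(per_class_confusions) {
  if (length(per_class_confusions) == 0) stop("empty class set")
  f1_of <- function(cc) {
    p <- .safe_ratio(cc$TP, cc$TP + cc$FP)
    r <- .safe_ratio(cc$TP, cc$TP + cc$FN)
    if (is.na(p) || is.na(r) || (p + r) == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  per_class <- vapply(per_class_confusions, f1_of, numeric(1))
  support <- vapply(per_class_confusions, function(cc) cc$TP + cc$FN, numeric(1))
  tp <- sum(vapply(per_class_confusions, function(cc) cc$TP, numeric(1)))
  fp <- sum(vapply(per_class_confusions, function(cc) cc$FP, numeric(1)))
  fn <- sum(vapply(per_class_confusions, function(cc) cc$FN, numeric(1)))
  micro_p <- .safe_ratio(tp, tp + fp)
  micro_r <- .safe_ratio(tp, tp + fn)
  micro <- if (is.na(micro_p) || is.na(micro_r) || (micro_p + micro_r) == 0)
    NA_real_ else 2 * micro_p * micro_r / (micro_p + micro_r)
  list(per_class = per_class,
       macro = mean(per_class, na.rm = TRUE),
       weighted = sum(per_class * support, na.rm = TRUE) /
         sum(support[!is.na(per_class)]),
       micro = micro)
}

# Trapezoidal area under the full ROC curve.
.auroc_trapezoid <- function(scores, labels) {
  pos <- labels
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp_inc <- tapply(as.numeric(y), grp, sum)
  fp_inc <- tapply(as.numeric(!y), grp, sum)
  tpr <- c(0, cumsum(tp_inc)) / sum(pos)
  fpr <- c(0, cumsum(fp_inc)) / sum(!pos)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Mann-Whitney formulation with ties counted 1/2.
.auroc_rank <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the ROC curve
#'
#' Computes the AUROC both as the trapezoidal area over all score
#' thresholds and as the normalized Mann-Whitney statistic (tied pairs
#' counted 1/2); the two are asserted equal before returning.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or coercible) positive-class indicators; both
#'   classes must be present.
#' @param method `"both"` (default; assert agreement), `"trapezoid"` or
#'   `"rank"`.
#' @return The AUROC in `[0, 1]`.
#' @export
roc_auroc <- function(scores, labels, method = c("both", "trapezoid", "rank")) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  switch(method,
    trapezoid = .auroc_trapezoid(scores, labels),
    rank = .auroc_rank(scores, labels),
    both = {
      a <- .auroc_trapezoid(scores, labels)
      b <- .auroc_rank(scores, labels)
      if (abs(a - b) > 1e-10)
        stop("internal error: AUROC formulations disagree")
      b
    })
}

#' Stratified percentile bootstrap CI for the AUROC
#'
#' Resamples positives and negatives separately with replacement; a
#' resample that loses a class is redrawn (bounded retries). Defaults to
#' 2,000 replicates at the 95% level.
#'
#' @param scores,labels As in [roc_auroc()].
#' @param reps Bootstrap replicates (>= 100).
#' @param alpha Two-sided miscoverage; 0.05 gives a 95% interval.
#' @param seed RNG seed.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, reps = 2000, alpha = 0.05,
                               seed = 1L) {
  labels <- as.logical(labels)
  if (reps < 100) stop("reps must be >= 100")
  ip <- which(labels);ineg <- which(!labels)
  .with_seed(seed, {
    stat <- vapply(seq_len(reps), function(r) {
      for (try in 1:100) {
        bp <- sample(ip, length(ip), replace = TRUE)
        bn <- sample(ineg, length(ineg), replace = TRUE)
        s <- c(scores[bp], scores[bn])
        l <- c(rep(TRUE, length(bp)), rep(FALSE, length(bn)))
        if (any(l) && !all(l)) return(.auroc_rank(s, l))
      }
      stop("could not draw a two-class resample")
    }, numeric(1))
    stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                    type = 7)
  })
}

#' PPV/NPV table over score cut-offs
#'
#' Dual-cut-off semantics: at cut-off `t`, samples with score `>= t` are
#' called positive and samples with score `<= 1 - t` are called negative;
#' samples in between abstain (so at stringent cut-offs the two call sets
#' do not partition the data). PPV is the percentage of positive calls
#' that are truly positive, NPV the percentage of negative calls that are
#' truly negative; an empty call set is reported as 0 with a flag.
#'
#' @param scores Probability scores in `[0, 1]`.
#' @param labels Logical positive-class indicators.
#' @param thresholds Cut-offs in `[0, 1]`, conventionally descending.
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_pred_pos`, `n_correct_pos`, `ppv`, `n_pred_neg`, `n_correct_neg`,
#'   `npv`, `empty_pos`, `empty_neg`.
#' @export
ppv_npv_table <- function(scores, labels, thresholds) {
  labels <- as.logical(labels)
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0,1]")
  eps <- 1e-9   # guard the complementary cut-off against fp rounding
  rows <- lapply(thresholds, function(t) {
    pos_call <- scores >= t - eps
    neg_call <- scores <= 1 - t + eps
    np <- sum(pos_call); ncp <- sum(pos_call & labels)
    nn <- sum(neg_call); ncn <- sum(neg_call & !labels)
    data.frame(threshold = t,
               n_pred_pos = np, n_correct_pos = ncp,
               ppv = if (np == 0) 0 else 100 * ncp / np,
               n_pred_neg = nn, n_correct_neg = ncn,
               npv = if (nn == 0) 0 else 100 * ncn / nn,
               empty_pos = np == 0, empty_neg = nn == 0)
  })
  do.call(rbind, rows)
}
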