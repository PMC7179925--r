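# Directional single-transcript threshold classifiers.
#
# For one transcript, the classifier assigns a sample to the class with
# the greater mean expression iff its value is >= a cut-point, and to the
# other class otherwise. The cut-point is chosen to maximize the point
# AUROC, defined as (sensitivity + specificity)/2 -- the trapezoidal area
# of the three-point ROC {(0,0), (FPR,TPR), (1,1)} of the fixed-threshold
# rule. Candidate cut-points are the observed unique expression values,
# swept from the minimum to the maximum.

# Fast core: returns direction, threshold, auroc, confusion, means, flag.
.fit_threshold_core <- function(vp, vn) {
  mp <- mean(vp); mn <- mean(vn)
  positive_high <- mp >= mn          # ties default to positive_high
  cand <- sort(unique(c(vp, vn)))
  np <- length(vp); nn <- length(vn)
  # counts >= t for each candidate t
  ge_p <- np - findInterval(cand, sort(vp), left.open = TRUE)
  ge_n <- nn - (findInterval(cand, sort(vn), left.open = TRUE))
  if (positive_high) {
    sens <- ge_p / np          # pos assigned pos iff value >= t
    spec <- (nn - ge_n) / nn   # neg assigned neg iff value < t
  } else {
    sens <- (np - ge_p) / np   # pos assigned pos iff value < t
    spec <- ge_n / nn
  }
  bal <- (sens + spec) / 2
  best <- which.max(bal)       # which.max takes the first (smallest t) tie
  degenerate <- mp == mn || length(cand) == 1L
  tp <- round(sens[best] * np); fn <- np - tp
  tn <- round(spec[best] * nn); fp <- nn - tn
  list(direction = if (positive_high) "positive_high" else "negative_high",
       threshold = cand[best],
       point_auroc = bal[best],
       confusion_at_threshold = confusion_counts_raw(tp, fp, tn, fn),
       mean_pos = mp, mean_neg = mn, degenerate = degenerate)
}

#' Fit a directional threshold classifier for one transcript
#'
#' @param values_pos,values_neg Numeric expression values (log2 scale by
#'   convention) of the positive and negative class samples; both
#'   non-empty and finite.
#' @param transcript_id Optional ID stored in the result.
#' @return An object of class `threshold_model`: `direction`
#'   (`positive_high` if the positive class has the greater mean),
#'   `threshold` (smallest maximizer on ties), `point_auroc`,
#'   `confusion_at_threshold`, class means, and a `degenerate` flag
#'   (constant values or exactly equal class means).
#' @examples
#' fit_threshold_model(c(5, 4, 3), c(1, 2, 0))   # separates perfectly at 3
#' @export
fit_threshold_model <- function(values_pos, values_neg, transcript_id = NA_character_) {
  if (length(values_pos) == 0 || length(values_neg) == 0)
    stop("both classes must be non-empty")
  if (!all(is.finite(values_pos)) || !all(is.finite(values_neg)))
    stop("non-finite expression value")
  core <- .fit_threshold_core(values_pos, values_neg)
  structure(c(list(transcript_id = transcript_id), core),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Threshold model%s: direction %s, threshold %.4g, point AUROC %.3f%s\n",
              if (is.na(x$transcript_id)) "" else paste0(" [", x$transcript_id, "]"),
              x$direction, x$threshold, x$point_auroc,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Rank all transcripts by threshold-model point AUROC
#'
#' Fits one directional threshold classifier per transcript and returns
#' the ranked table: highest point AUROC first, ties broken by transcript
#' ID. Optionally attaches two-sided Wilcoxon rank-sum p-values with
#' Benjamini-Hochberg adjustment.
#'
#' @param x An `expr_matrix` (log2 scale).
#' @param labels A `sample_labels` table.
#' @param positive_class,negative_class Class names; samples of other
#'   classes are dropped.
#' @param p_values Attach Wilcoxon p-values (default `TRUE`).
#' @return A data.frame of class `ranked_features` with columns
#'   `transcript_id`, `direction`, `threshold`, `point_auroc`,
#'   `mean_pos`, `mean_neg` and, when requested, `p_value`, `adjusted_p`.
#' @export
rank_features <- function(x, labels, positive_class = "early",
                          negative_class = "late", p_values = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  cls <- .classes_for(x, labels)
  pos <- cls == positive_class
  neg <- cls == negative_class
  if (!any(pos) || !any(neg))
    stop("both classes must be present among the matrix samples")
  vp_all <- x$values[, pos, drop = FALSE]
  vn_all <- x$values[, neg, drop = FALSE]
  n <- nrow(x$values)
  dir <- character(n); thr <- numeric(n); auc <- numeric(n)
  mp <- numeric(n); mn <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    core <- .fit_threshold_core(vp_all[i, ], vn_all[i, ])
    dir[i] <- core$direction; thr[i] <- core$threshold
    auc[i] <- core$point_auroc
    mp[i] <- core$mean_pos; mn[i] <- core$mean_neg
    degen[i] <- core$degenerate
  }
  tab <- data.frame(transcript_id = x$transcript_ids, direction = dir,
                    threshold = thr, point_auroc = auc,
                    mean_pos = mp, mean_neg = mn, degenerate = degen,
                    stringsAsFactors = FALSE)
  if (p_values) {
    wt <- wilcoxon_rank_test(x, labels, positive_class, negative_class)
    tab$p_value <- wt$p_value
    tab$adjusted_p <- wt$adjusted_p
  }
  ord <- order(-tab$point_auroc, tab$transcript_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("ranked_features", "data.frame"))
}

#' Extract an AUROC-cutoff panel from a ranked table
#'
#' Keeps the transcripts whose point AUROC is greater than or equal to
#' `cutoff` (inclusive boundary), preserving the ranking order. Typical
#' cutoffs: 0.60 for the early/late stage task, 0.85 for cancer/normal.
#'
#' @param table A `ranked_features` table.
#' @param cutoff AUROC cutoff in `[0, 1]`.
#' @return A `feature_panel`; an empty panel is allowed and flagged in its
#'   provenance.
#' @export
select_by_auroc <- function(table, cutoff = 0.60) {
  stopifnot(inherits(table, "ranked_features"))
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0,1]")
  keep <- table$point_auroc >= cutoff - 1e-12   # inclusive under fp rounding
  feature_panel(table$transcript_id[keep],
                method = "auroc_cutoff",
                parameters = list(cutoff = cutoff, empty = !any(keep)),
                scores = table$point_auroc[keep])
}

#' Per-transcript Wilcoxon rank-sum test between two classes
#'
#' Two-sided rank-sum p-value per transcript: exact when the combined
#' sample size is at most 25 and there are no ties, otherwise the normal
#' approximation with tie correction. Adjustment across transcripts is
#' Benjamini-Hochberg.
#'
#' @param x An `expr_matrix`.
#' @param labels A `sample_labels` table.
#' @param positive_class,negative_class Class names.
#' @return data.frame with `transcript_id`, `p_value`, `adjusted_p` in the
#'   matrix's row order.
#' @export
wilcoxon_rank_test <- function(x, labels, positive_class = "early",
                               negative_class = "late") {
  stopifnot(inherits(x, "expr_matrix"))
  cls <- .classes_for(x, labels)
  pos <- cls == positive_class
  neg <- cls == negative_class
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  if (sum(pos) < 2 || sum(neg) < 2) stop("each class needs n >= 2")
  p <- vapply(seq_len(nrow(x$values)), function(i) {
    vp <- x$values[i, pos]; vn <- x$values[i, neg]
    pooled <- c(vp, vn)
    if (length(unique(pooled)) == 1) return(1)   # no evidence either way
    exact <- length(pooled) <= 25 && !anyDuplicated(pooled)
    suppressWarnings(
      stats::wilcox.test(vp, vn, exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  data.frame(transcript_id = x$transcript_ids, p_value = p,
             adjusted_p = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Write a ranked feature table as TSV
#'
#' @param table A `ranked_features` table.
#' @param path Output path.
#' @export
write_ranked_features <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
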