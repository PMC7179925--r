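#' Log2 transform an FPKM matrix
#'
#' Applies `x <- log2(x + 1)` entrywise, the standard variance-stabilizing
#' transform for FPKM expression; the pseudocount of 1 keeps all
#' transformed values non-negative and maps structural zeros to 0.
#'
#' @param x An `expr_matrix` with `scale = "fpkm"`.
#' @return An `expr_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "fpkm") stop("log2_transform expects an FPKM-scale matrix")
  expression_matrix(log2(x$values + 1), scale = "log2")
}

#' Remove low-variance transcripts
#'
#' Retains transcripts whose sample variance (n-1 denominator) is at least
#' `min_variance`. Applied on the log2 scale, after the log transform and
#' before Z-scoring.
#'
#' @param x An `expr_matrix` (log2 scale).
#' @param min_variance Non-negative variance cutoff; 0.25 is the default
#'   for the early/late stage task, 0.02 for the cancer/normal task.
#' @return An `expr_matrix` with attribute `"report"` listing `n_removed`
#'   and `n_kept`.
#' @export
variance_filter <- function(x, min_variance = 0.25) {
  stopifnot(inherits(x, "expr_matrix"))
  if (min_variance < 0) stop("min_variance must be >= 0")
  v <- apply(x$values, 1L, stats::var)
  keep <- v >= min_variance
  out <- subset_matrix(x, transcripts = which(keep))
  attr(out, "report") <- list(n_removed = sum(!keep), n_kept = sum(keep))
  out
}

#' Fit per-transcript Z-score normalization statistics
#'
#' Records the training-partition mean and standard deviation (n-1
#' denominator, matching [variance_filter()]) of every transcript. These
#' frozen statistics are applied unchanged to held-out data.
#'
#' @param x An `expr_matrix` on the log2 scale with at least 2 samples.
#' @return A data.frame of class `norm_stats` with columns
#'   `transcript_id`, `mean`, `sd`; zero-sd transcripts are flagged in the
#'   logical column `zero_sd`.
#' @export
fit_zscore <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) stop("need >= 2 samples to fit z-score statistics")
  mu <- rowMeans(x$values)
  sdv <- apply(x$values, 1L, stats::sd)
  structure(data.frame(transcript_id = x$transcript_ids,
                       mean = unname(mu), sd = unname(sdv),
                       zero_sd = sdv == 0,
                       stringsAsFactors = FALSE),
            class = c("norm_stats", "data.frame"))
}

#' Apply frozen Z-score statistics to a matrix
#'
#' Each value becomes `(x - mean) / sd` using the *training* statistics in
#' `stats`, never the target matrix's own moments.
#'
#' @param x An `expr_matrix` (log2 scale).
#' @param stats A `norm_stats` table covering every transcript of `x`.
#' @return An `expr_matrix` with `scale = "zscore"`.
#' @export
apply_zscore <- function(x, stats) {
  stopifnot(inherits(x, "expr_matrix"), inherits(stats, "norm_stats"))
  idx <- match(x$transcript_ids, stats$transcript_id)
  if (anyNA(idx))
    stop("transcript(s) missing from normalization stats: ",
         paste(x$transcript_ids[is.na(idx)], collapse = ", "))
  mu <- stats$mean[idx]
  sdv <- stats$sd[idx]
  if (any(sdv == 0))
    stop("zero-sd transcript(s) cannot be z-scored: ",
         paste(x$transcript_ids[sdv == 0], collapse = ", "))
  expression_matrix((x$values - mu) / sdv, scale = "zscore")
}

#' Write / read normalization statistics as TSV
#'
#' @param stats A `norm_stats` table.
#' @param path File path.
#' @export
write_norm_stats <- function(stats, path) {
  utils::write.table(
    format(stats[c("transcript_id", "mean", "sd")], digits = 17,
           trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(data.frame(transcript_id = as.character(df$transcript_id),
                       mean = as.numeric(df$mean), sd = as.numeric(df$sd),
                       zero_sd = as.numeric(df$sd) == 0,
                       stringsAsFactors = FALSE),
            class = c("norm_stats", "data.frame"))
}

# Map one transcript's target values onto the reference's empirical
# quantiles. Rank positions are linear on rank/(n-1); target ties share
# the mean of their mapped values so the map stays deterministic and
# symmetric.
.qmap_row <- function(target, reference) {
  n_t <- length(target)
  ref_sorted <- sort(reference)
  n_r <- length(ref_sorted)
  if (n_t == 1) {
    # a single observation maps to the reference median
    return(stats::quantile(ref_sorted, 0.5, names = FALSE, type = 7))
  }
  r <- rank(target, ties.method = "average")
  p <- (r - 1) / (n_t - 1)
  mapped <- stats::quantile(ref_sorted, p, names = FALSE, type = 7)
  mapped
}

#' Feature-specific quantile normalization onto a reference cohort
#'
#' For every shared transcript, the target cohort's values are replaced by
#' the reference cohort's empirical quantiles at the corresponding ranks
#' (linear interpolation when the sample counts differ). Within each
#' transcript the rank order of target samples is preserved, so any
#' monotone cross-platform distortion is undone exactly.
#'
#' @param target,reference `expr_matrix` objects on the log2 scale;
#'   normalization runs on their shared transcript set (version suffixes
#'   stripped for matching).
#' @return An `expr_matrix` (log2 scale) with the target's samples and the
#'   shared transcripts, in target order.
#' @export
quantile_normalize_to_reference <- function(target, reference) {
  stopifnot(inherits(target, "expr_matrix"), inherits(reference, "expr_matrix"))
  t_key <- .strip_version(target$transcript_ids)
  r_key <- .strip_version(reference$transcript_ids)
  shared <- intersect(t_key, r_key)
  if (length(shared) == 0) stop("no shared transcripts between target and reference")
  if (ncol(reference$values) < 2)
    stop("reference must have >= 2 samples per transcript")
  t_idx <- match(shared, t_key)
  r_idx <- match(shared, r_key)
  out <- target$values[t_idx, , drop = FALSE]
  for (i in seq_along(shared)) {
    out[i, ] <- .qmap_row(target$values[t_idx[i], ],
                          reference$values[r_idx[i], ])
  }
  expression_matrix(out, scale = "log2")
}

#' Align a matrix to a feature panel
#'
#' Restricts and reorders the matrix rows to the panel's transcripts;
#' panel members absent from the matrix are returned so the caller can
#' decide to retrain on the intersection. ID version suffixes are stripped
#' for matching.
#'
#' @param x An `expr_matrix`.
#' @param panel A `feature_panel` or character vector of transcript IDs.
#' @return List with `matrix` (rows in panel order, intersection only) and
#'   `missing` (panel IDs not found).
#' @export
align_features <- function(x, panel) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- if (inherits(panel, "feature_panel")) panel$transcript_ids else panel
  m_key <- .strip_version(x$transcript_ids)
  p_key <- .strip_version(ids)
  idx <- match(p_key, m_key)
  missing <- ids[is.na(idx)]
  found <- idx[!is.na(idx)]
  if (length(found) == 0)
    stop("no panel transcript found in the matrix")
  list(matrix = subset_matrix(x, transcripts = found), missing = missing)
}
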