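#' Construct an expression matrix
#'
#' The universal payload between pipeline stages: a numeric matrix with
#' transcripts as rows and samples as columns, plus a scale tag recording
#' which transform has been applied.
#'
#' @param values Numeric matrix, transcripts x samples, with rownames
#'   (transcript IDs) and colnames (sample IDs).
#' @param scale One of `"fpkm"`, `"log2"`, `"zscore"`.
#' @return An object of class `expr_matrix` with elements `values`,
#'   `transcript_ids`, `sample_ids` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("fpkm", "log2", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  tid <- rownames(values)
  sid <- colnames(values)
  if (is.null(tid) && nrow(values) == 0) tid <- character(0)
  if (is.null(sid) && ncol(values) == 0) sid <- character(0)
  if (is.null(tid) || is.null(sid))
    stop("`values` must carry transcript rownames and sample colnames")
  rownames(values) <- tid
  colnames(values) <- sid
  if (anyDuplicated(tid))
    stop("duplicate transcript IDs: ",
         paste(unique(tid[duplicated(tid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (scale == "fpkm" && any(values < 0))
    stop("FPKM values must be non-negative")
  structure(
    list(values = values, transcript_ids = tid, sample_ids = sid,
         scale = scale),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d transcripts x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by transcripts and/or samples
#'
#' @param x An `expr_matrix`.
#' @param transcripts,samples Character vectors of IDs (or logical/integer
#'   indices) to keep, in the requested order. `NULL` keeps everything.
#' @return An `expr_matrix` on the same scale.
#' @export
subset_matrix <- function(x, transcripts = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(transcripts)) v <- v[transcripts, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, scale = x$scale)
}

#' Read an FPKM expression matrix from delimited text
#'
#' Expects the GDC HTSeq-FPKM dialect: first column transcript IDs, header
#' row sample IDs, numeric non-negative body.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return An `expr_matrix` with `scale = "fpkm"`; row/column order as on
#'   disk.
#' @export
read_fpkm_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs a transcript column and at least one sample")
  tid <- df[[1L]]
  if (anyDuplicated(tid))
    stop("duplicate transcript ID in ", path, ": ",
         paste(unique(tid[duplicated(tid)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at transcript '%s', sample '%s'",
                 tid[bad[1L]], colnames(df)[-1L][bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative FPKM at transcript '%s', sample '%s'",
                 tid[bad[1L]], colnames(df)[-1L][bad[2L]]))
  }
  rownames(num) <- tid
  colnames(num) <- colnames(df)[-1L]
  expression_matrix(num, scale = "fpkm")
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_fpkm_matrix()]; the round trip is value-exact (values
#' are written with full double precision).
#'
#' @param x An `expr_matrix`.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(x, "expr_matrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(transcript_id = x$transcript_ids,
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical stage strings -> merged class
.parse_stage <- function(stage) {
  s <- tolower(trimws(stage))
  s <- sub("^stage[ _-]*", "", s)
  map <- c("i" = "I", "1" = "I", "ii" = "II", "2" = "II",
           "iii" = "III", "3" = "III", "iv" = "IV", "4" = "IV",
           "normal" = "normal")
  out <- unname(map[s])
  if (anyNA(out))
    stop("unrecognized stage value(s): ",
         paste(unique(stage[is.na(out)]), collapse = ", "))
  out
}

#' Derive the merged class from a raw stage label
#'
#' Stages I and II are pooled as `early`, III and IV as `late`; `normal`
#' is kept as its own class.
#'
#' @param raw_stage Character vector of `I`..`IV` / `normal`.
#' @return Character vector of `early` / `late` / `normal`.
#' @export
stage_to_class <- function(raw_stage) {
  c("I" = "early", "II" = "early", "III" = "late", "IV" = "late",
    "normal" = "normal")[raw_stage]
}

#' Read sample stage labels
#'
#' Two-column delimited table `sample_id`, `stage`. Stage spellings are
#' tolerant: roman or arabic numerals, with or without a "stage" prefix,
#' case-insensitive.
#'
#' @param path File path (TSV).
#' @return A `data.frame` of class `sample_labels` with columns
#'   `sample_id`, `raw_stage` (I/II/III/IV/normal) and `class`
#'   (early/late/normal).
#' @export
read_stage_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("label file needs sample_id and stage columns")
  sample_labels(df[[1L]], df[[2L]])
}

#' Construct sample labels from raw stage strings
#'
#' @param sample_id Character vector of unique sample IDs.
#' @param stage Raw stage strings (see [read_stage_labels()]) or already
#'   merged classes `early`/`late`/`normal`.
#' @return A `sample_labels` data.frame.
#' @export
sample_labels <- function(sample_id, stage) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  s <- tolower(trimws(stage))
  if (all(s %in% c("early", "late", "normal"))) {
    raw <- ifelse(s == "normal", "normal", NA_character_)
    cls <- s
  } else {
    raw <- .parse_stage(stage)
    cls <- unname(stage_to_class(raw))
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       raw_stage = raw, class = cls,
                       stringsAsFactors = FALSE),
            class = c("sample_labels", "data.frame"))
}

# class vector aligned to an expr_matrix's samples
.classes_for <- function(x, labels) {
  idx <- match(x$sample_ids, labels$sample_id)
  if (anyNA(idx))
    stop("unlabelled sample(s): ",
         paste(x$sample_ids[is.na(idx)], collapse = ", "))
  labels$class[idx]
}

#' Read a transcript-to-biotype annotation table
#'
#' @param path Two-column TSV (`transcript_id`, `biotype`).
#' @return Named character vector mapping transcript ID to biotype.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Restrict an expression matrix to transcripts of given biotypes
#'
#' Transcripts missing from the annotation are excluded and counted rather
#' than silently dropped.
#'
#' @param x An `expr_matrix`.
#' @param annotation Named character vector (ID -> biotype), e.g. from
#'   [read_annotation()].
#' @param biotypes Character vector of biotypes to keep.
#' @return An `expr_matrix` with attribute `"report"`: a list with
#'   `n_kept`, `n_removed` and `n_unannotated`.
#' @export
filter_by_biotype <- function(x, annotation, biotypes) {
  stopifnot(inherits(x, "expr_matrix"))
  bt <- annotation[x$transcript_ids]
  unannot <- is.na(bt)
  keep <- !unannot & bt %in% biotypes
  out <- subset_matrix(x, transcripts = which(keep))
  attr(out, "report") <- list(n_kept = sum(keep),
                              n_removed = sum(!keep & !unannot),
                              n_unannotated = sum(unannot))
  out
}

#' Stratified train/validation split
#'
#' Per stratum, exactly `floor(train_fraction * n)` samples are drawn
#' uniformly (by `seed`) into the training partition; the remainder form
#' the validation partition. The stratification key is the raw four-level
#' stage when available, so that e.g. an 80:20 split of stage counts
#' 281/52/112/55/58 yields training sizes 224+41 = 265 early,
#' 89+44 = 133 late and 46 normal.
#'
#' @param x An `expr_matrix`.
#' @param labels A `sample_labels` table covering every sample of `x`.
#' @param train_fraction Fraction in (0,1); default 0.8.
#' @param seed Integer RNG seed; identical seeds give identical partitions.
#' @return List with elements `train` and `validation`, each a list of
#'   `matrix` (an `expr_matrix`) and `labels` (a `sample_labels` subset).
#' @export
stratified_split <- function(x, labels, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1)")
  idx <- match(x$sample_ids, labels$sample_id)
  if (anyNA(idx))
    stop("unlabelled sample(s): ",
         paste(x$sample_ids[is.na(idx)], collapse = ", "))
  lab <- labels[idx, , drop = FALSE]
  key <- ifelse(is.na(lab$raw_stage), lab$class, lab$raw_stage)
  train_ids <- .with_seed(seed, {
    out <- character(0)
    for (k in sort(unique(key))) {
      ids <- x$sample_ids[key == k]
      n_train <- floor(train_fraction * length(ids))
      if (n_train > 0)
        out <- c(out, sample(ids, n_train))
    }
    out
  })
  is_train <- x$sample_ids %in% train_ids
  subset_with_labels <- function(keep) {
    list(matrix = subset_matrix(x, samples = which(keep)),
         labels = structure(lab[keep, , drop = FALSE],
                            class = c("sample_labels", "data.frame")))
  }
  list(train = subset_with_labels(is_train),
       validation = subset_with_labels(!is_train))
}
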