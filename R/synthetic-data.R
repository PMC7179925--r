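# Synthetic FPKM expression datasets with planted stage-informative
# transcripts. The generator emulates the structure of a TCGA-style
# cohort -- non-negative FPKM with structural zeros, a few hundred tumor
# samples split into early/late stages plus a small normal group -- at a
# desk-scale feature count, so every pipeline stage can be exercised and
# its parameter recovery quantified offline.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: class
#' composition 333 early / 167 late / 58 normal, 2,000 transcripts
#' (scaled down from a transcriptome-wide 60,483), 36 planted
#' stage-informative transcripts with a 1.5-sd early/late shift.
#'
#' @param n_transcripts Number of transcript features.
#' @param n_informative Number of planted stage-informative transcripts.
#' @param class_sizes Named integer vector for classes
#'   `normal`, `early`, `late`.
#' @param effect_size_sd Mean log2 shift between early and late for
#'   planted transcripts, in units of the within-class sd.
#' @param normal_effect_sd Shift of planted transcripts between normal
#'   and tumor, same units.
#' @param baseline_log_mean,baseline_log_sd Lognormal baseline of
#'   transcript abundance on the log2 scale.
#' @param noise_sd Within-class sd of log2 expression.
#' @param dropout_rate Probability that a value is an exact 0 FPKM.
#' @param external_overlap_fraction Fraction of features shared with a
#'   generated external cohort.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_transcripts = 2000, n_informative = 36,
                              class_sizes = c(normal = 58, early = 333,
                                              late = 167),
                              effect_size_sd = 1.5, normal_effect_sd = 2.5,
                              baseline_log_mean = 3, baseline_log_sd = 1.5,
                              noise_sd = 1, dropout_rate = 0.05,
                              external_overlap_fraction = 0.5, seed = 1L) {
  if (n_informative > n_transcripts)
    stop("n_informative must not exceed n_transcripts")
  if (any(class_sizes < 0)) stop("class sizes must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0,1)")
  if (external_overlap_fraction <= 0 || external_overlap_fraction > 1)
    stop("external_overlap_fraction must be in (0,1]")
  structure(as.list(environment()), class = "sim_config")
}

# log2-scale class shift matrix for the planted transcripts
.planted_shifts <- function(direction, effect, normal_effect, classes) {
  shift <- matrix(0, nrow = length(direction), ncol = length(classes),
                  dimnames = list(NULL, classes))
  if ("late" %in% classes) shift[, "late"] <- direction * effect
  if ("normal" %in% classes) shift[, "normal"] <- -direction * normal_effect
  shift
}

#' Generate a labelled synthetic expression dataset
#'
#' Per transcript, a baseline log2 abundance is drawn from
#' `Normal(baseline_log_mean, baseline_log_sd)`; per sample the log2
#' value is baseline + class shift + `Normal(0, noise_sd)`, and the FPKM
#' value is `2^level - 1` clipped at 0 (effects are additive on the log2
#' scale, i.e. multiplicative fold changes on FPKM). Planted transcripts
#' shift the late class by `direction * effect_size_sd * noise_sd`
#' relative to early, and the normal class by
#' `-direction * normal_effect_sd * noise_sd`, giving a monotone
#' normal -> early -> late progression along each planted axis. Dropout
#' zeros are applied last.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset`: `matrix` (an
#'   `expr_matrix`, FPKM scale), `labels` (a `sample_labels` table) and
#'   `truth` (data.frame of planted transcript IDs, directions +1/-1 for
#'   up/down in late, and realized log2 effect sizes).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$class_sizes
  classes <- rep(names(cs), times = cs)
  n_s <- length(classes)
  n_t <- config$n_transcripts
  tid <- sprintf("TX%05d", seq_len(n_t))
  sid <- sprintf("S%04d", seq_len(n_s))
  .with_seed(config$seed, {
    baseline <- stats::rnorm(n_t, config$baseline_log_mean,
                             config$baseline_log_sd)
    informative <- sort(sample.int(n_t, config$n_informative))
    direction <- rep_len(c(1, -1), config$n_informative)
    shift <- matrix(0, n_t, n_s)
    if (config$n_informative > 0) {
      sh <- .planted_shifts(direction,
                            config$effect_size_sd * config$noise_sd,
                            config$normal_effect_sd * config$noise_sd,
                            unique(classes))
      for (cl in unique(classes))
        shift[informative, classes == cl] <- sh[, cl]
    }
    level <- baseline + shift +
      matrix(stats::rnorm(n_t * n_s, 0, config$noise_sd), n_t, n_s)
    fpkm <- pmax(2^level - 1, 0)
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_t * n_s) < config$dropout_rate, n_t, n_s)
      fpkm[drop] <- 0
    }
    rownames(fpkm) <- tid
    colnames(fpkm) <- sid
    truth <- data.frame(
      transcript_id = tid[informative],
      direction = direction,
      effect_size = rep(config$effect_size_sd * config$noise_sd,
                        length(informative)),
      stringsAsFactors = FALSE)
    structure(list(matrix = expression_matrix(fpkm, "fpkm"),
                   labels = sample_labels(sid, classes),
                   truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d transcripts x %d samples (%s), %d planted\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              paste(sprintf("%s=%d", names(table(x$labels$class)),
                            table(x$labels$class)), collapse = ", "),
              nrow(x$truth)))
  invisible(x)
}

#' Generate an external cohort sharing a feature subset
#'
#' Emulates a cross-platform external validation cohort: only
#' `external_overlap_fraction` of the source features are retained
#' (always including at least half of the planted truth set), every
#' retained feature receives a monotone platform distortion
#' (`log2' = a * log2 + b` with `a > 0`), and new samples are drawn from
#' the same generative model. Default composition is 17 early / 3 late,
#' the shape of a small external stage cohort.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param class_sizes Named sizes of the new cohort's classes.
#' @param seed Seed for the new draw (default: source seed + 1).
#' @return A `synthetic_dataset` whose matrix holds the distorted FPKM
#'   values; `truth` is restricted to the retained planted transcripts.
#' @export
generate_external_cohort <- function(dataset,
                                     class_sizes = c(early = 17, late = 3),
                                     seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  config <- dataset$config
  if (is.null(seed)) seed <- config$seed + 1L
  n_t <- config$n_transcripts
  n_keep <- max(1L, round(config$external_overlap_fraction * n_t))
  tid <- dataset$matrix$transcript_ids
  truth_idx <- match(dataset$truth$transcript_id, tid)
  .with_seed(seed, {
    n_truth_keep <- min(length(truth_idx),
                        max(ceiling(length(truth_idx) / 2),
                            round(config$external_overlap_fraction *
                                    length(truth_idx))))
    if (length(truth_idx) > 0 && n_truth_keep == 0)
      stop("feature overlap excludes all planted transcripts")
    keep_truth <- sort(sample(truth_idx, n_truth_keep))
    others <- setdiff(seq_len(n_t), truth_idx)
    keep_other <- sort(sample(others, max(0L, n_keep - n_truth_keep)))
    keep <- sort(c(keep_truth, keep_other))
    classes <- rep(names(class_sizes), times = class_sizes)
    n_s <- length(classes)
    sid <- sprintf("E%04d", seq_len(n_s))
    # regenerate expression for the retained transcripts, same baselines
    base_all <- .with_seed(config$seed,
                           stats::rnorm(n_t, config$baseline_log_mean,
                                        config$baseline_log_sd))
    direction <- dataset$truth$direction
    shift <- matrix(0, length(keep), n_s)
    planted_pos <- match(intersect(keep, truth_idx), keep)
    if (length(planted_pos) > 0) {
      dir_kept <- direction[match(keep[planted_pos], truth_idx)]
      sh <- .planted_shifts(dir_kept,
                            config$effect_size_sd * config$noise_sd,
                            config$normal_effect_sd * config$noise_sd,
                            unique(classes))
      for (cl in unique(classes))
        shift[planted_pos, classes == cl] <- sh[, cl]
    }
    level <- base_all[keep] + shift +
      matrix(stats::rnorm(length(keep) * n_s, 0, config$noise_sd),
             length(keep), n_s)
    # monotone per-feature platform distortion on the log2 scale
    a <- stats::runif(length(keep), 0.6, 1.4)
    b <- stats::runif(length(keep), -1, 1)
    level <- a * level + b
    fpkm <- pmax(2^level - 1, 0)
    rownames(fpkm) <- tid[keep]
    colnames(fpkm) <- sid
    truth <- dataset$truth[dataset$truth$transcript_id %in% tid[keep], ,
                           drop = FALSE]
    structure(list(matrix = expression_matrix(fpkm, "fpkm"),
                   labels = sample_labels(sid, classes),
                   truth = truth, config = config,
                   distortion = data.frame(transcript_id = tid[keep],
                                           scale = a, offset = b)),
              class = "synthetic_dataset")
  })
}

#' A tiny fixed worked example (4 transcripts x 6 samples)
#'
#' Hard-coded log2-scale values with known optimal thresholds and point
#' AUROCs, used in documentation and tests: transcript A separates the
#' classes perfectly at threshold 3; B reaches point AUROC 5/6 at
#' threshold 2; C is a perfectly separating down-regulated transcript;
#' D is constant (degenerate, point AUROC 0.5). No RNG is involved.
#'
#' @return A `synthetic_dataset` whose matrix is on the log2 scale.
#' @export
generate_worked_example <- function() {
  vals <- rbind(
    A = c(5, 4, 3, 1, 2, 0),
    B = c(3, 2, 2, 2, 1, 1),
    C = c(0, 1, 0, 2, 3, 4),
    D = c(2, 2, 2, 2, 2, 2))
  colnames(vals) <- sprintf("S%d", 1:6)
  classes <- c(rep("early", 3), rep("late", 3))
  truth <- data.frame(transcript_id = c("A", "B", "C"),
                      direction = c(-1, -1, 1),   # +1 = up in late
                      effect_size = NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(matrix = expression_matrix(vals, "log2"),
                 labels = sample_labels(colnames(vals), classes),
                 truth = truth, config = NULL),
            class = "synthetic_dataset")
}
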