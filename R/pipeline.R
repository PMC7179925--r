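# End-to-end orchestration of the analysis stages as reproducible runs:
# read -> preprocess -> rank/select -> train -> evaluate -> predict.
# Every run writes its resolved configuration next to its outputs so a
# rerun with the same config and seed is byte-identical.

#' Pipeline configuration
#'
#' Defaults encode the analysis' standard settings: log2(FPKM+1)
#' transform, variance cutoff 0.25 for the early/late stage task (0.02
#' for cancer/normal), AUROC panel cutoffs 0.60 / 0.85, an 80:20
#' stratified split and 10-fold cross-validation.
#'
#' @param matrix_path,labels_path,annotation_path Input file paths
#'   (annotation optional).
#' @param out_dir Output directory.
#' @param task `"early_late"`, `"cancer_normal"` or `"multiclass"`.
#' @param variance_cutoff Variance filter threshold; `NULL` picks the
#'   task default (0.25 stage, 0.02 cancer/normal).
#' @param auroc_cutoff Panel cutoff; `NULL` picks the task default
#'   (0.60 stage, 0.85 cancer/normal).
#' @param selection `"auroc"`, `"fcbf"`, `"anova"`, `"l1"`.
#' @param selection_k Top-k for ANOVA selection.
#' @param l1_penalty Penalty for L1 selection.
#' @param train_fraction Stratified split fraction.
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, labels_path = NULL,
                            annotation_path = NULL, out_dir = tempfile("run"),
                            task = c("early_late", "cancer_normal",
                                     "multiclass"),
                            variance_cutoff = NULL, auroc_cutoff = NULL,
                            selection = c("auroc", "fcbf", "anova", "l1"),
                            selection_k = 100, l1_penalty = 1,
                            train_fraction = 0.8, grid = grid_spec(),
                            seed = 1L) {
  task <- match.arg(task)
  selection <- match.arg(selection)
  if (is.null(variance_cutoff))
    variance_cutoff <- if (task == "cancer_normal") 0.02 else 0.25
  if (is.null(auroc_cutoff))
    auroc_cutoff <- if (task == "cancer_normal") 0.85 else 0.60
  structure(as.list(environment()), class = "pipeline_config")
}

# task -> (positive, negative) class names
.task_classes <- function(task) {
  switch(task,
         early_late = c("early", "late"),
         cancer_normal = c("cancer", "normal"),
         multiclass = c("normal", "early", "late"))
}

# for the cancer/normal task, early+late collapse into "cancer"
.task_labels <- function(labels, task) {
  if (task != "cancer_normal") return(labels)
  cls <- ifelse(labels$class == "normal", "normal", "cancer")
  out <- labels
  out$class <- cls
  structure(out, class = c("sample_labels", "data.frame"))
}

.write_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keep <- !vapply(config, is.null, logical(1))
  flat <- vapply(config[keep], function(v) {
    if (inherits(v, "grid_spec"))
      sprintf("gamma=%s;cost=%s;folds=%s;seed=%d",
              paste(v$gamma_values, collapse = ","),
              paste(v$cost_values, collapse = ","),
              as.character(v$folds), v$seed)
    else paste(as.character(v), collapse = ",")
  }, character(1))
  writeLines(c(sprintf("package_version=%s",
                       as.character(utils::packageVersion("oncostage"))),
               paste0(names(flat), "=", flat)),
             file.path(dir, "config.txt"))
}

# load inputs from paths or accept in-memory objects
.load_inputs <- function(config, matrix = NULL, labels = NULL) {
  if (is.null(matrix)) matrix <- read_fpkm_matrix(config$matrix_path)
  if (is.null(labels)) labels <- read_stage_labels(config$labels_path)
  list(matrix = matrix, labels = .task_labels(labels, config$task))
}

#' Rank transcripts and extract an AUROC-cutoff panel
#'
#' Runs read -> log2 -> variance filter -> threshold-model ranking and
#' writes `ranked.tsv`, `panel.tsv`, `counts.txt` (transcripts in / after
#' variance filter / in panel) and the resolved `config.txt` to the
#' output directory.
#'
#' @param config A [pipeline_config()].
#' @param matrix,labels Optional in-memory `expr_matrix` /
#'   `sample_labels` overriding the configured paths.
#' @return Invisibly, a list with the `ranked_features` table and the
#'   `feature_panel`.
#' @export
pipeline_rank <- function(config, matrix = NULL, labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- .load_inputs(config, matrix, labels)
  .write_config(config, config$out_dir)
  classes <- .task_classes(config$task)
  lg <- if (inp$matrix$scale == "fpkm") log2_transform(inp$matrix) else inp$matrix
  filt <- variance_filter(lg, config$variance_cutoff)
  ranked <- rank_features(filt, inp$labels, positive_class = classes[1],
                          negative_class = classes[2])
  panel <- select_by_auroc(ranked, config$auroc_cutoff)
  write_ranked_features(ranked, file.path(config$out_dir, "ranked.tsv"))
  write_panel(panel, file.path(config$out_dir, "panel.tsv"))
  writeLines(sprintf(c("transcripts_in=%d", "after_variance_filter=%d",
                       "in_panel=%d"),
                     c(nrow(inp$matrix$values), nrow(filt$values),
                       length(panel))),
             file.path(config$out_dir, "counts.txt"))
  invisible(list(ranked = ranked, panel = panel))
}

#' Split, select, train and evaluate a stage model
#'
#' Full training pipeline: stratified 80:20 split, preprocessing with
#' training-frozen statistics, feature selection on the training
#' partition only, grid-searched RBF classifier, and evaluation on
#' training and validation partitions (per-class one-vs-rest reports for
#' the multiclass task). The fitted model is archived as plain text
#' under `model/` in the output directory, with JSON metric reports
#' alongside.
#'
#' @inheritParams pipeline_rank
#' @return Invisibly, a list with `model` (a `stage_model`), `reports`
#'   and the `split`.
#' @export
pipeline_train <- function(config, matrix = NULL, labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- .load_inputs(config, matrix, labels)
  .write_config(config, config$out_dir)
  classes <- .task_classes(config$task)
  lg <- if (inp$matrix$scale == "fpkm") log2_transform(inp$matrix) else inp$matrix
  filt <- variance_filter(lg, config$variance_cutoff)
  split <- stratified_split(filt, inp$labels, config$train_fraction,
                            config$seed)
  tr <- split$train; va <- split$validation
  panel <- .select_panel(config, tr$matrix, tr$labels, classes)
  if (config$task == "multiclass") {
    model <- train_multiclass_ovr(tr$matrix, tr$labels, panel, config$grid,
                                  classes = classes)
    reports <- list(
      train = .ovr_reports(model, tr$matrix, tr$labels),
      validation = .ovr_reports(model, va$matrix, va$labels))
  } else {
    model <- train_binary(tr$matrix, tr$labels, panel, config$grid,
                          positive_class = classes[1],
                          negative_class = classes[2])
    reports <- list(
      train = .binary_report(model, tr$matrix, tr$labels),
      validation = .binary_report(model, va$matrix, va$labels))
  }
  write_stage_model(model, file.path(config$out_dir, "model"))
  jsonlite::write_json(.reports_json(reports),
                       file.path(config$out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, reports = reports, split = split,
                 panel = panel))
}

.select_panel <- function(config, train_matrix, train_labels, classes) {
  switch(config$selection,
    auroc = {
      ranked <- rank_features(train_matrix, train_labels,
                              positive_class = classes[1],
                              negative_class = classes[2],
                              p_values = FALSE)
      select_by_auroc(ranked, config$auroc_cutoff)
    },
    fcbf = fcbf_select(train_matrix, train_labels,
                       positive_class = classes[1],
                       negative_class = classes[2]),
    anova = anova_f_select(train_matrix, train_labels, config$selection_k),
    l1 = {
      st <- fit_zscore(train_matrix)
      ok <- !st$zero_sd
      z <- apply_zscore(subset_matrix(train_matrix, transcripts = which(ok)),
                        st[ok, , drop = FALSE])
      l1_linear_select(z, train_labels, config$l1_penalty,
                       positive_class = classes[1],
                       negative_class = classes[2])
    })
}

.binary_report <- function(model, matrix, labels) {
  s <- predict_scores(model, matrix)
  cls <- .classes_for(matrix, labels)
  truth <- cls == model$positive_class
  rep <- compute_metrics(confusion_counts(truth,
                                          s >= model$decision_threshold))
  rep$auroc <- roc_auroc(s, truth)
  rep$auroc_ci <- bootstrap_auroc_ci(s, truth, seed = 1L)
  rep$ppv_npv <- ppv_npv_table(s, truth, seq(1.0, 0.6, by = -0.05))
  rep
}

.ovr_reports <- function(model, matrix, labels) {
  sc <- predict(model, matrix, type = "score")
  pred <- colnames(sc)[max.col(sc, ties.method = "first")]
  cls <- .classes_for(matrix, labels)
  out <- lapply(model$classes, function(cl) {
    rep <- compute_metrics(confusion_counts(cls == cl, pred == cl))
    rep$auroc <- roc_auroc(sc[, cl], cls == cl)
    rep$auroc_ci <- bootstrap_auroc_ci(sc[, cl], cls == cl, seed = 1L)
    rep
  })
  names(out) <- model$classes
  out
}

.report_json_one <- function(r) {
  list(TP = r$counts$TP, FP = r$counts$FP, TN = r$counts$TN,
       FN = r$counts$FN, recall = r$sensitivity, precision = r$precision,
       specificity = r$specificity, accuracy = r$accuracy, mcc = r$mcc,
       auroc = r$auroc, auroc_ci = r$auroc_ci, f1_micro = r$f1$micro,
       f1_macro = r$f1$macro, f1_per_class = r$f1$per_class)
}

.reports_json <- function(reports) {
  serialize_level <- function(node) {
    if (inherits(node, "metric_report")) return(.report_json_one(node))
    if (is.list(node)) return(lapply(node, serialize_level))
    node
  }
  serialize_level(reports)
}

#' Predict new samples with an archived model
#'
#' Applies the stored preprocessing chain to a new FPKM (or log2) matrix
#' and writes per-sample predictions with scores. When a reference
#' matrix is supplied, the input is first harmonized with
#' feature-specific quantile normalization onto the reference (the
#' cross-cohort path).
#'
#' @param model A `stage_model` or the path of a model archive
#'   directory.
#' @param matrix An `expr_matrix` or the path of a matrix file.
#' @param out_dir Optional output directory for `predictions.tsv`.
#' @param threshold Optional decision-threshold override.
#' @param reference Optional reference `expr_matrix` (log2 scale) for
#'   quantile harmonization.
#' @return data.frame with `sample_id`, `score`, `predicted_class`,
#'   `out_of_distribution`.
#' @export
pipeline_predict <- function(model, matrix, out_dir = NULL,
                             threshold = NULL, reference = NULL) {
  if (is.character(model)) model <- read_stage_model(model)
  if (is.character(matrix)) matrix <- read_fpkm_matrix(matrix)
  if (!is.null(reference)) {
    lg <- if (matrix$scale == "fpkm") log2_transform(matrix) else matrix
    matrix <- quantile_normalize_to_reference(lg, reference)
  }
  if (model$kind == "svm_rbf_ovr") {
    sc <- predict(model, matrix, type = "score")
    pred <- colnames(sc)[max.col(sc, ties.method = "first")]
    out <- data.frame(sample_id = rownames(sc),
                      score = apply(sc, 1, max),
                      predicted_class = pred,
                      out_of_distribution = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    s <- predict_scores(model, matrix)
    thr <- if (is.null(threshold)) model$decision_threshold else threshold
    out <- data.frame(
      sample_id = names(s), score = as.numeric(s),
      predicted_class = ifelse(s >= thr, model$positive_class,
                               setdiff(model$classes,
                                       model$positive_class)[1]),
      out_of_distribution = attr(s, "ood"),
      stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
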