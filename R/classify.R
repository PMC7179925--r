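# RBF-kernel margin classifiers over a feature panel, with frozen
# per-feature normalization statistics and a tunable decision threshold.
# The deployable unit (`stage_model`) bundles panel + stats + fitted
# classifier + classes + threshold, so prediction can start from raw FPKM.

#' Hyperparameter grid specification
#'
#' @param gamma_values RBF kernel widths; default log-spaced over
#'   `[1e-3, 10]`.
#' @param cost_values Soft-margin costs; default integers 1..10.
#' @param folds Cross-validation folds (>= 2) or `"loo"`.
#' @param seed RNG seed for fold assignment.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(gamma_values = 10^(-3:1), cost_values = 1:10,
                      folds = 10, seed = 1L) {
  if (!identical(folds, "loo") && folds < 2) stop("folds must be >= 2 or 'loo'")
  structure(list(gamma_values = gamma_values, cost_values = cost_values,
                 folds = folds, seed = as.integer(seed)),
            class = "grid_spec")
}

# prepare a samples x features design matrix from a model-ready chain:
# fpkm -> log2 -> panel restriction -> frozen z-score
.design_matrix <- function(x, panel_ids, stats) {
  if (x$scale == "fpkm") x <- log2_transform(x)
  if (x$scale != "log2" && x$scale != "zscore")
    stop("matrix must be on fpkm, log2 or zscore scale")
  m_key <- .strip_version(x$transcript_ids)
  idx <- match(.strip_version(panel_ids), m_key)
  if (anyNA(idx))
    stop("panel feature(s) missing from matrix: ",
         paste(panel_ids[is.na(idx)], collapse = ", "),
         "; use align_features() and retrain on the intersection")
  sub <- subset_matrix(x, transcripts = idx)
  if (x$scale == "log2") sub <- apply_zscore_ids(sub, stats, panel_ids)
  t(sub$values)
}

# apply_zscore keyed on version-stripped IDs so external cohorts match
apply_zscore_ids <- function(x, stats, panel_ids) {
  idx <- match(.strip_version(x$transcript_ids),
               .strip_version(stats$transcript_id))
  if (anyNA(idx)) stop("transcript(s) missing from normalization stats")
  mu <- stats$mean[idx]; sdv <- stats$sd[idx]
  if (any(sdv == 0))
    stop("zero-sd transcript(s) cannot be z-scored: ",
         paste(x$transcript_ids[sdv == 0], collapse = ", "))
  expression_matrix((x$values - mu) / sdv, scale = "zscore")
}

#' Grid search with stratified cross-validation
#'
#' For every (gamma, cost) cell, stratified k-fold cross-validated mean
#' accuracy of an RBF margin classifier; the winning cell maximizes CV
#' accuracy with ties broken by smaller cost then smaller gamma.
#'
#' @param x An `expr_matrix` on the z-score scale, restricted to a panel.
#' @param labels A `sample_labels` table.
#' @param grid A [grid_spec()].
#' @return List with `best_gamma`, `best_cost` and `table` (per-cell CV
#'   accuracy).
#' @export
grid_search_cv <- function(x, labels, grid = grid_spec()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(grid, "grid_spec"))
  cls <- .classes_for(x, labels)
  y <- factor(cls)
  k <- if (identical(grid$folds, "loo")) length(y) else grid$folds
  fold_id <- .stratified_folds(cls, k, grid$seed)
  for (f in seq_len(k)) {
    if (length(unique(cls[fold_id != f])) < 2)
      stop("a training fold contains a single class; ",
           "use stratification-compatible fold counts or larger folds")
  }
  X <- t(x$values)
  cells <- expand.grid(gamma = grid$gamma_values, cost = grid$cost_values)
  acc <- vapply(seq_len(nrow(cells)), function(ci) {
    correct <- 0
    for (f in seq_len(k)) {
      tr <- fold_id != f
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        gamma = cells$gamma[ci], cost = cells$cost[ci],
                        scale = FALSE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  ord <- order(-acc, cells$cost, cells$gamma)
  best <- ord[1]
  list(best_gamma = cells$gamma[best], best_cost = cells$cost[best],
       table = cbind(cells, cv_accuracy = acc))
}

#' Train a binary RBF margin stage classifier
#'
#' Runs the full chain on the training matrix: log2 transform (if given
#' FPKM), panel restriction, per-feature z-score statistics frozen from
#' the training data, grid search for (gamma, cost), and a final RBF
#' classifier with monotone (sigmoid) probability calibration fitted on
#' training folds.
#'
#' @param x Training `expr_matrix` (fpkm or log2 scale).
#' @param labels A `sample_labels` table; exactly the two classes named
#'   below are used.
#' @param panel A `feature_panel` or character vector of transcript IDs.
#' @param grid A [grid_spec()].
#' @param positive_class,negative_class Class names (defaults
#'   early/late); `positive_class` is the class whose probability
#'   [predict_scores()] reports.
#' @param decision_threshold Score threshold for calling the positive
#'   class (inclusive); default 0.5.
#' @return An object of class `stage_model`.
#' @export
train_binary <- function(x, labels, panel, grid = grid_spec(),
                         positive_class = "early", negative_class = "late",
                         decision_threshold = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- if (inherits(panel, "feature_panel")) panel$transcript_ids else as.character(panel)
  if (x$scale == "fpkm") x <- log2_transform(x)
  cls <- .classes_for(x, labels)
  keep_s <- which(cls %in% c(positive_class, negative_class))
  if (length(unique(cls[keep_s])) < 2) stop("need both classes to train")
  m_key <- .strip_version(x$transcript_ids)
  idx <- match(.strip_version(ids), m_key)
  if (anyNA(idx))
    stop("panel feature(s) missing from matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  train_m <- subset_matrix(x, transcripts = idx, samples = keep_s)
  stats <- fit_zscore(train_m)
  if (any(stats$zero_sd))
    stop("zero-variance panel feature(s) in the training data: ",
         paste(stats$transcript_id[stats$zero_sd], collapse = ", "))
  z <- apply_zscore(train_m, stats)
  y <- factor(cls[keep_s], levels = c(positive_class, negative_class))
  lab_sub <- sample_labels(train_m$sample_ids, as.character(y))
  gs <- grid_search_cv(z, lab_sub, grid)
  X <- t(z$values)
  fit <- .with_seed(grid$seed, {
    e1071::svm(X, y, kernel = "radial", gamma = gs$best_gamma,
               cost = gs$best_cost, probability = TRUE, scale = FALSE)
  })
  structure(list(kind = "svm_rbf_binary", panel = ids, stats = stats,
                 classifier = fit, classes = levels(y),
                 positive_class = positive_class,
                 decision_threshold = decision_threshold,
                 grid_summary = list(best_gamma = gs$best_gamma,
                                     best_cost = gs$best_cost,
                                     cv_accuracy = max(gs$table$cv_accuracy))),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("Stage model (%s): %d-feature panel, classes %s, threshold %.2f\n",
              x$kind, length(x$panel), paste(x$classes, collapse = "/"),
              x$decision_threshold))
  invisible(x)
}

#' @export
summary.stage_model <- function(object, ...) {
  print(object)
  cat(sprintf("  grid choice: gamma=%g cost=%g (CV accuracy %.3f)\n",
              object$grid_summary$best_gamma, object$grid_summary$best_cost,
              object$grid_summary$cv_accuracy))
  cat("  panel:", paste(utils::head(object$panel, 10), collapse = ", "),
      if (length(object$panel) > 10) "..." else "", "\n")
  invisible(object)
}

#' Probability scores for new samples
#'
#' Applies the model's own preprocessing chain (log2 transform when given
#' FPKM, panel restriction, frozen training z-score) and returns the
#' calibrated probability of the positive class. Samples whose
#' standardized expression exceeds |z| > 6 for any panel feature are
#' flagged as out-of-distribution in the `"ood"` attribute (scores are
#' still returned).
#'
#' @param model A `stage_model`.
#' @param x An `expr_matrix` (fpkm or log2 scale; zscore accepted as-is).
#' @return Named numeric vector of scores in `[0, 1]`, one per sample;
#'   attribute `"ood"` is a logical vector.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "stage_model"), inherits(x, "expr_matrix"))
  X <- .design_matrix(x, model$panel, model$stats)
  ood <- apply(abs(X) > 6, 1L, any)
  if (model$kind == "svm_rbf_binary") {
    pr <- attr(stats::predict(model$classifier, X, probability = TRUE),
               "probabilities")
    s <- pr[, model$positive_class]
  } else {
    sc <- .ovr_scores(model, X)
    s <- sc[, model$positive_class]
  }
  names(s) <- rownames(X)
  attr(s, "ood") <- unname(ood)
  s
}

#' Predict classes or scores for new samples
#'
#' @param object A `stage_model`.
#' @param newdata An `expr_matrix`.
#' @param type `"class"` (default) or `"score"`.
#' @param threshold Optional override of the stored decision threshold
#'   (binary models); a sample is called positive iff its score is
#'   greater than or equal to the threshold (inclusive).
#' @param ... Unused.
#' @return Character vector of classes, or scores (binary: vector;
#'   multiclass: per-class score matrix).
#' @export
predict.stage_model <- function(object, newdata, type = c("class", "score"),
                                threshold = NULL, ...) {
  type <- match.arg(type)
  if (object$kind == "svm_rbf_ovr") {
    X <- .design_matrix(newdata, object$panel, object$stats)
    sc <- .ovr_scores(object, X)
    if (type == "score") return(sc)
    cls <- colnames(sc)[max.col(sc, ties.method = "first")]
    names(cls) <- rownames(X)
    return(cls)
  }
  s <- predict_scores(object, newdata)
  if (type == "score") return(s)
  thr <- if (is.null(threshold)) object$decision_threshold else threshold
  out <- ifelse(s >= thr, object$positive_class,
                setdiff(object$classes, object$positive_class)[1])
  names(out) <- names(s)
  out
}

#' Choose a decision threshold balancing recall and specificity
#'
#' Over the unique observed scores, selects the threshold minimizing
#' `|recall - specificity|`, breaking ties by maximum accuracy and then
#' by the smallest threshold. Constant scores return 0.5 with a
#' `"degenerate"` attribute.
#'
#' @param scores Probability scores.
#' @param labels Logical (or coercible) positive-class indicators; both
#'   classes must be present.
#' @return The chosen threshold (positive call iff score >= threshold).
#' @export
choose_decision_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  cand <- sort(unique(scores))
  if (length(cand) == 1) {
    out <- 0.5
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  stats_at <- vapply(cand, function(t) {
    pos_call <- scores >= t
    recall <- sum(pos_call & labels) / n_pos
    spec <- sum(!pos_call & !labels) / n_neg
    acc <- (sum(pos_call & labels) + sum(!pos_call & !labels)) / length(labels)
    c(diff = abs(recall - spec), acc = acc)
  }, numeric(2))
  ord <- order(stats_at["diff", ], -stats_at["acc", ], cand)
  cand[ord[1]]
}

.ovr_scores <- function(model, X) {
  sc <- vapply(model$classes, function(cl) {
    pr <- attr(stats::predict(model$classifiers[[cl]], X, probability = TRUE),
               "probabilities")
    pr[, "yes"]
  }, numeric(nrow(X)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1, dimnames = list(NULL, model$classes))
  rownames(sc) <- rownames(X)
  sc
}

#' Train a one-vs-rest multiclass stage classifier
#'
#' Fits one binary RBF scorer per class (class vs rest, each with its
#' own probability calibration); the predicted class is the argmax of the
#' per-class scores, which are also exposed for per-class ROC analysis.
#'
#' @inheritParams train_binary
#' @param classes Class order for reports; default the sorted classes
#'   present.
#' @return A `stage_model` of kind `svm_rbf_ovr`.
#' @export
train_multiclass_ovr <- function(x, labels, panel, grid = grid_spec(),
                                 classes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- if (inherits(panel, "feature_panel")) panel$transcript_ids else as.character(panel)
  if (x$scale == "fpkm") x <- log2_transform(x)
  cls <- .classes_for(x, labels)
  if (is.null(classes)) classes <- sort(unique(cls))
  k <- if (identical(grid$folds, "loo")) length(cls) else grid$folds
  small <- table(cls)[table(cls) < k]
  if (length(small) > 0)
    stop("class(es) with fewer samples than folds: ",
         paste(names(small), collapse = ", "))
  idx <- match(.strip_version(ids), .strip_version(x$transcript_ids))
  if (anyNA(idx)) stop("panel feature(s) missing from matrix")
  train_m <- subset_matrix(x, transcripts = idx)
  stats <- fit_zscore(train_m)
  if (any(stats$zero_sd)) stop("zero-variance panel feature(s)")
  z <- apply_zscore(train_m, stats)
  X <- t(z$values)
  gs <- grid_search_cv(z, labels, grid)
  classifiers <- lapply(classes, function(cl) {
    yb <- factor(ifelse(cls == cl, "yes", "no"), levels = c("yes", "no"))
    .with_seed(grid$seed, {
      e1071::svm(X, yb, kernel = "radial", gamma = gs$best_gamma,
                 cost = gs$best_cost, probability = TRUE, scale = FALSE)
    })
  })
  names(classifiers) <- classes
  structure(list(kind = "svm_rbf_ovr", panel = ids, stats = stats,
                 classifiers = classifiers, classes = classes,
                 positive_class = classes[1],
                 decision_threshold = 0.5,
                 grid_summary = list(best_gamma = gs$best_gamma,
                                     best_cost = gs$best_cost,
                                     cv_accuracy = max(gs$table$cv_accuracy))),
            class = "stage_model")
}

#' Stratified k-fold / leave-one-out cross-validation
#'
#' Each sample is tested exactly once; the pooled confusion across folds
#' (total = n) is reported together with the per-fold reports and the
#' pooled AUROC of the held-out scores.
#'
#' @param x An `expr_matrix` (fpkm or log2).
#' @param labels A `sample_labels` table.
#' @param panel Feature panel (IDs or `feature_panel`).
#' @param gamma,cost Fixed RBF hyperparameters used in every fold (no
#'   nested grid search); `gamma = NULL` uses 1/panel size.
#' @param folds Integer >= 2 or `"loo"`.
#' @param seed RNG seed for fold assignment.
#' @param positive_class,negative_class The two classes.
#' @return List with `pooled` (a `metric_report` including AUROC),
#'   `per_fold` (list of `confusion_counts`), `scores` and `fold_id`.
#' @export
cross_validate <- function(x, labels, panel, gamma = NULL, cost = 1,
                           folds = 10, seed = 1L,
                           positive_class = "early",
                           negative_class = "late") {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- if (inherits(panel, "feature_panel")) panel$transcript_ids else as.character(panel)
  if (is.null(gamma)) gamma <- 1 / length(ids)
  if (x$scale == "fpkm") x <- log2_transform(x)
  cls <- .classes_for(x, labels)
  keep_s <- which(cls %in% c(positive_class, negative_class))
  xs <- subset_matrix(x, samples = keep_s)
  y <- factor(cls[keep_s], levels = c(positive_class, negative_class))
  n <- length(y)
  k <- if (identical(folds, "loo")) n else folds
  if (k > n) stop("more folds than samples")
  fold_id <- .stratified_folds(as.character(y), k, seed)
  idx <- match(.strip_version(ids), .strip_version(xs$transcript_ids))
  if (anyNA(idx)) stop("panel feature(s) missing from matrix")
  scores <- numeric(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    train_m <- subset_matrix(xs, transcripts = idx, samples = which(tr))
    st <- fit_zscore(train_m)
    ok <- !st$zero_sd
    z_tr <- apply_zscore(subset_matrix(train_m, transcripts = which(ok)),
                         st[ok, , drop = FALSE])
    fit <- .with_seed(seed + f, {
      e1071::svm(t(z_tr$values), y[tr], kernel = "radial", gamma = gamma,
                 cost = cost, probability = TRUE, scale = FALSE)
    })
    test_m <- subset_matrix(xs, transcripts = idx[ok], samples = which(!tr))
    z_te <- apply_zscore(test_m, st[ok, , drop = FALSE])
    pr <- attr(stats::predict(fit, t(z_te$values), probability = TRUE),
               "probabilities")
    scores[!tr] <- pr[, positive_class]
    per_fold[[f]] <- confusion_counts(y[!tr] == positive_class,
                                      pr[, positive_class] >= 0.5)
  }
  pooled_cc <- confusion_counts(y == positive_class, scores >= 0.5)
  pooled <- compute_metrics(pooled_cc)
  pooled$auroc <- roc_auroc(scores, y == positive_class)
  pooled$auroc_ci <- bootstrap_auroc_ci(scores, y == positive_class,
                                        reps = 2000, seed = seed)
  list(pooled = pooled, per_fold = per_fold, scores = scores,
       fold_id = fold_id)
}

#' Persist / restore a trained stage model as a plain-text archive
#'
#' The archive is a directory holding `manifest.json` (kind, classes,
#' threshold, grid summary, schema version), `panel.tsv`, `stats.tsv` and
#' the fitted classifier parameters deparsed to `classifier_*.txt` -- all
#' inspectable text. The round trip reproduces predictions exactly.
#'
#' @param model A `stage_model`.
#' @param dir Directory to create/write.
#' @export
write_stage_model <- function(model, dir) {
  stopifnot(inherits(model, "stage_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema = 1L, kind = model$kind, classes = model$classes,
                   positive_class = model$positive_class,
                   decision_threshold = model$decision_threshold,
                   grid_summary = model$grid_summary)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_panel(feature_panel(model$panel, method = "stored"),
              file.path(dir, "panel.tsv"))
  write_norm_stats(model$stats, file.path(dir, "stats.tsv"))
  dump_clf <- function(obj, path) {
    con <- file(path, "w")
    on.exit(close(con))
    dput(obj, file = con, control = c("all", "digits17"))
  }
  if (model$kind == "svm_rbf_binary") {
    dump_clf(model$classifier, file.path(dir, "classifier_binary.txt"))
  } else {
    for (cl in model$classes)
      dump_clf(model$classifiers[[cl]],
               file.path(dir, sprintf("classifier_%s.txt", cl)))
  }
  invisible(dir)
}

#' @rdname write_stage_model
#' @export
read_stage_model <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  panel <- read_panel(file.path(dir, "panel.tsv"))
  stats <- read_norm_stats(file.path(dir, "stats.tsv"))
  model <- list(kind = manifest$kind, panel = panel$transcript_ids,
                stats = stats, classes = manifest$classes,
                positive_class = manifest$positive_class,
                decision_threshold = manifest$decision_threshold,
                grid_summary = manifest$grid_summary)
  if (manifest$kind == "svm_rbf_binary") {
    model$classifier <- dget(file.path(dir, "classifier_binary.txt"))
  } else {
    model$classifiers <- lapply(manifest$classes, function(cl)
      dget(file.path(dir, sprintf("classifier_%s.txt", cl))))
    names(model$classifiers) <- manifest$classes
  }
  structure(model, class = "stage_model")
}
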