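# Multivariate feature selection over expression matrices.

#' Construct a feature panel
#'
#' An ordered set of selected transcript IDs with selection provenance.
#'
#' @param transcript_ids Character vector without duplicates.
#' @param method Name of the selecting method.
#' @param parameters Named list of method parameters.
#' @param scores Optional per-feature score vector aligned to
#'   `transcript_ids`.
#' @return An object of class `feature_panel`.
#' @export
feature_panel <- function(transcript_ids, method = "manual",
                          parameters = list(), scores = NULL) {
  transcript_ids <- as.character(transcript_ids)
  if (anyDuplicated(transcript_ids))
    stop("duplicate transcript IDs in panel")
  structure(list(transcript_ids = transcript_ids, method = method,
                 parameters = parameters, scores = scores),
            class = "feature_panel")
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("Feature panel: %d transcripts (method: %s)\n",
              length(x$transcript_ids), x$method))
  invisible(x)
}

#' @export
length.feature_panel <- function(x) length(x$transcript_ids)

#' Write / read a feature panel as TSV with provenance
#'
#' @param panel A `feature_panel`.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  hdr <- sprintf("# method=%s params=%s", panel$method,
                 jsonlite::toJSON(panel$parameters, auto_unbox = TRUE))
  df <- data.frame(rank = seq_along(panel$transcript_ids),
                   transcript_id = panel$transcript_ids,
                   score = if (is.null(panel$scores)) NA_real_ else panel$scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  hdr <- readLines(path, n = 1L)
  method <- sub("^# method=([^ ]+) .*$", "\\1", hdr)
  params <- jsonlite::fromJSON(sub("^# method=[^ ]+ params=", "", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  feature_panel(df$transcript_id, method = method,
                parameters = as.list(params),
                scores = if (all(is.na(df$score))) NULL else df$score)
}

#' Supervised MDL discretization (recursive entropy minimization)
#'
#' Recursively splits the value range at the entropy-minimizing boundary,
#' accepting a split only when its information gain exceeds the
#' minimum-description-length penalty
#' `(log2(n-1) + log2(3^k - 2) - k*E + k1*E1 + k2*E2) / n`,
#' where `k`, `k1`, `k2` are the class counts present in the parent and
#' child partitions and `E*` their entropies. Features for which no split
#' is accepted remain a single bin.
#'
#' @param values Numeric vector.
#' @param labels Class labels of equal length.
#' @return Numeric vector of accepted cut points (possibly empty),
#'   ascending; a value `v` falls into bin `sum(cuts < v) + 1` ... bins
#'   are assigned with [discretize_values()].
#' @export
mdl_discretize <- function(values, labels) {
  if (length(values) != length(labels)) stop("mismatched lengths")
  if (length(values) < 2) return(numeric(0))
  ord <- order(values)
  sort(.mdl_rec(values[ord], as.character(labels)[ord]))
}

.mdl_rec <- function(v, y) {
  n <- length(v)
  ent <- function(yy) .entropy2(table(yy))
  e_s <- ent(y)
  if (e_s == 0 || n < 2) return(numeric(0))
  # candidate cuts: midpoints between adjacent distinct values
  distinct <- which(diff(v) > 0)
  if (length(distinct) == 0) return(numeric(0))
  best_gain <- -Inf; best_cut <- NA_real_; best_i <- NA_integer_
  for (i in distinct) {
    e1 <- ent(y[1:i]); e2 <- ent(y[(i + 1):n])
    gain <- e_s - (i / n) * e1 - ((n - i) / n) * e2
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best_cut <- (v[i] + v[i + 1]) / 2
      best_i <- i
    }
  }
  y1 <- y[1:best_i]; y2 <- y[(best_i + 1):n]
  k <- length(unique(y)); k1 <- length(unique(y1)); k2 <- length(unique(y2))
  delta <- log2(3^k - 2) - (k * e_s - k1 * ent(y1) - k2 * ent(y2))
  if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  c(.mdl_rec(v[1:best_i], y1), best_cut,
    .mdl_rec(v[(best_i + 1):n], y2))
}

#' Assign values to discretization bins
#'
#' @param values Numeric vector.
#' @param cuts Cut points from [mdl_discretize()].
#' @return Integer bin index per value (1 = below the first cut).
#' @export
discretize_values <- function(values, cuts) {
  findInterval(values, sort(cuts)) + 1L
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' `SU = 2 * I(x;y) / (H(x) + H(y))` with base-2 entropies estimated from
#' the empirical joint distribution; 0 when both entropies are 0.
#'
#' @param x,y Discrete vectors of equal length.
#' @return A value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  joint <- table(x, y)
  hx <- .entropy2(rowSums(joint))
  hy <- .entropy2(colSums(joint))
  if (hx + hy == 0) return(0)
  hxy <- .entropy2(joint)
  2 * (hx + hy - hxy) / (hx + hy)
}

#' Fast correlation-based feature selection
#'
#' Each feature is discretized with [mdl_discretize()] against the class;
#' features left in a single bin get class-SU 0 and are never selected.
#' Features are ranked by symmetrical uncertainty with the class
#' (descending, ties by transcript ID) and scanned in that order: a
#' feature is kept unless some already-kept feature `Fj` predominates it,
#' i.e. `SU(Fi, Fj) >= SU(Fi, class)`.
#'
#' @param x An `expr_matrix`.
#' @param labels A `sample_labels` table (two classes among the matrix
#'   samples).
#' @param su_threshold Minimum class-SU for a feature to be considered;
#'   default 0 (keep all relevant, prune redundant).
#' @param positive_class,negative_class The two classes.
#' @return A `feature_panel` ordered by class-SU.
#' @export
fcbf_select <- function(x, labels, su_threshold = 0,
                        positive_class = "early", negative_class = "late") {
  stopifnot(inherits(x, "expr_matrix"))
  if (su_threshold < 0 || su_threshold > 1) stop("su_threshold must be in [0,1]")
  cls <- .classes_for(x, labels)
  keep_s <- cls %in% c(positive_class, negative_class)
  y <- cls[keep_s]
  vals <- x$values[, keep_s, drop = FALSE]
  n_feat <- nrow(vals)
  disc <- vector("list", n_feat)
  su_class <- numeric(n_feat)
  for (i in seq_len(n_feat)) {
    cuts <- mdl_discretize(vals[i, ], y)
    if (length(cuts) == 0) {
      su_class[i] <- 0
      disc[i] <- list(NULL)
    } else {
      d <- discretize_values(vals[i, ], cuts)
      disc[[i]] <- d
      su_class[i] <- symmetrical_uncertainty(d, y)
    }
  }
  cand <- which(su_class > 0 & su_class >= su_threshold)
  ord <- cand[order(-su_class[cand], x$transcript_ids[cand])]
  kept <- integer(0)
  for (i in ord) {
    predominated <- FALSE
    for (j in kept) {
      if (symmetrical_uncertainty(disc[[i]], disc[[j]]) >= su_class[i]) {
        predominated <- TRUE
        break
      }
    }
    if (!predominated) kept <- c(kept, i)
  }
  feature_panel(x$transcript_ids[kept], method = "fcbf",
                parameters = list(su_threshold = su_threshold),
                scores = su_class[kept])
}

#' ANOVA-F top-k feature selection
#'
#' Per feature, the one-way ANOVA F statistic
#' `F = (between-group SS / (g - 1)) / (within-group SS / (n - g))`;
#' for two classes this is the square of the pooled two-sample t
#' statistic. The top `k` features by F are returned.
#'
#' @param x An `expr_matrix`.
#' @param labels A `sample_labels` table (>= 2 classes among samples).
#' @param k Number of features to keep.
#' @return A `feature_panel` ordered by F descending (ties by ID).
#' @export
anova_f_select <- function(x, labels, k) {
  stopifnot(inherits(x, "expr_matrix"))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x$values)) stop("k exceeds the number of features")
  cls <- .classes_for(x, labels)
  g <- unique(cls)
  if (length(g) < 2) stop("need >= 2 classes")
  n <- ncol(x$values)
  grand <- rowMeans(x$values)
  ss_between <- 0
  ss_within <- 0
  for (cl in g) {
    m <- x$values[, cls == cl, drop = FALSE]
    ni <- ncol(m)
    mi <- rowMeans(m)
    ss_between <- ss_between + ni * (mi - grand)^2
    ss_within <- ss_within + rowSums((m - mi)^2)
  }
  f <- (ss_between / (length(g) - 1)) / (ss_within / (n - length(g)))
  f[ss_within == 0 & ss_between == 0] <- 0
  ord <- order(-f, x$transcript_ids)[seq_len(k)]
  feature_panel(x$transcript_ids[ord], method = "anova_f",
                parameters = list(k = k), scores = unname(f[ord]))
}

# Squared-hinge + L1 linear classifier fitted by FISTA (proximal
# gradient with Nesterov acceleration); intercept unpenalized.
.l1_squared_hinge <- function(X, y, lambda, max_iter = 2000, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  Xb <- cbind(X, 1)                      # last column = intercept
  # Lipschitz constant of the smooth part: 2 * sigma_max(Xb)^2
  L <- 2 * (svd(Xb, nu = 0, nv = 0)$d[1])^2
  w <- rep(0, p + 1)
  z <- w; tk <- 1
  soft <- function(u, a) sign(u) * pmax(abs(u) - a, 0)
  obj <- function(w) {
    m <- pmax(0, 1 - y * drop(Xb %*% w))
    sum(m^2) + lambda * sum(abs(w[1:p]))
  }
  prev <- obj(w)
  for (it in seq_len(max_iter)) {
    m <- pmax(0, 1 - y * drop(Xb %*% z))
    grad <- -2 * drop(crossprod(Xb, y * m))
    u <- z - grad / L
    w_new <- c(soft(u[1:p], lambda / L), u[p + 1])
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- w_new + ((tk - 1) / t_new) * (w_new - w)
    w <- w_new; tk <- t_new
    cur <- obj(w)
    if (abs(prev - cur) < tol * max(1, abs(prev))) break
    prev <- cur
  }
  list(w = w[1:p], b = w[p + 1])
}

#' L1-penalized linear-margin feature selection
#'
#' Fits a linear max-margin classifier with squared-hinge loss and an L1
#' penalty (`sum(max(0, 1 - y*(w.x + b))^2) + lambda * ||w||_1`, intercept
#' unpenalized) and keeps the features with nonzero weight (|w| > 1e-8),
#' ordered by |w| descending.
#'
#' @param x An `expr_matrix` on the z-score scale.
#' @param labels A `sample_labels` table with two classes among samples.
#' @param penalty_strength The L1 weight `lambda` (> 0); larger values
#'   select fewer features.
#' @param positive_class,negative_class The two classes.
#' @return A `feature_panel`.
#' @export
l1_linear_select <- function(x, labels, penalty_strength,
                             positive_class = "early",
                             negative_class = "late") {
  stopifnot(inherits(x, "expr_matrix"))
  cls <- .classes_for(x, labels)
  keep_s <- cls %in% c(positive_class, negative_class)
  y <- ifelse(cls[keep_s] == positive_class, 1, -1)
  if (length(unique(y)) < 2) stop("need both classes")
  X <- t(x$values[, keep_s, drop = FALSE])
  fit <- .l1_squared_hinge(X, y, penalty_strength)
  nz <- which(abs(fit$w) > 1e-8)
  nz <- nz[order(-abs(fit$w[nz]), x$transcript_ids[nz])]
  feature_panel(x$transcript_ids[nz], method = "l1_linear",
                parameters = list(penalty_strength = penalty_strength),
                scores = abs(fit$w[nz]))
}

#' Find an L1 penalty yielding a requested panel size
#'
#' Bisection on `penalty_strength` between `lambda_min` and `lambda_max`
#' until the panel has (close to) `target_size` features. The panel-size
#' path is monotone non-increasing in the penalty, but not every size is
#' attainable; the closest achieved panel is returned.
#'
#' @inheritParams l1_linear_select
#' @param target_size Desired number of selected features.
#' @param lambda_min,lambda_max Bracket for the search.
#' @param max_steps Bisection iterations.
#' @return A `feature_panel` (closest achievable size).
#' @export
l1_select_size <- function(x, labels, target_size, lambda_min = 1e-4,
                           lambda_max = 100, max_steps = 25,
                           positive_class = "early",
                           negative_class = "late") {
  best <- NULL
  lo <- lambda_min; hi <- lambda_max
  for (s in seq_len(max_steps)) {
    mid <- sqrt(lo * hi)
    panel <- l1_linear_select(x, labels, mid, positive_class, negative_class)
    if (is.null(best) ||
        abs(length(panel) - target_size) < abs(length(best) - target_size))
      best <- panel
    if (length(panel) == target_size) return(panel)
    if (length(panel) > target_size) lo <- mid else hi <- mid
  }
  best
}

#' Stochastic subset search maximizing cross-validated MCC
#'
#' Population-based binary-mask search over a feature pool (at most 100
#' features, mirroring a 100-bit mask encoding): masks evolve by
#' tournament selection, uniform crossover and bit mutation; the fitness
#' of a mask is the mean Matthews correlation coefficient of a
#' stratified 10-fold cross-validated RBF margin classifier restricted to
#' the masked features. Fold assignment is fixed per call, fitness values
#' are cached, and the whole search is seed-reproducible.
#'
#' @param x An `expr_matrix` (z-score scale recommended).
#' @param labels A `sample_labels` table with two classes among samples.
#' @param pool A `feature_panel` (or character vector) of candidate
#'   features, size <= 100.
#' @param iterations Number of generations (>= 1); `1` returns the best
#'   of the initial random population.
#' @param seed Integer RNG seed.
#' @param folds Cross-validation folds for the fitness (default 10).
#' @param pop_size Population size (default 20).
#' @param positive_class,negative_class The two classes.
#' @return A `feature_panel`; attribute `"fitness_trace"` records the
#'   best fitness per generation and attribute `"fitness"` the winning
#'   mask's fitness.
#' @export
subset_search_select <- function(x, labels, pool, iterations = 50,
                                 seed = 1L, folds = 10, pop_size = 20,
                                 positive_class = "early",
                                 negative_class = "late") {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- if (inherits(pool, "feature_panel")) pool$transcript_ids else as.character(pool)
  if (length(ids) == 0) stop("empty feature pool")
  if (length(ids) > 100) stop("pool size must be <= 100")
  if (iterations < 1) stop("iterations must be >= 1")
  cls <- .classes_for(x, labels)
  keep_s <- cls %in% c(positive_class, negative_class)
  y <- factor(cls[keep_s], levels = c(positive_class, negative_class))
  vals <- x$values[match(ids, x$transcript_ids), keep_s, drop = FALSE]
  if (anyNA(vals)) stop("pool feature absent from matrix")
  fold_id <- .stratified_folds(as.character(y), folds, seed)
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    Xm <- t(vals[mask, , drop = FALSE])
    mccs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- e1071::svm(Xm[tr, , drop = FALSE], y[tr], kernel = "radial",
                        scale = FALSE)
      pred <- stats::predict(fit, Xm[!tr, , drop = FALSE])
      cc <- confusion_counts(y[!tr] == positive_class,
                             pred == positive_class)
      compute_metrics(cc)$mcc
    }, numeric(1))
    val <- mean(mccs)
    cache[[key]] <- val
    val
  }
  p <- length(ids)
  .with_seed(seed + 1L, {
    pop <- lapply(seq_len(pop_size), function(i) {
      m <- stats::runif(p) < 0.5
      if (!any(m)) m[sample.int(p, 1)] <- TRUE
      m
    })
    trace <- numeric(iterations)
    best_mask <- NULL; best_fit <- -Inf
    for (gen in seq_len(iterations)) {
      fits <- vapply(pop, fitness, numeric(1))
      gb <- which.max(fits)
      if (fits[gb] > best_fit) {
        best_fit <- fits[gb]; best_mask <- pop[[gb]]
      }
      trace[gen] <- best_fit
      if (gen == iterations) break
      tournament <- function() {
        ij <- sample.int(pop_size, 2)
        pop[[ij[if (fits[ij[1]] >= fits[ij[2]]) 1 else 2]]]
      }
      new_pop <- list(best_mask)            # elitism
      while (length(new_pop) < pop_size) {
        pa <- tournament(); pb <- tournament()
        take <- stats::runif(p) < 0.5
        child <- ifelse(take, pa, pb)
        flip <- stats::runif(p) < 1 / p
        child <- xor(child, flip)
        if (!any(child)) child[sample.int(p, 1)] <- TRUE
        new_pop[[length(new_pop) + 1L]] <- child
      }
      pop <- new_pop
    }
    out <- feature_panel(ids[best_mask], method = "subset_search",
                         parameters = list(iterations = iterations,
                                           seed = seed, folds = folds,
                                           pop_size = pop_size))
    attr(out, "fitness") <- best_fit
    attr(out, "fitness_trace") <- trace
    out
  })
}
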