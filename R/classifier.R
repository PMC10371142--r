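# Shared train/validate/test machinery for the reactivation and BBB models:
# k-means-stratified splitting, grid-searched extreme gradient boosting,
# iterative importance-ranked reduced-set selection, and per-class metrics.

#' k-means-stratified train/test split
#'
#' Clusters the scaled feature matrix with k-means, then draws the test
#' fraction within every (cluster x class) cell so both partitions see the
#' same regions of descriptor space and every class. A final deterministic
#' adjustment keeps the overall test count within one sample of the target.
#'
#' @param features Numeric matrix with sample ids as rownames.
#' @param labels Class labels, one per row.
#' @param test_fraction Fraction reserved for testing (default 0.2).
#' @param k Number of k-means clusters; default `3 * nlevels(labels)`,
#'   capped at the number of distinct rows.
#' @param seed Integer seed; the split is a pure function of
#'   (features, labels, test_fraction, k, seed).
#' @return A `split_plan`: list with `assignment` (named `"train_val"` /
#'   `"test"` vector), `clusters`, `test_fraction`, `k`, `seed`.
#' @export
stratified_split <- function(features, labels, test_fraction = 0.2,
                             k = NULL, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            !is.null(rownames(features)))
  labels <- as.character(labels)
  n <- nrow(features)
  if (!is.null(k) && k > n) stop("k exceeds the sample count", call. = FALSE)
  if (is.null(k)) k <- 3L * length(unique(labels))
  n_distinct <- nrow(unique(features))
  k <- max(2L, min(as.integer(k), n_distinct, n - 1L))
  set.seed(seed)
  cl <- if (n_distinct == 1L) rep(1L, n) else
    kmeans(features, centers = k, nstart = 5L, iter.max = 50L)$cluster
  ids <- rownames(features)
  assignment <- stats::setNames(rep("train_val", n), ids)
  cell <- paste(cl, labels, sep = "|")
  for (cc in unique(cell)) {
    members <- which(cell == cc)
    m <- length(members)
    n_test <- round(test_fraction * m)
    if (m > 1L) n_test <- min(n_test, m - 1L)
    if (n_test > 0L) {
      assignment[members[sample.int(m, n_test)]] <- "test"
    }
  }
  # nudge the overall count to within one sample of the target
  target <- round(test_fraction * n)
  repeat {
    n_test <- sum(assignment == "test")
    if (abs(n_test - target) <= 1L) break
    if (n_test > target) {
      pool <- which(assignment == "test")
      assignment[pool[sample.int(length(pool), 1L)]] <- "train_val"
    } else {
      pool <- which(assignment == "train_val")
      # prefer cells that keep a training representative
      keep <- pool[vapply(pool, function(i) {
        sum(assignment[cell == cell[i]] == "train_val") > 1L
      }, logical(1))]
      if (!length(keep)) keep <- pool
      assignment[keep[sample.int(length(keep), 1L)]] <- "test"
    }
  }
  structure(list(assignment = assignment,
                 clusters = stats::setNames(cl, ids),
                 test_fraction = test_fraction, k = k, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", sum(x$assignment == "train_val"), " train_val / ",
      sum(x$assignment == "test"), " test (k=", x$k, ", seed=", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Ids in one partition of a split plan
#'
#' @param plan A `split_plan`.
#' @param partition `"train_val"` or `"test"`.
#' @return Character vector of sample ids.
#' @export
split_ids <- function(plan, partition = c("train_val", "test")) {
  partition <- match.arg(partition)
  names(plan$assignment)[plan$assignment == partition]
}

#' Default hyperparameter grid for the gradient-boosted classifiers
#'
#' Tree count, depth and learning rate — the axes the grid search tunes.
#'
#' @return A `data.frame` of candidate configurations.
#' @export
default_grid <- function() {
  expand.grid(nrounds = c(100L, 300L), max_depth = c(3L, 5L),
              eta = c(0.1, 0.3), KEEP.OUT.ATTRS = FALSE)
}

macro_f1 <- function(truth, pred, classes) {
  f1 <- vapply(classes, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

# seeded, class-stratified CV fold ids
cv_folds <- function(labels, nfold, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
  }
  fold
}

fit_xgb <- function(x, y_int, n_class, nrounds, max_depth, eta, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = y_int, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = n_class,
                  max_depth = max_depth, eta = eta, nthread = 1,
                  seed = seed),
    data = dm, nrounds = nrounds, verbose = 0)
}

predict_xgb <- function(model, x, classes) {
  p <- predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
  if (!is.matrix(p)) p <- matrix(p, ncol = length(classes), byrow = TRUE)
  classes[max.col(p, ties.method = "first")]
}

# mean cross-validated macro F1 of one configuration
cv_score <- function(x, y, classes, nrounds, max_depth, eta, nfold, seed) {
  fold <- cv_folds(y, nfold, seed)
  scores <- vapply(seq_len(nfold), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    m <- fit_xgb(x[tr, , drop = FALSE],
                 match(y[tr], classes) - 1L, length(classes),
                 nrounds, max_depth, eta, seed)
    macro_f1(y[!tr], predict_xgb(m, x[!tr, , drop = FALSE], classes), classes)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Train a gradient-boosted classifier with grid-searched hyperparameters
#'
#' Cross-validated grid search (macro-F1 selection) over tree count, depth
#' and learning rate, followed by a refit on all supplied samples with the
#' winning configuration.
#'
#' @param features Numeric matrix (samples x descriptors, scaled), rownames
#'   set.
#' @param labels Class labels, one per row; at least two classes.
#' @param feature_subset Optional [select_reduced_set()] result or character
#'   vector restricting (and ordering) the columns used.
#' @param grid Hyperparameter `data.frame` (`nrounds`, `max_depth`, `eta`);
#'   see [default_grid()].
#' @param nfold Cross-validation folds (default 5).
#' @param seed Integer seed; training is deterministic given it.
#' @return An `oxime_classifier` artifact: the fitted booster plus the
#'   feature names (order is binding at prediction time), class set, chosen
#'   hyperparameters, seed and a training manifest.
#' @export
train_classifier <- function(features, labels, feature_subset = NULL,
                             grid = default_grid(), nfold = 5L, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (is.null(grid) || !nrow(grid)) stop("empty hyperparameter grid",
                                         call. = FALSE)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training data has a single class",
                                 call. = FALSE)
  if (!is.null(feature_subset)) {
    nm <- if (inherits(feature_subset, "feature_subset"))
      feature_subset$names else as.character(feature_subset)
    miss <- setdiff(nm, colnames(features))
    if (length(miss)) stop("unknown feature(s): ",
                           paste(head(miss, 5), collapse = ", "),
                           call. = FALSE)
    features <- features[, nm, drop = FALSE]
  }
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    cv_score(features, labels, classes, grid$nrounds[i], grid$max_depth[i],
             grid$eta[i], nfold, seed)
  }, numeric(1))
  best <- which.max(scores)  # first (smallest-index) config wins ties
  model <- fit_xgb(features, match(labels, classes) - 1L, length(classes),
                   grid$nrounds[best], grid$max_depth[best], grid$eta[best],
                   seed)
  structure(list(
    model = model,
    feature_names = colnames(features),
    classes = classes,
    hyperparams = as.list(grid[best, , drop = FALSE]),
    seed = seed,
    manifest = list(
      grid = grid, cv_macro_f1 = scores, best_index = best, nfold = nfold,
      n_train = nrow(features), class_counts = as.list(table(labels)),
      toolkit = list(xgboost = as.character(utils::packageVersion("xgboost")))
    )
  ), class = "oxime_classifier")
}

#' @export
print.oxime_classifier <- function(x, ...) {
  cat("<oxime_classifier> ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ", length(x$feature_names),
      " features, nrounds=", x$hyperparams$nrounds, " depth=",
      x$hyperparams$max_depth, " eta=", x$hyperparams$eta, "\n", sep = "")
  invisible(x)
}

#' Predict classes for new samples
#'
#' @param object An `oxime_classifier`.
#' @param newdata Numeric matrix containing (at least) the artifact's
#'   feature columns; they are selected and ordered automatically.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.oxime_classifier <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ",
                         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  x <- newdata[, object$feature_names, drop = FALSE]
  predict_xgb(object$model, x, object$classes)
}

#' Importance-ranked reduced-set (RS) feature selection
#'
#' Trains on the full descriptor set, ranks features by importance, then
#' evaluates nested top-m subsets by cross-validated macro F1 and returns the
#' best, breaking ties toward the smaller subset. `method = "recursive"`
#' re-ranks after each shrink instead of using the single full-set ranking.
#'
#' @param features,labels As in [train_classifier()].
#' @param sizes Candidate subset sizes; sizes above `ncol(features)` are
#'   treated as the full set. Default geometric grid
#'   `c(4, 6, 9, 14, 20, 30, 50)` plus the full set.
#' @param importance `"gain"` (model gain, default) or `"permutation"`.
#' @param method `"ranking"` (single full-set ranking, default) or
#'   `"recursive"` elimination.
#' @param grid,nfold,seed As in [train_classifier()] (the grid here is used
#'   only to score subsets; keep it small).
#' @return A `feature_subset`: `names` (ordered), `importances`,
#'   `selection_f1`, and the per-size `candidates` table.
#' @export
select_reduced_set <- function(features, labels,
                               sizes = c(4L, 6L, 9L, 14L, 20L, 30L, 50L),
                               importance = c("gain", "permutation"),
                               method = c("ranking", "recursive"),
                               grid = data.frame(nrounds = 100L,
                                                 max_depth = 4L, eta = 0.2),
                               nfold = 5L, seed = 1L) {
  importance <- match.arg(importance)
  method <- match.arg(method)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training data has a single class",
                                 call. = FALSE)
  p <- ncol(features)
  sizes <- sort(unique(pmin(as.integer(sizes), p)))
  if (!p %in% sizes) sizes <- c(sizes, p)

  rank_features <- function(x) {
    m <- fit_xgb(x, match(labels, classes) - 1L, length(classes),
                 grid$nrounds[1], grid$max_depth[1], grid$eta[1], seed)
    if (importance == "gain") {
      imp <- xgboost::xgb.importance(model = m)
      sc <- stats::setNames(rep(0, ncol(x)), colnames(x))
      sc[imp$Feature] <- imp$Gain
    } else {
      base <- macro_f1(labels, predict_xgb(m, x, classes), classes)
      set.seed(seed)
      sc <- vapply(seq_len(ncol(x)), function(j) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        base - macro_f1(labels, predict_xgb(m, xp, classes), classes)
      }, numeric(1))
      sc <- pmax(sc, 0)
      names(sc) <- colnames(x)
    }
    sort(sc, decreasing = TRUE)
  }

  full_rank <- rank_features(features)
  cand <- data.frame(size = sizes, macro_f1 = NA_real_)
  subset_names <- vector("list", length(sizes))
  current <- names(full_rank)
  for (i in rev(seq_along(sizes))) {   # largest first, for recursive mode
    m_i <- sizes[i]
    if (method == "recursive" && m_i < length(current)) {
      rk <- rank_features(features[, current, drop = FALSE])
      current <- names(rk)[seq_len(m_i)]
    }
    nm <- if (method == "recursive") current[seq_len(min(m_i, length(current)))]
          else names(full_rank)[seq_len(m_i)]
    subset_names[[i]] <- nm
    cand$macro_f1[i] <- cv_score(features[, nm, drop = FALSE], labels,
                                 classes, grid$nrounds[1], grid$max_depth[1],
                                 grid$eta[1], nfold, seed)
  }
  best <- which(cand$macro_f1 == max(cand$macro_f1))[1]  # smallest size wins
  structure(list(
    names = subset_names[[best]],
    importances = full_rank[subset_names[[best]]],
    selection_f1 = cand$macro_f1[best],
    candidates = cand,
    importance = importance, method = method, seed = seed
  ), class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("<feature_subset> ", length(x$names), " descriptors (macro F1 ",
      round(x$selection_f1, 3), "): ",
      paste(head(x$names, 6), collapse = ", "),
      if (length(x$names) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Per-class metrics from a confusion matrix
#'
#' @param confusion Square counts matrix, true classes in rows, predicted in
#'   columns, identical dimnames.
#' @return List with `confusion`, `normalized` (rows sum to 1), `per_class`
#'   data.frame (sensitivity, selectivity i.e. specificity, precision, f1)
#'   and `overall_accuracy` = trace / total.
#' @export
confusion_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            identical(rownames(confusion), colnames(confusion)))
  classes <- rownames(confusion)
  total <- sum(confusion)
  per <- do.call(rbind, lapply(classes, function(cls) {
    tp <- confusion[cls, cls]
    fn <- sum(confusion[cls, ]) - tp
    fp <- sum(confusion[, cls]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else 0
    data.frame(class = cls, sensitivity = sens, selectivity = spec,
               precision = prec, f1 = f1, n = tp + fn,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  rs <- rowSums(confusion)
  normalized <- sweep(confusion, 1L, ifelse(rs > 0, rs, 1), "/")
  list(confusion = confusion, normalized = normalized, per_class = per,
       overall_accuracy = sum(diag(confusion)) / total,
       macro_f1 = mean(per$f1))
}

#' Evaluate a classifier on held-out samples
#'
#' @param artifact An `oxime_classifier`.
#' @param features Test feature matrix.
#' @param labels True classes; every label must be known to the artifact.
#' @return An evaluation report from [confusion_metrics()], plus the raw
#'   predictions.
#' @export
evaluate_classifier <- function(artifact, features, labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty test set", call. = FALSE)
  unknown <- setdiff(unique(labels), artifact$classes)
  if (length(unknown)) stop("test class(es) absent from the artifact: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  pred <- predict(artifact, features)
  classes <- artifact$classes
  confusion <- table(factor(labels, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(classes, classes))
  rep <- confusion_metrics(confusion)
  rep$predictions <- stats::setNames(pred, rownames(features))
  rep
}

#' Save a classifier artifact to a directory
#'
#' Writes the booster in the toolkit's binary format plus a JSON manifest
#' (features, classes, hyperparameters, seed, toolkit versions). Reloading
#' with [load_classifier()] reproduces predictions exactly.
#'
#' @param artifact An `oxime_classifier`.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(artifact, dir) {
  stopifnot(inherits(artifact, "oxime_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(artifact$model, file.path(dir, "model.ubj"))
  meta <- artifact[c("feature_names", "classes", "hyperparams", "seed",
                     "manifest")]
  meta$manifest$grid <- as.list(meta$manifest$grid)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a classifier artifact saved by [save_classifier()]
#'
#' @param dir Artifact directory.
#' @return An `oxime_classifier`.
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  structure(list(
    model = xgboost::xgb.load(file.path(dir, "model.ubj")),
    feature_names = meta$feature_names,
    classes = meta$classes,
    hyperparams = as.list(meta$hyperparams),
    seed = meta$seed,
    manifest = meta$manifest
  ), class = "oxime_classifier")
}
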