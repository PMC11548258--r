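#' Classification pipeline configuration
#'
#' @param normalize Apply z-score normalization (on by default).
#' @param quasi_constant_threshold Drop features whose most frequent value
#'   has relative frequency at or above this, default 0.99.
#' @param kendall_tau_threshold Drop features whose absolute Kendall tau
#'   with an already-kept feature reaches this, default 0.9.
#' @param pca_variance_kept Cumulative explained-variance target for PCA;
#'   `NA` disables the PCA step.  Default 0.95.
#' @param au_threshold Mental-performance split for the labels.
#' @param test_per_class Held-out test rows per class in the random split.
#'   The original protocol used 100 per class out of 1112 samples; scale
#'   this down for smaller studies.
#' @param cv_folds Stratified cross-validation folds, default 10.
#' @param balance_classes Subsample the majority class to the minority
#'   count before splitting (the evaluation protocol keeps the test set
#'   balanced either way).
#' @param seed Seed controlling the split, fold assignment and every model
#'   fit.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(normalize = TRUE,
                            quasi_constant_threshold = 0.99,
                            kendall_tau_threshold = 0.9,
                            pca_variance_kept = 0.95,
                            au_threshold = 1.5,
                            test_per_class = 100,
                            cv_folds = 10,
                            balance_classes = FALSE,
                            seed = 1) {
  stopifnot(quasi_constant_threshold > 0, quasi_constant_threshold <= 1,
            kendall_tau_threshold > 0, kendall_tau_threshold <= 1,
            cv_folds >= 2, test_per_class >= 1)
  if (!is.na(pca_variance_kept) &&
      (pca_variance_kept <= 0 || pca_variance_kept > 1)) {
    stop("`pca_variance_kept` must lie in (0, 1] or be NA", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Z-score normalization
#'
#' Subtracts each feature's mean and divides by its standard deviation.
#' The population convention (denominator n) is used so that re-applying
#' the returned parameters to the training matrix reproduces the normalized
#' output and normalization is idempotent to numerical precision.
#'
#' @param x Numeric matrix or data frame (rows = samples).
#' @param params Optional parameters from a previous call; when given, `x`
#'   is transformed with them instead of refitting.
#' @return A list with `matrix` (the normalized matrix) and `params`
#'   (`center`, `scale`).
#' @export
zscore_normalize <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (is.null(params)) {
    if (nrow(x) < 2L) stop("need at least 2 rows to normalize",
                           call. = FALSE)
    center <- colMeans(x)
    n <- nrow(x)
    scale <- sqrt(colMeans(sweep(x, 2, center)^2))
    if (any(scale == 0)) {
      stop(sprintf(
        "zero-variance column(s): %s; remove them with remove_quasi_constant() first",
        paste(colnames(x)[scale == 0], collapse = ", ")), call. = FALSE)
    }
    params <- list(center = center, scale = scale)
  }
  out <- sweep(sweep(x, 2, params$center[colnames(x)]), 2,
               params$scale[colnames(x)], `/`)
  list(matrix = out, params = params)
}

#' Remove quasi-constant features
#'
#' Drops columns whose most frequent value has relative frequency at or
#' above `threshold`; survivor order is preserved.
#'
#' @param x Numeric matrix or data frame.
#' @param threshold Dominant-value frequency threshold in (0, 1].
#' @return The matrix without quasi-constant columns (attribute `dropped`
#'   lists the removed names).  All columns dropped is an error.
#' @export
remove_quasi_constant <- function(x, threshold = 0.99) {
  x <- as.matrix(x)
  freq <- apply(x, 2, function(col) {
    max(table(col)) / length(col)
  })
  drop <- freq >= threshold
  if (all(drop)) stop("all features are quasi-constant", call. = FALSE)
  out <- x[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(x)[drop]
  out
}

#' Remove Kendall-correlated features
#'
#' Scans columns left to right, keeping a column only if its absolute
#' Kendall tau with every already-kept column stays below the threshold.
#'
#' @param x Numeric matrix or data frame.
#' @param tau_threshold Absolute tau at or above which a column is dropped,
#'   default 0.9.
#' @return The reduced matrix (attribute `dropped`).
#' @export
remove_kendall_correlated <- function(x, tau_threshold = 0.9) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) return(x)
  kept <- 1L
  for (j in 2:p) {
    tau <- suppressWarnings(
      abs(cor(x[, j], x[, kept, drop = FALSE], method = "kendall")))
    tau[is.na(tau)] <- 0
    if (all(tau < tau_threshold)) kept <- c(kept, j)
  }
  out <- x[, kept, drop = FALSE]
  attr(out, "dropped") <- colnames(x)[-kept]
  out
}

#' PCA dimensionality reduction
#'
#' Projects a (normalized) matrix onto the smallest number of principal
#' components whose cumulative explained variance reaches
#' `variance_kept`; the rotation is retained so future data can be
#' projected identically.
#'
#' @param x Numeric matrix, already normalized.
#' @param variance_kept Target cumulative explained variance in (0, 1].
#' @param transform Optional transform from a previous call, applied
#'   instead of refitting.
#' @return A list with `matrix` (scores) and `transform` (`rotation`,
#'   `center`, `k`).
#' @export
pca_reduce <- function(x, variance_kept = 0.95, transform = NULL) {
  x <- as.matrix(x)
  if (!is.null(transform)) {
    cols <- rownames(transform$rotation)
    if (!is.null(cols) && !is.null(colnames(x))) {
      x <- x[, cols, drop = FALSE]
    }
    sc <- sweep(x, 2, transform$center) %*% transform$rotation
    return(list(matrix = sc, transform = transform))
  }
  if (is.na(variance_kept) || variance_kept <= 0 || variance_kept > 1) {
    stop("`variance_kept` must lie in (0, 1]", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2
  cum <- cumsum(vr) / sum(vr)
  k <- which(cum >= variance_kept - 1e-12)[1L]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  transform <- list(rotation = rot, center = pc$center, k = k)
  list(matrix = pc$x[, seq_len(k), drop = FALSE], transform = transform)
}

#' Classifier parameter grid
#'
#' The grid of model configurations evaluated by [grid_train()], per
#' family: random forest over 10..100 trees (step 10); decision tree over
#' the gini and information (entropy) split criteria; k-nearest neighbours
#' over k = 1..10 with uniform and inverse-distance vote weights;
#' single-hidden-layer perceptron over hidden sizes 1..20 (logistic
#' activation, BFGS optimization, cross-entropy loss); logistic regression
#' (one configuration, Fisher scoring, cross-entropy loss); and a margin
#' classifier over the linear, polynomial, radial and sigmoid kernels
#' (hinge loss).
#'
#' @param families Subset of
#'   `c("random_forest", "decision_tree", "knn", "mlp",
#'   "logistic_regression", "svm")`.
#' @return A data frame with columns `family`, `param`, `value` -- one row
#'   per configuration.
#' @export
model_grid <- function(families = c("random_forest", "decision_tree", "knn",
                                    "mlp", "logistic_regression", "svm")) {
  families <- match.arg(families, several.ok = TRUE)
  grids <- list(
    random_forest = data.frame(family = "random_forest",
                               param = "ntree",
                               value = as.character(seq(10, 100, by = 10))),
    decision_tree = data.frame(family = "decision_tree",
                               param = "split",
                               value = c("gini", "information")),
    knn = data.frame(family = "knn",
                     param = "k_weights",
                     value = as.vector(outer(1:10,
                                             c("uniform", "distance"),
                                             paste, sep = "/"))),
    mlp = data.frame(family = "mlp", param = "size",
                     value = as.character(1:20)),
    logistic_regression = data.frame(family = "logistic_regression",
                                     param = "solver", value = "irls"),
    svm = data.frame(family = "svm", param = "kernel",
                     value = c("linear", "polynomial", "radial", "sigmoid")))
  do.call(rbind, grids[families])
}

# ---- model fitting ---------------------------------------------------------

fit_config <- function(family, value, x, y, seed) {
  with_seed(seed, switch(
    family,
    random_forest = randomForest::randomForest(
      x, y, ntree = as.integer(value)),
    decision_tree = {
      df <- data.frame(x, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = value))
    },
    knn = {
      kw <- strsplit(value, "/", fixed = TRUE)[[1L]]
      list(train = x, labels = y, k = as.integer(kw[1L]), weights = kw[2L])
    },
    mlp = {
      nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2L, drop = FALSE],
                 size = as.integer(value), entropy = TRUE, maxit = 300,
                 decay = 1e-3, trace = FALSE)
    },
    logistic_regression = {
      df <- data.frame(x, .label = y, check.names = FALSE)
      suppressWarnings(glm(.label ~ ., data = df, family = binomial()))
    },
    svm = e1071::svm(x, y, kernel = value, probability = FALSE),
    stop(sprintf("unknown family: %s", family), call. = FALSE)))
}

predict_config <- function(family, model, x, levels) {
  x <- as.matrix(x)
  switch(
    family,
    random_forest = predict(model, x),
    decision_tree = {
      cls <- predict(model, data.frame(x, check.names = FALSE),
                     type = "class")
      factor(as.character(cls), levels = levels)
    },
    knn = knn_predict(model, x),
    mlp = {
      p <- predict(model, x)
      factor(ifelse(p[, 1L] > 0.5, levels[2L], levels[1L]), levels = levels)
    },
    logistic_regression = {
      p <- predict(model, data.frame(x, check.names = FALSE),
                   type = "response")
      factor(ifelse(p > 0.5, levels[2L], levels[1L]), levels = levels)
    },
    svm = predict(model, x),
    stop(sprintf("unknown family: %s", family), call. = FALSE))
}

predict_score <- function(family, model, x, positive) {
  x <- as.matrix(x)
  switch(
    family,
    random_forest = predict(model, x, type = "prob")[, positive],
    decision_tree = predict(model, data.frame(x, check.names = FALSE),
                            type = "prob")[, positive],
    mlp = as.numeric(predict(model, x)),
    logistic_regression = as.numeric(
      predict(model, data.frame(x, check.names = FALSE),
              type = "response")),
    knn = ,
    svm = rep(NA_real_, nrow(x)))
}

knn_predict <- function(model, x) {
  tr <- model$train
  nte <- nrow(x)
  d2 <- outer(rowSums(x^2), rowSums(tr^2), `+`) - 2 * x %*% t(tr)
  d2[d2 < 0] <- 0
  lv <- levels(model$labels)
  out <- character(nte)
  for (i in seq_len(nte)) {
    ord <- order(d2[i, ])[seq_len(model$k)]
    lab <- model$labels[ord]
    if (model$weights == "uniform") {
      tab <- table(lab)
    } else {
      d <- sqrt(d2[i, ord])
      if (any(d == 0)) {
        tab <- table(lab[d == 0])
      } else {
        tab <- tapply(1 / d, lab, sum)
        tab[is.na(tab)] <- 0
      }
    }
    out[i] <- names(tab)[which.max(tab)]
  }
  factor(out, levels = lv)
}

#' Classification metrics
#'
#' Accuracy, F1 and the confusion matrix.  The positive class for F1 is
#' the fatigued one, i.e. `"low"` mental performance.  When the positive
#' class is never predicted and never present, F1 is 0 by convention.
#'
#' @param predicted,actual Factors with identical levels.
#' @param positive The positive-class level, default `"low"`.
#' @return A list with `accuracy`, `f1`, `precision`, `recall`,
#'   `confusion`.
#' @export
classification_metrics <- function(predicted, actual, positive = "low") {
  stopifnot(length(predicted) == length(actual))
  lv <- union(levels(factor(actual)), levels(factor(predicted)))
  predicted <- factor(predicted, levels = lv)
  actual <- factor(actual, levels = lv)
  cm <- table(predicted = predicted, actual = actual)
  tp <- sum(predicted == positive & actual == positive)
  fp <- sum(predicted == positive & actual != positive)
  fn <- sum(predicted != positive & actual == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = mean(predicted == actual), f1 = f1,
       precision = precision, recall = recall, confusion = cm)
}

# Fit the preprocessing chain on a feature matrix; returns transformed
# matrix plus the parameters needed to replay it at inference time.
fit_preprocess <- function(x, cfg) {
  x <- as.matrix(x)
  steps <- list(columns = colnames(x))
  x <- remove_quasi_constant(x, cfg$quasi_constant_threshold)
  steps$after_quasi_constant <- colnames(x)
  if (cfg$normalize) {
    z <- zscore_normalize(x)
    x <- z$matrix
    steps$normalize <- z$params
  }
  x <- remove_kendall_correlated(x, cfg$kendall_tau_threshold)
  steps$after_kendall <- colnames(x)
  if (!is.na(cfg$pca_variance_kept)) {
    pr <- pca_reduce(x, cfg$pca_variance_kept)
    x <- pr$matrix
    steps$pca <- pr$transform
  }
  list(matrix = x, steps = steps)
}

apply_preprocess <- function(x, steps) {
  x <- as.matrix(x)
  missing_cols <- setdiff(steps$after_quasi_constant, colnames(x))
  if (length(missing_cols)) {
    stop(sprintf("feature definition mismatch; missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- x[, steps$after_quasi_constant, drop = FALSE]
  if (!is.null(steps$normalize)) {
    x <- zscore_normalize(x, steps$normalize)$matrix
  }
  x <- x[, steps$after_kendall, drop = FALSE]
  if (!is.null(steps$pca)) {
    x <- pca_reduce(x, transform = steps$pca)$matrix
  }
  x
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train the classifier grid
#'
#' Runs the full classification protocol on a feature matrix: the
#' preprocessing chain (quasi-constant removal, z-score normalization,
#' Kendall-correlation removal, PCA), a stratified random split with a
#' balanced held-out test set (`test_per_class` rows per class), training
#' and evaluation of every grid configuration on that split, and
#' stratified k-fold cross-validation of every configuration on the full
#' data (pooled out-of-fold predictions).  The best configuration is the
#' one with the highest random-split accuracy; cross-validation metrics
#' are reported alongside for trustworthiness.  Fully seeded and
#' deterministic given `cfg$seed`.
#'
#' @param x A feature matrix built by [build_feature_matrix()] (the label
#'   column is taken from it), or a plain numeric matrix, in which case
#'   `labels` must be given.
#' @param labels Factor of class labels (`high`/`low`) when `x` is a plain
#'   matrix.
#' @param families Model families to include, see [model_grid()].
#' @param cfg A [pipeline_config()].
#' @return An object of class `fatigue_model`: a list with `report` (one
#'   row per configuration with split and CV accuracy/F1), `best`, the
#'   fitted best model, preprocessing steps and the feature definition.
#' @export
grid_train <- function(x, labels = NULL,
                       families = c("random_forest", "decision_tree", "knn",
                                    "mlp", "logistic_regression", "svm"),
                       cfg = pipeline_config()) {
  feature_def <- attr(x, "feature_def")
  if (is.data.frame(x) && !is.null(attr(x, "feature_columns"))) {
    labels <- x$label
    x <- as.matrix(x[, attr(x, "feature_columns"), drop = FALSE])
  }
  x <- as.matrix(x)
  labels <- factor(labels, levels = c("high", "low"))
  ok <- stats::complete.cases(x) & !is.na(labels)
  if (!all(ok)) {
    message(sprintf("dropping %d row(s) with missing values", sum(!ok)))
    x <- x[ok, , drop = FALSE]
    labels <- labels[ok]
  }
  if (nlevels(droplevels(labels)) != 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  grid <- model_grid(families)
  with_seed(cfg$seed, {
    if (cfg$balance_classes) {
      n_min <- min(table(labels))
      keep <- unlist(lapply(levels(labels), function(lv) {
        sample(which(labels == lv), n_min)
      }))
      keep <- sort(keep)
      x <- x[keep, , drop = FALSE]
      labels <- labels[keep]
    }
    pp <- fit_preprocess(x, cfg)
    xm <- pp$matrix
    ## balanced held-out split
    test_idx <- unlist(lapply(levels(labels), function(lv) {
      idx <- which(labels == lv)
      if (length(idx) <= cfg$test_per_class) {
        stop(sprintf(
          "class %s has only %d rows; test_per_class = %d leaves no training data",
          lv, length(idx), cfg$test_per_class), call. = FALSE)
      }
      sample(idx, cfg$test_per_class)
    }))
    train_idx <- setdiff(seq_len(nrow(xm)), test_idx)
    if (nlevels(droplevels(labels[train_idx])) != 2L) {
      stop("a class is absent from the training split", call. = FALSE)
    }
    fold <- stratified_folds(labels, cfg$cv_folds)
    lv <- levels(labels)
    report <- grid
    report$split_accuracy <- report$split_f1 <- NA_real_
    report$cv_accuracy <- report$cv_f1 <- NA_real_
    models <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      fam <- grid$family[g]; val <- grid$value[g]
      fit_seed <- derive_seed(cfg$seed, g)
      m <- fit_config(fam, val, xm[train_idx, , drop = FALSE],
                      labels[train_idx], fit_seed)
      models[[g]] <- m
      pred <- predict_config(fam, m, xm[test_idx, , drop = FALSE], lv)
      met <- classification_metrics(pred, labels[test_idx])
      report$split_accuracy[g] <- met$accuracy
      report$split_f1[g] <- met$f1
      cv_pred <- factor(rep(NA_character_, nrow(xm)), levels = lv)
      for (f in seq_len(cfg$cv_folds)) {
        tr <- fold != f
        if (nlevels(droplevels(labels[tr])) != 2L) next
        mf <- fit_config(fam, val, xm[tr, , drop = FALSE], labels[tr],
                         derive_seed(cfg$seed, g, f))
        cv_pred[!tr] <- predict_config(fam, mf, xm[!tr, , drop = FALSE], lv)
      }
      cvm <- classification_metrics(cv_pred[!is.na(cv_pred)],
                                    labels[!is.na(cv_pred)])
      report$cv_accuracy[g] <- cvm$accuracy
      report$cv_f1[g] <- cvm$f1
    }
    best_g <- which.max(report$split_accuracy)
    structure(list(
      report = report,
      best = list(family = grid$family[best_g], value = grid$value[best_g],
                  model = models[[best_g]],
                  split_accuracy = report$split_accuracy[best_g],
                  split_f1 = report$split_f1[best_g],
                  cv_accuracy = report$cv_accuracy[best_g],
                  cv_f1 = report$cv_f1[best_g]),
      preprocess = pp$steps,
      levels = lv,
      feature_names = colnames(x),
      feature_def = feature_def,
      cfg = cfg),
      class = "fatigue_model")
  })
}

#' @export
print.fatigue_model <- function(x, ...) {
  cat(sprintf(
    "<fatigue_model> best: %s (%s) | split acc %.3f F1 %.3f | CV acc %.3f F1 %.3f\n",
    x$best$family, x$best$value, x$best$split_accuracy, x$best$split_f1,
    x$best$cv_accuracy, x$best$cv_f1))
  invisible(x)
}

#' Evaluate a trained model on held-out data
#'
#' @param model A `fatigue_model` from [grid_train()].
#' @param x Feature matrix (same columns the model was trained on) or a
#'   feature data frame from [build_feature_matrix()].
#' @param labels Factor of true labels when `x` is a plain matrix.
#' @return [classification_metrics()] of the best model's predictions.
#' @export
evaluate_model <- function(model, x, labels = NULL) {
  stopifnot(inherits(model, "fatigue_model"))
  if (is.data.frame(x) && !is.null(attr(x, "feature_columns"))) {
    labels <- x$label
    x <- as.matrix(x[, attr(x, "feature_columns"), drop = FALSE])
  }
  xm <- apply_preprocess(x, model$preprocess)
  pred <- predict_config(model$best$family, model$best$model, xm,
                         model$levels)
  classification_metrics(pred, factor(labels, levels = model$levels))
}
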