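risk_factor_features <- c("sex", "age", "bmi", "htn", "fhdm")

scale_features <- function(x, center, scale) {
  scale(as.matrix(x), center = center, scale = scale)
}

stratified_folds <- function(labels, nfolds) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

#' Train a classifier that reproduces the discovery clusters
#'
#' Fits a multiclass model mapping the five risk factors to the
#' discovery-cluster labels so that independent cohorts can be placed
#' into the same clusters without re-clustering. The default is an
#' RBF-kernel support vector machine (one-vs-one multiclass) on
#' z-scored features with inverse-frequency class weights; the cost and
#' kernel-width grid is tuned by stratified cross-validation on the
#' training cohort. A multinomial-logistic fallback
#' (`method = "multinom"`) is available for debuggability.
#'
#' @param cohort Training cohort with the five risk factors.
#' @param assignment Integer cluster labels, one per row.
#' @param config Optional list: `method` (`"svm"` or `"multinom"`),
#'   `cost` and `gamma` grids, `nfolds` (default 5), `class_weights`
#'   (default `TRUE`).
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `"cluster_classifier"` carrying the fitted
#'   model, the frozen feature center/scale, the training feature
#'   ranges, and tuning metadata (`cv_accuracy`, selected
#'   hyperparameters, seed).
#' @export
train_cluster_classifier <- function(cohort, assignment,
                                     config = list(), seed = 1) {
  if (nrow(cohort) != length(assignment))
    stop("assignment must cover the cohort")
  labels <- as.integer(assignment)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 clusters")
  method <- if (is.null(config$method)) "svm" else config$method
  nfolds <- if (is.null(config$nfolds)) 5L else config$nfolds
  if (min(table(labels)) < nfolds)
    stop("a cluster has fewer members than cross-validation folds")

  x <- as.matrix(cohort[, risk_factor_features])
  storage.mode(x) <- "double"
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale_features(x, center, scl)
  y <- factor(labels, levels = classes)
  cw <- if (isTRUE(config$class_weights) || is.null(config$class_weights)) {
    w <- length(y) / (length(classes) * table(y))
    stats::setNames(as.numeric(w), names(w))
  } else NULL

  fit_one <- function(xtr, ytr, cost, gamma) {
    if (method == "svm") {
      e1071::svm(xtr, ytr, kernel = "radial", cost = cost,
                 gamma = gamma, scale = FALSE, class.weights = cw)
    } else {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop("the 'nnet' package is required for method = 'multinom'")
      df <- data.frame(.y = ytr, xtr)
      nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300)
    }
  }
  predict_one <- function(fit, xnew) {
    if (method == "svm") stats::predict(fit, xnew)
    else stats::predict(fit, newdata = data.frame(xnew))
  }

  set.seed(seed)
  fold <- stratified_folds(labels, nfolds)
  grid <- if (method == "svm") {
    expand.grid(cost = config$cost %||% c(1, 10),
                gamma = config$gamma %||% c(0.2, 1))
  } else data.frame(cost = NA_real_, gamma = NA_real_)
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fit <- fit_one(xs[tr, , drop = FALSE], y[tr],
                     grid$cost[g], grid$gamma[g])
      pred <- predict_one(fit, xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(cv_acc)
  fit <- fit_one(xs, y, grid$cost[best], grid$gamma[best])

  structure(list(fit = fit, method = method, center = center,
                 scale = scl, classes = classes,
                 features = risk_factor_features,
                 train_range = apply(x, 2, range),
                 cv_accuracy = cv_acc[best],
                 cv_trace = cbind(grid, accuracy = cv_acc),
                 hyperparameters = as.list(grid[best, , drop = FALSE]),
                 seed = seed),
            class = "cluster_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_classifier <- function(x, ...) {
  cat(sprintf(
    "<cluster_classifier> %s over %d clusters; CV accuracy %.3f\n",
    x$method, length(x$classes), x$cv_accuracy))
  invisible(x)
}

#' Assign participants to the discovery clusters
#'
#' Applies a trained [train_cluster_classifier()] model to a new
#' cohort. Features are standardised with the center and scale frozen
#' at training time (never refit), so validation cohorts are measured
#' on the discovery scale; values outside the training range are
#' predicted anyway with a warning.
#'
#' @param model A `"cluster_classifier"`.
#' @param cohort Cohort with the five risk factors.
#' @return Integer cluster labels, named by `participant_id` when
#'   present.
#' @export
assign_clusters <- function(model, cohort) {
  stopifnot(inherits(model, "cluster_classifier"))
  missing_cols <- setdiff(model$features, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks feature(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(cohort[, model$features])
  storage.mode(x) <- "double"
  out_of_range <- vapply(seq_along(model$features), function(j) {
    any(x[, j] < model$train_range[1, j] |
          x[, j] > model$train_range[2, j])
  }, logical(1))
  if (any(out_of_range))
    warning("feature(s) outside the training range: ",
            paste(model$features[out_of_range], collapse = ", "))
  xs <- scale_features(x, model$center, model$scale)
  pred <- if (model$method == "svm") stats::predict(model$fit, xs)
  else stats::predict(model$fit, newdata = data.frame(xs))
  labels <- as.integer(as.character(pred))
  names(labels) <- if ("participant_id" %in% names(cohort))
    as.character(cohort$participant_id) else rownames(cohort)
  labels
}
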