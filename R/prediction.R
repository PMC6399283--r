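#' Fit a multivariable diabetes risk score
#'
#' Logistic regression of diabetes status on the five risk factors
#' (sex, age, BMI, hypertension, family history). Predictors constant
#' within the fitted subset — common inside a cluster, where e.g.
#' hypertension defines the cluster — are dropped automatically.
#' Complete separation is detected (diverging coefficients) and the
#' model is refit with a small ridge penalty, flagged in the result.
#'
#' @param cohort Cohort subset containing `dm` and the risk factors.
#' @param features Predictor columns (default the five risk factors).
#' @return Object of class `"risk_score"` with `coefficients`,
#'   `features` (those actually used), `dropped`, and `separation`
#'   flag. Use `predict(object, newdata, type = "response")`.
#' @export
fit_risk_score <- function(cohort, features = risk_factor_features) {
  missing_cols <- setdiff(c("dm", features), names(cohort))
  if (length(missing_cols) > 0)
    stop("column(s) missing: ", paste(missing_cols, collapse = ", "))
  y <- cohort$dm
  if (length(unique(y)) < 2L)
    stop("subset contains a single outcome class")
  constant <- vapply(features, function(f)
    length(unique(cohort[[f]])) < 2L, logical(1))
  used <- features[!constant]
  if (length(used) == 0) stop("all predictors are constant")
  dat <- cohort[, c("dm", used)]
  fit <- suppressWarnings(
    stats::glm(dm ~ ., data = dat, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  coefs <- stats::coef(fit)
  if (separation) {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("complete separation detected and 'glmnet' is unavailable ",
           "for the penalised fallback")
    x <- as.matrix(dat[, used, drop = FALSE])
    pen <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 0.01)
    coefs <- stats::setNames(
      as.numeric(stats::coef(pen)), rownames(stats::coef(pen)))
  }
  structure(list(coefficients = coefs, features = used,
                 dropped = features[constant], separation = separation,
                 fit = if (separation) NULL else fit),
            class = "risk_score")
}

#' @export
predict.risk_score <- function(object, newdata,
                               type = c("link", "response"), ...) {
  type <- match.arg(type)
  x <- cbind(1, as.matrix(newdata[, object$features, drop = FALSE]))
  eta <- drop(x %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.risk_score <- function(x, ...) {
  cat("<risk_score> logistic model on:",
      paste(x$features, collapse = ", "), "\n")
  if (length(x$dropped) > 0)
    cat("  dropped (constant):", paste(x$dropped, collapse = ", "), "\n")
  if (x$separation) cat("  complete separation: ridge fallback used\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

## DeLong structural components by midranks: V10 per case, V01 per
## control. AUC = mean(V10) = mean(V01).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both outcome classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' ROC curve and AUC with asymptotic confidence interval
#'
#' AUC by the rank (Mann-Whitney) construction with ties counted 1/2;
#' the 95% CI uses the DeLong variance estimate, the same variance the
#' between-cluster comparison ([compare_auc()]) uses, and is clipped to
#' `[0, 1]`. The ROC staircase is evaluated at every distinct score.
#'
#' @param scores Numeric risk scores (higher = more likely diabetic).
#' @param labels Binary outcomes (0/1).
#' @param cluster Optional cluster id carried into the result.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `"roc_result"`: `auc`, `var`, `ci`,
#'   `n_pos`, `n_neg`, `cluster`, and `roc`, a data frame of
#'   (threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels, cluster = "all",
                    conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be coded 0/1")
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, dc$auc + c(-1, 1) * z * sqrt(v)))
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t)
    mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t)
    mean(scores[labels == 0] < t), numeric(1))
  structure(list(auc = dc$auc, var = v, ci = ci,
                 n_pos = dc$m, n_neg = dc$n, cluster = cluster,
                 conf_level = conf_level,
                 roc = data.frame(threshold = thr, sensitivity = sens,
                                  specificity = spec),
                 v10 = dc$v10, v01 = dc$v01),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC (%s): %.3f, %d%% CI %.3f-%.3f (pos %d, neg %d)\n",
              x$cluster, x$auc, round(100 * x$conf_level),
              x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two AUCs
#'
#' DeLong-style z test of the AUC difference. Clusters are disjoint
#' participant sets, so the default is the unpaired variant, which sums
#' the two independent DeLong variances; `paired = TRUE` uses the full
#' covariance of the structural components and requires both ROC
#' results to come from the same participants in the same order.
#'
#' @param a,b `"roc_result"` objects.
#' @param paired Same-subject comparison?
#' @return List of class `"auc_comparison"`: `difference` (a - b),
#'   `statistic` (z), `p_value`.
#' @export
compare_auc <- function(a, b, paired = FALSE) {
  stopifnot(inherits(a, "roc_result"), inherits(b, "roc_result"))
  diff <- a$auc - b$auc
  if (paired) {
    if (a$n_pos != b$n_pos || a$n_neg != b$n_neg)
      stop("paired comparison requires identical participant sets")
    v <- a$var + b$var -
      2 * (stats::cov(a$v10, b$v10) / a$n_pos +
             stats::cov(a$v01, b$v01) / a$n_neg)
    v <- max(v, 0)
  } else {
    v <- a$var + b$var
  }
  z <- if (v == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / sqrt(v)
  structure(list(difference = diff, statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)), paired = paired,
                 clusters = c(a$cluster, b$cluster)),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC difference %s vs %s: %.3f (z = %.3f, p = %.3g)\n",
              x$clusters[1], x$clusters[2], x$difference, x$statistic,
              x$p_value))
  invisible(x)
}

#' Cluster-specific AUC of the five-factor risk score
#'
#' Fits the logistic risk score separately inside each cluster and
#' evaluates its discrimination there, mirroring the cluster-specific
#' prediction-performance comparison. By default the AUC is apparent
#' (in-sample); set `cv_folds > 1` for a stratified cross-validated
#' AUC from out-of-fold scores.
#'
#' @param cohort Cohort with `dm` and the risk factors.
#' @param assignment Cluster labels.
#' @param cv_folds 1 for apparent AUC, otherwise the number of folds.
#' @return Named list of `"roc_result"` objects, one per cluster.
#' @export
cluster_specific_aucs <- function(cohort, assignment, cv_folds = 1) {
  if (length(assignment) != nrow(cohort))
    stop("assignment must cover the cohort")
  out <- lapply(sort(unique(assignment)), function(cl) {
    sub <- cohort[assignment == cl, , drop = FALSE]
    scores <- if (cv_folds > 1) {
      fold <- stratified_folds(sub$dm, cv_folds)
      s <- numeric(nrow(sub))
      for (f in seq_len(cv_folds)) {
        rs <- fit_risk_score(sub[fold != f, , drop = FALSE])
        s[fold == f] <- predict(rs, sub[fold == f, , drop = FALSE])
      }
      s
    } else {
      predict(fit_risk_score(sub), sub)
    }
    roc_auc(scores, sub$dm, cluster = as.character(cl))
  })
  names(out) <- as.character(sort(unique(assignment)))
  out
}

#' Per-cluster AUC of a single pooled risk model
#'
#' Fits one logistic score on the complete data and evaluates its AUC
#' separately within each cluster, showing how a one-size-fits-all
#' model performs across subpopulations.
#'
#' @inheritParams cluster_specific_aucs
#' @return Named list of `"roc_result"` objects per cluster, plus
#'   element `"all"` for the pooled evaluation.
#' @export
single_model_cluster_aucs <- function(cohort, assignment) {
  if (length(assignment) != nrow(cohort))
    stop("assignment must cover the cohort")
  rs <- fit_risk_score(cohort)
  scores <- predict(rs, cohort)
  out <- lapply(sort(unique(assignment)), function(cl) {
    idx <- assignment == cl
    roc_auc(scores[idx], cohort$dm[idx], cluster = as.character(cl))
  })
  names(out) <- as.character(sort(unique(assignment)))
  out$all <- roc_auc(scores, cohort$dm, cluster = "all")
  out
}

#' Sensitivity/specificity sweep of a fasting-glucose threshold
#'
#' For each cluster and each threshold `t` in the grid, computes
#' sensitivity `P(fg >= t | dm = 1)` and specificity
#' `P(fg < t | dm = 0)`. The default grid spans 4.95 to 5.5 mmol/L in
#' 0.05 steps. Clusters lacking an outcome class get `NA` (flagged),
#' never a fabricated estimate.
#'
#' @param fg Fasting glucose, mmol/L.
#' @param labels Binary outcome (0/1).
#' @param assignment Cluster labels (or a single value for pooled).
#' @param grid Threshold grid in mmol/L.
#' @return Object of class `"threshold_sweep"`: data frame (cluster,
#'   threshold, sensitivity, specificity).
#' @export
threshold_sweep <- function(fg, labels, assignment = rep("all", length(fg)),
                            grid = seq(4.95, 5.5, by = 0.05)) {
  stopifnot(length(fg) == length(labels),
            length(fg) == length(assignment))
  if (!all(labels %in% c(0, 1))) stop("labels must be coded 0/1")
  rows <- list()
  for (cl in sort(unique(assignment))) {
    idx <- assignment == cl
    pos <- fg[idx & labels == 1]; neg <- fg[idx & labels == 0]
    if (length(pos) == 0 || length(neg) == 0)
      warning("cluster ", cl, " lacks an outcome class; ",
              "entries set to NA")
    sens <- if (length(pos) > 0)
      vapply(grid, function(t) mean(pos >= t), numeric(1))
    else rep(NA_real_, length(grid))
    spec <- if (length(neg) > 0)
      vapply(grid, function(t) mean(neg < t), numeric(1))
    else rep(NA_real_, length(grid))
    rows[[as.character(cl)]] <- data.frame(
      cluster = as.character(cl), threshold = grid,
      sensitivity = sens, specificity = spec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("threshold_sweep", "data.frame"))
}
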