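## Keep only participants contributing to follow-up: non-diabetic at
## baseline with a recorded disease-free interval.
followup_subset <- function(cohort, assignment) {
  if (length(assignment) != nrow(cohort))
    stop("assignment must cover the cohort")
  if (!all(c("followup_months", "event") %in% names(cohort)))
    stop("cohort lacks followup_months/event columns")
  keep <- cohort$dm == 0 & !is.na(cohort$followup_months) &
    !is.na(cohort$event)
  if ("dm" %in% names(cohort) && any(cohort$dm == 1))
    message(sum(cohort$dm == 1),
            " baseline-diabetic row(s) excluded from follow-up analysis")
  list(time = cohort$followup_months[keep],
       event = cohort$event[keep],
       cluster = factor(assignment[keep]))
}

#' Kaplan-Meier disease-free survival per cluster
#'
#' Product-limit estimate of the disease-free interval from baseline to
#' diabetes diagnosis or end of follow-up, stratified by cluster.
#' Follow-up times are monthly-recorded; simultaneous events at the
#' same month are handled by the standard tied-death convention.
#' Baseline diabetics are excluded.
#'
#' @param cohort Cohort with `followup_months`, `event`, `dm`.
#' @param assignment Cluster labels, one per cohort row.
#' @return Object of class `"km_curves"`: a list with one data frame
#'   per cluster (`time`, `n_risk`, `n_event`, `n_censor`, `surv`).
#' @export
km_curves <- function(cohort, assignment) {
  d <- followup_subset(cohort, assignment)
  if (any(table(d$cluster) == 0)) stop("cluster with no follow-up rows")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ cluster,
    data = data.frame(time = d$time, event = d$event,
                      cluster = d$cluster))
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) {
    factor(rep(levels(d$cluster)[1], length(sm$time)))
  } else sm$strata
  curves <- lapply(split(seq_along(sm$time), strata), function(idx) {
    data.frame(time = sm$time[idx], n_risk = sm$n.risk[idx],
               n_event = sm$n.event[idx], n_censor = sm$n.censor[idx],
               surv = sm$surv[idx])
  })
  names(curves) <- sub("^cluster=", "", names(curves))
  structure(curves, class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  for (cl in names(x)) {
    final <- x[[cl]][nrow(x[[cl]]), ]
    cat(sprintf("cluster %s: %d time points, S(%g) = %.3f\n",
                cl, nrow(x[[cl]]), final$time, final$surv))
  }
  invisible(x)
}

#' k-sample log-rank test across clusters
#'
#' Tests whether the diabetes-free survival distributions differ
#' between clusters (df = k - 1).
#'
#' @inheritParams km_curves
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(cohort, assignment) {
  d <- followup_subset(cohort, assignment)
  if (sum(d$event) == 0) stop("no events observed")
  if (nlevels(droplevels(d$cluster)) < 2L)
    stop("need at least 2 clusters with follow-up")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ cluster,
    data = data.frame(time = d$time, event = d$event,
                      cluster = droplevels(d$cluster)))
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cumulative incidence of diabetes per cluster
#'
#' The published definition: new cases during follow-up divided by the
#' cluster's initial at-risk count (a simple proportion, ignoring
#' censoring time).
#'
#' @inheritParams km_curves
#' @return Named numeric vector of per-cluster incidence proportions.
#' @export
cumulative_incidence <- function(cohort, assignment) {
  d <- followup_subset(cohort, assignment)
  at_risk <- table(d$cluster)
  if (any(at_risk == 0)) stop("empty cluster in follow-up data")
  events <- tapply(d$event, d$cluster, sum)
  out <- as.numeric(events) / as.numeric(at_risk)
  names(out) <- names(at_risk)
  out
}

#' Two-way ANOVA of a biomarker by cluster and diabetes status
#'
#' Fits the two-factor linear model with interaction
#' `value ~ cluster * dm` and reports sums of squares, F and p per
#' effect. For unbalanced data the default is Type II sums of squares
#' (each main effect adjusted for the other; the interaction term is
#' identical across types); sequential Type I and marginal Type III
#' (sum-to-zero contrasts) are available. The restriction to
#' participants never previously diagnosed is applied by the caller
#' (filter on `prior_dx` upstream).
#'
#' @param values Numeric biomarker vector.
#' @param cluster Cluster labels.
#' @param dm Diabetes status (0/1).
#' @param type Sums-of-squares convention: `"II"`, `"I"`, or `"III"`.
#' @param biomarker Optional name carried into the result.
#' @return Object of class `"anova_result"`: data frame with rows
#'   cluster, dm, interaction, residual and columns `ss`, `df`,
#'   `statistic`, `p_value`; attribute `"empty_cells"` flags an
#'   inestimable interaction.
#' @export
two_way_anova <- function(values, cluster, dm, type = c("II", "I", "III"),
                          biomarker = NULL) {
  type <- match.arg(type)
  stopifnot(length(values) == length(cluster),
            length(values) == length(dm))
  ok <- !is.na(values) & !is.na(cluster) & !is.na(dm)
  values <- values[ok]
  cl <- droplevels(factor(cluster[ok]))
  dmf <- droplevels(factor(dm[ok]))
  if (nlevels(cl) < 2L) stop("need at least 2 clusters")
  if (nlevels(dmf) < 2L) stop("both diabetes groups must be present")
  empty <- any(table(cl, dmf) == 0)
  if (empty)
    warning("empty cluster-by-status cell; ",
            "the interaction is not estimable in that cell")

  k <- nlevels(cl)
  dat <- data.frame(y = values, cl = cl, dmf = dmf)
  full <- stats::lm(y ~ cl * dmf, data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  ms_res <- rss_full / df_res

  rss <- function(formula) sum(stats::residuals(
    stats::lm(formula, data = dat))^2)
  if (type == "II") {
    rss_add <- rss(y ~ cl + dmf)
    ss <- c(cluster = rss(y ~ dmf) - rss_add,
            dm = rss(y ~ cl) - rss_add,
            interaction = rss_add - rss_full)
  } else if (type == "I") {
    a <- stats::anova(full)
    ss <- c(cluster = a["cl", "Sum Sq"], dm = a["dmf", "Sum Sq"],
            interaction = a["cl:dmf", "Sum Sq"])
  } else {
    opts <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(opts), add = TRUE)
    full3 <- stats::lm(y ~ cl * dmf, data = dat)
    X <- stats::model.matrix(full3)
    asg <- attr(X, "assign")
    rss_drop <- function(term) {
      keep <- asg != term
      f <- stats::lm.fit(X[, keep, drop = FALSE], values)
      sum(f$residuals^2)
    }
    rss_f3 <- sum(stats::residuals(full3)^2)
    ss <- c(cluster = rss_drop(1) - rss_f3, dm = rss_drop(2) - rss_f3,
            interaction = rss_drop(3) - rss_f3)
  }
  dfs <- c(cluster = k - 1, dm = 1, interaction = k - 1)
  fstat <- (ss / dfs) / ms_res
  pval <- stats::pf(fstat, dfs, df_res, lower.tail = FALSE)
  tab <- data.frame(
    effect = c("cluster", "dm", "interaction", "residual"),
    ss = c(ss, rss_full), df = c(dfs, df_res),
    statistic = c(fstat, NA), p_value = c(pval, NA),
    row.names = NULL)
  structure(tab, class = c("anova_result", "data.frame"),
            biomarker = biomarker, type = type, empty_cells = empty)
}

#' @export
print.anova_result <- function(x, ...) {
  bm <- attr(x, "biomarker")
  cat(sprintf("Two-way ANOVA%s (Type %s SS)\n",
              if (is.null(bm)) "" else paste0(" of ", bm),
              attr(x, "type")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
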