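## Published per-cluster composition of the six risk-factor clusters
## (discovery cohort n = 10023; cross-sectional validation n = 215083).
## These printed counts and moments parameterise the synthetic-cohort
## generator and serve as fixtures for the heterogeneity statistics.

published_composition <- function(cohort = c("discovery", "validation")) {
  cohort <- match.arg(cohort)
  if (cohort == "discovery") {
    data.frame(
      cluster  = paste0("CL", 1:6),
      n        = c(1985, 3241, 862, 1013, 2645, 277),
      male     = c(1985, 0, 374, 1013, 1258, 122),
      female   = c(0, 3241, 488, 0, 1387, 155),
      age_mean = c(45.72, 51.04, 47.89, 61.87, 56.41, 53.27),
      age_sd   = c(4.13, 8.74, 6.90, 4.23, 8.57, 8.45),
      bmi_mean = c(24.22, 24.35, 24.61, 23.11, 25.50, 26.20),
      bmi_sd   = c(2.81, 3.15, 2.95, 2.90, 3.21, 3.06),
      htn      = c(0, 0, 0, 0, 1, 1),
      fhdm     = c(0, 0, 1, 0, 0, 1),
      ndm      = c(1808, 2937, 690, 807, 2050, 156),
      dm       = c(177, 304, 172, 206, 595, 121))
  } else {
    data.frame(
      cluster  = paste0("CL", 1:6),
      n        = c(24768, 83436, 27465, 19271, 50155, 9988),
      male     = c(24768, 0, 8099, 19271, 21231, 3784),
      female   = c(0, 83436, 19366, 0, 28924, 6204),
      age_mean = c(46.84, 51.90, 50.55, 61.70, 57.33, 55.50),
      age_sd   = c(4.66, 7.91, 7.72, 4.41, 7.80, 7.95),
      bmi_mean = c(24.09, 23.40, 23.73, 23.60, 25.09, 25.29),
      bmi_sd   = c(2.88, 2.85, 2.88, 2.62, 3.06, 3.03),
      htn      = c(0, 0, 0, 0, 1, 1),
      fhdm     = c(0, 0, 1, 0, 0, 1),
      ndm      = c(23761, 80783, 24390, 17374, 41636, 6823),
      dm       = c(1007, 2653, 3075, 1897, 8519, 3165))
  }
}

#' Published diabetes-by-cluster counts
#'
#' The 2 x 6 nondiabetic/diabetic counts per cluster as printed for the
#' discovery cohort (n = 10023) and the cross-sectional validation
#' cohort (n = 215083). These are the tables on which the published
#' heterogeneity statistics (discovery P = 3.16e-95; validation
#' P < 2.2e-16) were computed.
#'
#' @param cohort `"discovery"` or `"validation"`.
#' @return A `"prevalence_table"` with columns CL1..CL6.
#' @examples
#' prevalence(published_cluster_counts("discovery"))
#' chi_square_heterogeneity(published_cluster_counts("discovery"))
#' @export
published_cluster_counts <- function(cohort = c("discovery", "validation")) {
  comp <- published_composition(match.arg(cohort))
  as_prevalence_table(comp$ndm, comp$dm, labels = comp$cluster)
}
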