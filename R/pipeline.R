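#' Run the discovery stage of risk-factor-based clustering
#'
#' Executes the full discovery pipeline on a validated cohort: Gower
#' dissimilarity over the five risk factors, complete-linkage
#' agglomeration, cluster-count selection by chi-square prevalence
#' heterogeneity, and prevalence-ordered relabelling. When
#' `output_dir` is given, all artefacts (assignment, k-selection
#' trace, prevalence table, heterogeneity test, and a reproducibility
#' manifest) are written there; re-running with the same inputs
#' reproduces them.
#'
#' @param cohort Validated cohort with the five risk factors and `dm`.
#' @param specs Variable specification (default
#'   [default_variable_specs()]).
#' @param k_min,k_max Cluster-count scan range.
#' @param output_dir Optional directory for artefact files.
#' @return Object of class `"rfc_discovery"`: `dist`, `tree`,
#'   `k_selection`, `assignment` (prevalence-ordered),
#'   `table` (a `"prevalence_table"`), and `heterogeneity`.
#' @export
run_discover <- function(cohort, specs = default_variable_specs(),
                         k_min = 2, k_max = 12, output_dir = NULL) {
  d <- gower_matrix(cohort, specs)
  tree <- complete_linkage(d)
  sel <- select_k(tree, cohort$dm, k_min = k_min, k_max = k_max)
  assignment <- label_by_prevalence(cut_tree(tree, sel$selected_k),
                                    cohort$dm)
  names(assignment) <- if ("participant_id" %in% names(cohort))
    as.character(cohort$participant_id) else rownames(cohort)
  tab <- prevalence_table(assignment, cohort$dm)
  het <- suppressWarnings(chi_square_heterogeneity(tab))
  res <- structure(list(dist = d, tree = tree, k_selection = sel,
                        assignment = assignment, table = tab,
                        heterogeneity = het),
                   class = "rfc_discovery")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(assignment, file.path(output_dir, "assignment.csv"))
    write_results(sel, file.path(output_dir, "k_selection.json"))
    write_results(tab, file.path(output_dir, "prevalence_table.csv"))
    write_results(het, file.path(output_dir, "heterogeneity.json"))
    manifest <- list(
      stage = "discover", n = nrow(cohort),
      k_min = k_min, k_max = k_max, selected_k = sel$selected_k,
      variable_specs = lapply(attr(d, "variable_specs"), unclass),
      package_version = as.character(utils::packageVersion("rfclust")),
      r_version = R.version.string)
    jsonlite::write_json(manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.rfc_discovery <- function(x, ...) {
  cat("Risk-factor-based clustering (discovery)\n")
  print(x$k_selection)
  print(x$table)
  print(x$heterogeneity)
  invisible(x)
}

#' Run the validation stage on an independent cohort
#'
#' Transfers the discovery clusters to a new cohort with a trained
#' classifier, then reproduces the cluster characterisation there:
#' prevalence table, chi-square heterogeneity, cluster-specific AUCs of
#' the five-factor score, and (when fasting glucose is present) the
#' FG threshold sweep.
#'
#' @param model A [train_cluster_classifier()] model.
#' @param cohort Validated independent cohort.
#' @param output_dir Optional directory for artefact files.
#' @return Object of class `"rfc_validation"`: `assignment`, `table`,
#'   `heterogeneity`, `aucs`, and `sweep` (or `NULL`).
#' @export
run_validate <- function(model, cohort, output_dir = NULL) {
  if (nrow(cohort) == 0) stop("validation cohort is empty")
  assignment <- assign_clusters(model, cohort)
  tab <- prevalence_table(assignment, cohort$dm)
  het <- suppressWarnings(chi_square_heterogeneity(tab))
  aucs <- cluster_specific_aucs(cohort, assignment)
  sweep <- if ("fg" %in% names(cohort))
    threshold_sweep(cohort$fg, cohort$dm, assignment) else NULL
  res <- structure(list(assignment = assignment, table = tab,
                        heterogeneity = het, aucs = aucs,
                        sweep = sweep),
                   class = "rfc_validation")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(assignment, file.path(output_dir, "assignment.csv"))
    write_results(tab, file.path(output_dir, "prevalence_table.csv"))
    write_results(het, file.path(output_dir, "heterogeneity.json"))
    auc_df <- do.call(rbind, lapply(aucs, function(a)
      data.frame(cluster = a$cluster, auc = a$auc,
                 ci_lo = a$ci[1], ci_hi = a$ci[2],
                 n_pos = a$n_pos, n_neg = a$n_neg)))
    write_results(auc_df, file.path(output_dir, "cluster_aucs.csv"))
    if (!is.null(sweep))
      write_results(as.data.frame(sweep),
                    file.path(output_dir, "threshold_sweep.csv"))
  }
  res
}

#' @export
print.rfc_validation <- function(x, ...) {
  cat("Cluster transfer to validation cohort\n")
  ord <- order(prevalence(x$table))
  print(x$table[, ord, drop = FALSE])
  print(x$heterogeneity)
  for (a in x$aucs) print(a)
  invisible(x)
}
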