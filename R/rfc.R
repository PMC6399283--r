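#' Agglomerative clustering with complete linkage
#'
#' Hierarchical clustering of a Gower dissimilarity where the distance
#' between clusters is the maximum pairwise dissimilarity between their
#' members (complete agglomeration). This is the merge tree the
#' cluster-count selection rule ([select_k()]) scans.
#'
#' @param dist A `"dist"` object, e.g. from [gower_matrix()].
#' @return An `"hclust"` merge tree (n - 1 merges, non-decreasing merge
#'   heights).
#' @export
complete_linkage <- function(dist) {
  stopifnot(inherits(dist, "dist"))
  if (attr(dist, "Size") < 2L) stop("need at least 2 observations")
  stats::hclust(dist, method = "complete")
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges of the tree, yielding the `k`-group
#' membership. Labels follow the tree's observation order convention
#' (first appearance order), so cluster ids are arbitrary until
#' [label_by_prevalence()] renumbers them.
#'
#' @param tree An `"hclust"` object from [complete_linkage()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster ids in `1..k`, named by the tree's
#'   labels when present.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must lie in 1..", n)
  stats::cutree(tree, k = as.integer(k))
}

#' Cross-tabulate diabetes status by cluster
#'
#' Builds the 2 x k table of nondiabetic (`ndm`) and diabetic (`dm`)
#' counts per cluster on which the heterogeneity test operates.
#'
#' @param assignment Integer cluster ids (one per participant).
#' @param dm Binary diabetes status vector (0/1), same length.
#' @return An object of class `"prevalence_table"`: a 2 x k integer
#'   matrix with rows `ndm`, `dm` and cluster ids as column names.
#' @seealso [prevalence()], [chi_square_heterogeneity()]
#' @export
prevalence_table <- function(assignment, dm) {
  if (length(assignment) != length(dm))
    stop("assignment and dm must have the same length")
  if (!all(dm %in% c(0, 1))) stop("dm must be coded 0/1")
  cl <- sort(unique(assignment))
  tab <- vapply(cl, function(g) {
    c(ndm = sum(assignment == g & dm == 0),
      dm  = sum(assignment == g & dm == 1))
  }, numeric(2))
  colnames(tab) <- as.character(cl)
  new_prevalence_table(tab)
}

new_prevalence_table <- function(tab) {
  stopifnot(is.matrix(tab), nrow(tab) == 2L, all(tab >= 0))
  rownames(tab) <- c("ndm", "dm")
  storage.mode(tab) <- "double"
  structure(tab, class = c("prevalence_table", "matrix"))
}

#' Construct a prevalence table from published per-cluster counts
#'
#' @param ndm,dm Nondiabetic and diabetic counts per cluster.
#' @param labels Optional cluster names.
#' @return A `"prevalence_table"`.
#' @export
as_prevalence_table <- function(ndm, dm, labels = NULL) {
  stopifnot(length(ndm) == length(dm))
  tab <- rbind(ndm = as.numeric(ndm), dm = as.numeric(dm))
  colnames(tab) <- if (is.null(labels)) as.character(seq_along(ndm)) else labels
  new_prevalence_table(tab)
}

#' Per-cluster prevalence of the outcome
#'
#' @param table A `"prevalence_table"`.
#' @return Named numeric vector `dm / (ndm + dm)` per cluster.
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "prevalence_table"))
  drop(table["dm", ] / colSums(table))
}

#' @export
print.prevalence_table <- function(x, digits = 2, ...) {
  cat("Diabetes status by cluster (2 x", ncol(x), ")\n")
  print(unclass(x))
  cat("prevalence:",
      paste(sprintf("%s=%.*f", colnames(x), digits, prevalence(x)),
            collapse = "  "), "\n")
  invisible(x)
}

#' Chi-square heterogeneity of prevalence across clusters
#'
#' Pearson chi-square without continuity correction on the 2 x k
#' cluster-by-status table, df = k - 1. The p-value is computed and
#' stored on the natural-log scale so that the extreme significance
#' levels this analysis produces (p well below the smallest
#' representable double) survive; `p_value` is the back-transformed
#' value and underflows to 0 beyond about 1e-308.
#'
#' @param table A `"prevalence_table"` or any 2 x k count matrix.
#' @return List of class `"chisq_heterogeneity"` with `statistic`,
#'   `df`, `log_p` (natural log), and `p_value`.
#' @export
chi_square_heterogeneity <- function(table) {
  tab <- unclass(table)
  if (!is.matrix(tab) || nrow(tab) != 2L)
    stop("expected a 2 x k count table")
  if (ncol(tab) < 2L) stop("need at least 2 clusters")
  if (any(tab < 0)) stop("negative counts")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  expected <- outer(rs, cs) / n
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero expected count in cell (%s, %s)",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]]))
  }
  if (any(expected < 5))
    warning("some expected counts are below 5; ",
            "the chi-square approximation may be inaccurate")
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  log_p <- stats::pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE)
  structure(list(statistic = stat, df = df, log_p = log_p,
                 p_value = exp(log_p)),
            class = "chisq_heterogeneity")
}

#' @export
print.chisq_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "Chi-square heterogeneity: X2 = %.4g, df = %d, log10(p) = %.2f\n",
    x$statistic, x$df, x$log_p / log(10)))
  invisible(x)
}

#' Select the number of clusters by outcome heterogeneity
#'
#' Scans `k = k_min, ..., k_max`: at each `k` the tree is cut, the
#' 2 x k prevalence table built, and its chi-square heterogeneity
#' tested, with p-values compared on the log scale.
#'
#' Two stopping policies are offered. The default, `"max"`, selects
#' the `k` at which the heterogeneity is most significant over the
#' whole scan range (clustering until the prevalence heterogeneity is
#' maximised; ties go to the smaller `k`). The sequential variant
#' `"first_drop"` stops at the first `k` whose log p-value is strictly
#' smaller (more significant) than at `k + 1`, continuing on exact
#' ties. The two coincide when significance rises monotonically to a
#' single peak; `"first_drop"` is order-sensitive and halts early on
#' trees whose first split already isolates the dominant risk stratum,
#' which is why `"max"` is the default.
#'
#' @param tree An `"hclust"` object.
#' @param dm Binary outcome vector in tree order.
#' @param k_min,k_max Scan range (defaults 2 and 12).
#' @param policy `"max"` or `"first_drop"` (see Details).
#' @param min_cluster_size Cuts producing a cluster smaller than this
#'   floor are noted in the trace (default 1, i.e. no floor).
#' @return Object of class `"k_selection"`: `selected_k`, `reason`,
#'   and `trace`, a data frame with one row per evaluated `k`
#'   (statistic, df, log_p, smallest cluster size). Under `"max"` the
#'   trace always covers the full range; under `"first_drop"` it ends
#'   one past the selected `k`.
#' @export
select_k <- function(tree, dm, k_min = 2, k_max = 12,
                     policy = c("max", "first_drop"),
                     min_cluster_size = 1) {
  policy <- match.arg(policy)
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (length(dm) != n) stop("dm must have one value per observation")
  if (!all(dm %in% c(0, 1))) stop("dm must be coded 0/1")
  if (k_min < 2) stop("k_min must be at least 2")
  if (k_max >= n) stop("k_max must be below the number of observations")
  if (k_max < k_min) stop("k_max must be >= k_min")
  if (length(unique(dm)) < 2L)
    stop("outcome is constant; heterogeneity is undefined")

  ks <- k_min:k_max
  eval_k <- function(k) {
    a <- cut_tree(tree, k)
    tab <- prevalence_table(a, dm)
    ct <- suppressWarnings(chi_square_heterogeneity(tab))
    c(statistic = ct$statistic, df = ct$df, log_p = ct$log_p,
      min_size = min(colSums(tab)))
  }
  rows <- matrix(NA_real_, nrow = length(ks), ncol = 4,
                 dimnames = list(NULL,
                                 c("statistic", "df", "log_p", "min_size")))
  if (policy == "max") {
    for (i in seq_along(ks)) rows[i, ] <- eval_k(ks[i])
    best <- which.min(rows[, "log_p"])
    selected <- ks[best]
    reason <- if (selected == k_max) "scan exhausted"
    else "heterogeneity maximum"
  } else {
    selected <- NA_integer_; reason <- "scan exhausted"
    rows[1, ] <- eval_k(ks[1])
    for (i in seq_along(ks)) {
      if (i < length(ks)) {
        rows[i + 1, ] <- eval_k(ks[i + 1])
        if (rows[i, "log_p"] < rows[i + 1, "log_p"]) {
          selected <- ks[i]; reason <- "heterogeneity peak"
          rows <- rows[seq_len(i + 1), , drop = FALSE]
          ks <- ks[seq_len(i + 1)]
          break
        }
      } else {
        selected <- ks[i]
      }
    }
  }
  trace <- data.frame(k = ks, rows, row.names = NULL)
  if (any(trace$min_size < min_cluster_size))
    trace$below_floor <- trace$min_size < min_cluster_size
  structure(list(selected_k = as.integer(selected), reason = reason,
                 trace = trace),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Selected k = %d (%s)\n", x$selected_k, x$reason))
  tr <- x$trace
  tr$log10_p <- tr$log_p / log(10)
  print(tr[, c("k", "statistic", "df", "log10_p")], digits = 4,
        row.names = FALSE)
  invisible(x)
}

#' Renumber clusters by ascending diabetes prevalence
#'
#' The published convention labels clusters CL1..CLk from the lowest to
#' the highest prevalence. Ties on unrounded prevalence are broken by
#' descending cluster size, then by original label.
#'
#' @param assignment Integer cluster ids.
#' @param dm Binary outcome vector.
#' @return Relabelled integer assignment; attribute `"mapping"` gives
#'   the old-to-new label map (names = old labels).
#' @export
label_by_prevalence <- function(assignment, dm) {
  tab <- prevalence_table(assignment, dm)
  prev <- prevalence(tab)
  size <- colSums(tab)
  ord <- order(prev, -size, as.integer(colnames(tab)))
  mapping <- integer(length(ord))
  names(mapping) <- colnames(tab)[ord]
  mapping[] <- seq_along(ord)
  out <- mapping[as.character(assignment)]
  names(out) <- names(assignment)
  attr(out, "mapping") <- mapping[order(as.integer(names(mapping)))]
  out
}

#' Adjusted Rand agreement between two partitions
#'
#' Chance-corrected agreement (Hubert-Arabie adjusted Rand index)
#' between a recovered clustering and a reference partition, used to
#' quantify how faithfully the pipeline recovers planted clusters.
#'
#' @param a,b Two label vectors of equal length.
#' @return Adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
cluster_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Export a merge tree in Newick format
#'
#' Writes the dendrogram as a Newick string (branch lengths derived
#' from merge heights) for inspection in standard tree viewers.
#'
#' @param tree An `"hclust"` object.
#' @param path Output file path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_dendrogram <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
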