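#' Describe one variable entering the Gower dissimilarity
#'
#' The five diabetes risk factors mix continuous measurements (age, BMI)
#' with presence/absence indicators (hypertension, family history, and,
#' under the study's coding, female sex). Each variable is declared as
#' `numeric` (absolute difference scaled by the variable's range),
#' `binary_asymmetric` (joint absence carries no information: a 0-0 pair
#' is dropped from the weighted average), or `binary_symmetric`
#' (simple matching).
#'
#' @param name Column name in the cohort table.
#' @param kind One of `"numeric"`, `"binary_asymmetric"`,
#'   `"binary_symmetric"`.
#' @param range For numeric variables, optional `c(min, max)` override.
#'   When `NULL` the range is computed from the data handed to
#'   [gower_matrix()] and stored, so that distances for a later cohort
#'   can reuse the discovery ranges.
#' @param weight Non-negative weight (default 1).
#' @return An object of class `"variable_spec"`.
#' @seealso [default_variable_specs()], [gower_pair()], [gower_matrix()]
#' @export
variable_spec <- function(name,
                          kind = c("numeric", "binary_asymmetric",
                                   "binary_symmetric"),
                          range = NULL, weight = 1) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(weight), length(weight) == 1L, weight >= 0)
  if (!is.null(range)) {
    stopifnot(is.numeric(range), length(range) == 2L)
    if (kind != "numeric")
      stop("'range' only applies to numeric variables")
    if (diff(range) < 0)
      stop("range must satisfy max >= min for variable '", name, "'")
  }
  structure(list(name = name, kind = kind, range = range, weight = weight),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  rng <- if (is.null(x$range)) "data-derived" else
    paste0("[", x$range[1], ", ", x$range[2], "]")
  cat(sprintf("<variable_spec> %s: %s, range %s, weight %g\n",
              x$name, x$kind, rng, x$weight))
  invisible(x)
}

#' Default variable specification for the five risk factors
#'
#' Age and BMI are numeric; hypertension and family history of diabetes
#' are asymmetric binaries (sharing the absence of a risk factor is not
#' evidence of similarity). Sex, coded male = 0 / female = 1, is treated
#' as an asymmetric binary by default, so male-male pairs contribute no
#' sex term; set `sex_kind = "binary_symmetric"` for simple matching.
#'
#' @param sex_kind How to compare the sex indicator.
#' @return List of five [variable_spec()] objects (sex, age, bmi, htn,
#'   fhdm).
#' @export
default_variable_specs <- function(sex_kind = c("binary_asymmetric",
                                                "binary_symmetric")) {
  sex_kind <- match.arg(sex_kind)
  list(variable_spec("sex", sex_kind),
       variable_spec("age", "numeric"),
       variable_spec("bmi", "numeric"),
       variable_spec("htn", "binary_asymmetric"),
       variable_spec("fhdm", "binary_asymmetric"))
}

kind_code <- function(kind) {
  match(kind, c("numeric", "binary_asymmetric", "binary_symmetric")) - 1L
}

## Fill data-derived ranges; validate overridden ones against the data.
resolve_specs <- function(specs, data) {
  stopifnot(length(specs) >= 1L)
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  w <- vapply(specs, function(s) s$weight, numeric(1))
  if (all(w == 0)) stop("variable weights must not all be zero")
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!s$name %in% colnames(data))
      stop("variable '", s$name, "' not found in the data")
    x <- data[[s$name]]
    if (anyNA(x))
      stop("missing values in variable '", s$name,
           "'; exclude them before computing distances")
    if (s$kind == "numeric") {
      if (is.null(s$range)) {
        specs[[i]]$range <- range(x)
      } else if (any(x < s$range[1] | x > s$range[2])) {
        stop("values of '", s$name, "' fall outside the declared range")
      }
      if (diff(specs[[i]]$range) == 0)
        warning("numeric variable '", s$name,
                "' is constant; its Gower contribution is 0")
    } else if (!all(x %in% c(0, 1))) {
      stop("binary variable '", s$name, "' must contain only 0/1")
    }
  }
  specs
}

#' Gower dissimilarity between two risk-factor profiles
#'
#' Computes `sum(w_v * delta_v * d_v) / sum(w_v * delta_v)` over the
#' declared variables, where numeric variables contribute
#' `|a_v - b_v| / range_v` with `delta_v = 1`, symmetric binaries
#' contribute 0/1 matching, and asymmetric binaries are excluded
#' (`delta_v = 0`) when both profiles are 0. If every variable drops
#' out (possible only when all variables are jointly-absent asymmetric
#' binaries) the distance is defined as 0 with a warning.
#'
#' @param a,b Named vectors, lists, or one-row data frames holding the
#'   variables named in `specs`.
#' @param specs List of [variable_spec()]; numeric specs must carry
#'   explicit ranges here (there is no data to derive them from).
#' @return A single dissimilarity in `[0, 1]`.
#' @examples
#' specs <- list(variable_spec("sex", "binary_asymmetric"),
#'               variable_spec("age", "numeric", range = c(40, 70)),
#'               variable_spec("bmi", "numeric", range = c(20, 30)),
#'               variable_spec("htn", "binary_asymmetric"),
#'               variable_spec("fhdm", "binary_asymmetric"))
#' gower_pair(c(sex = 1, age = 50, bmi = 25, htn = 1, fhdm = 0),
#'            c(sex = 1, age = 60, bmi = 25, htn = 0, fhdm = 0),
#'            specs) # (0 + 10/30 + 0 + 1) / 4 = 1/3
#' @export
gower_pair <- function(a, b, specs) {
  a <- as.list(a); b <- as.list(b)
  num <- 0; den <- 0
  for (s in specs) {
    av <- as.numeric(a[[s$name]]); bv <- as.numeric(b[[s$name]])
    if (length(av) != 1L || length(bv) != 1L || anyNA(c(av, bv)))
      stop("profiles must provide a single non-missing value for '",
           s$name, "'")
    if (s$kind == "numeric") {
      if (is.null(s$range))
        stop("numeric variable '", s$name,
             "' needs an explicit range for pairwise evaluation")
      if (any(c(av, bv) < s$range[1]) || any(c(av, bv) > s$range[2]))
        stop("value of '", s$name, "' outside its declared range")
      rng <- diff(s$range)
      num <- num + if (rng > 0) s$weight * abs(av - bv) / rng else 0
      den <- den + s$weight
    } else if (s$kind == "binary_asymmetric") {
      if (av == 0 && bv == 0) next
      num <- num + s$weight * (av != bv)
      den <- den + s$weight
    } else {
      num <- num + s$weight * (av != bv)
      den <- den + s$weight
    }
  }
  if (den == 0) {
    warning("all variables dropped out of the Gower average; ",
            "distance defined as 0")
    return(0)
  }
  num / den
}

#' Pairwise Gower dissimilarity matrix for a cohort
#'
#' Computes all pairwise dissimilarities over the declared variables and
#' returns them as a condensed `"dist"` object (upper triangle, double
#' precision) ready for [complete_linkage()]. Numeric ranges left
#' unspecified are computed from this cohort and stored in the result's
#' `"variable_specs"` attribute, so later cohorts can be measured on the
#' discovery scale.
#'
#' @param cohort Data frame with one row per participant.
#' @param specs List of [variable_spec()]; defaults to
#'   [default_variable_specs()].
#' @return A `"dist"` object with attributes `"variable_specs"` (the
#'   resolved specs) and `"Labels"` (participant ids when present).
#' @export
gower_matrix <- function(cohort, specs = default_variable_specs()) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) < 2L) stop("need at least 2 rows")
  specs <- resolve_specs(specs, cohort)
  x <- vapply(specs, function(s) as.numeric(cohort[[s$name]]),
              numeric(nrow(cohort)))
  if (!is.matrix(x)) x <- matrix(x, nrow = nrow(cohort))
  res <- gower_condensed_cpp(
    x,
    kind_code(vapply(specs, `[[`, character(1), "kind")),
    vapply(specs, function(s) if (is.null(s$range)) 0 else diff(s$range),
           numeric(1)),
    vapply(specs, `[[`, numeric(1), "weight"))
  if (res$n_zero_denom > 0)
    warning(res$n_zero_denom,
            " pair(s) had no contributing variables; distance set to 0")
  if (all(res$d == 0))
    warning("all pairwise distances are zero (identical profiles)")
  labels <- if ("participant_id" %in% colnames(cohort))
    as.character(cohort$participant_id) else rownames(cohort)
  d <- structure(res$d, Size = nrow(cohort), Labels = labels,
                 Diag = FALSE, Upper = FALSE, method = "gower",
                 class = "dist")
  attr(d, "variable_specs") <- specs
  d
}
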