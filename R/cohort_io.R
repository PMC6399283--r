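#' Validate a cohort table
#'
#' Enforces the study's coding conventions on an in-memory table: the
#' five risk factors (sex, age, bmi, htn, fhdm) and diabetes status
#' `dm` must be present; rows missing any of them are removed; rows
#' outside the age window are removed (the study population is 40-70
#' years); when an age-at-diagnosis column is supplied, participants
#' diagnosed before age 20 are excluded (screening out probable type 1
#' diabetes). Binary columns must contain only 0/1 after mapping, and
#' `event = 1` requires a positive follow-up time.
#'
#' @param cohort Data frame, one row per participant.
#' @param age_range Inclusive age window, or `NULL` to disable.
#' @param dx_age_min Minimum age at diagnosis (applied only when a
#'   `dx_age` column exists).
#' @return List with `cohort` (the validated table) and `report`, a
#'   `"validation_report"` holding `n_input`, `n_removed_missing`,
#'   `n_removed_age`, `n_removed_early_dx`, and `messages`. Removal
#'   counts always sum with the retained rows to `n_input`.
#' @export
validate_cohort <- function(cohort, age_range = c(40, 70),
                            dx_age_min = 20) {
  cohort <- as.data.frame(cohort)
  required <- c("sex", "age", "bmi", "htn", "fhdm", "dm")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0)
    stop("required column(s) missing: ",
         paste(missing_cols, collapse = ", "))
  n_input <- nrow(cohort)
  msgs <- character(0)

  for (col in c("age", "bmi"))
    cohort[[col]] <- as.numeric(cohort[[col]])
  keep_complete <- stats::complete.cases(cohort[required])
  n_missing <- sum(!keep_complete)
  if (n_missing > 0)
    msgs <- c(msgs, sprintf(
      "%d row(s) removed for missing risk factors or diabetes status",
      n_missing))
  cohort <- cohort[keep_complete, , drop = FALSE]

  n_age <- 0L
  if (!is.null(age_range)) {
    in_window <- cohort$age >= age_range[1] & cohort$age <= age_range[2]
    n_age <- sum(!in_window)
    if (n_age > 0)
      msgs <- c(msgs, sprintf("%d row(s) outside the %g-%g age window",
                              n_age, age_range[1], age_range[2]))
    cohort <- cohort[in_window, , drop = FALSE]
  }

  n_early <- 0L
  if ("dx_age" %in% names(cohort) && !is.null(dx_age_min)) {
    early <- !is.na(cohort$dx_age) & cohort$dx_age < dx_age_min
    n_early <- sum(early)
    if (n_early > 0)
      msgs <- c(msgs, sprintf(
        "%d row(s) excluded for diabetes diagnosis before age %g",
        n_early, dx_age_min))
    cohort <- cohort[!early, , drop = FALSE]
  }

  for (col in intersect(c("sex", "htn", "fhdm", "dm", "event",
                          "prior_dx"), names(cohort))) {
    vals <- cohort[[col]][!is.na(cohort[[col]])]
    if (!all(vals %in% c(0, 1)))
      stop("non-binary value in column '", col, "'")
  }
  if (all(c("followup_months", "event") %in% names(cohort))) {
    bad <- !is.na(cohort$event) & cohort$event == 1 &
      (is.na(cohort$followup_months) | cohort$followup_months <= 0)
    if (any(bad))
      stop(sum(bad), " row(s) have an event without positive follow-up")
  }
  rownames(cohort) <- NULL
  report <- structure(list(n_input = n_input,
                           n_removed_missing = n_missing,
                           n_removed_age = n_age,
                           n_removed_early_dx = n_early,
                           messages = msgs),
                      class = "validation_report")
  list(cohort = cohort, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  kept <- x$n_input - x$n_removed_missing - x$n_removed_age -
    x$n_removed_early_dx
  cat(sprintf("Validation: %d of %d rows retained\n", kept, x$n_input))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' Read and validate a cohort file
#'
#' Reads a delimited participant table (comma- or tab-separated,
#' chosen by file extension), renames columns to the canonical names
#' via `schema`, recodes values via `value_maps` (e.g. sex given as
#' `"M"`/`"F"`), and applies [validate_cohort()].
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a header.
#' @param schema Named character vector mapping canonical names
#'   (`sex`, `age`, `bmi`, `htn`, `fhdm`, `dm`, and optionally
#'   `participant_id`, `followup_months`, `event`, `fg`, `tchol`,
#'   `tg`, `hdl`, `prior_dx`, `dx_age`) to the file's column names.
#'   Canonically named columns pass through unmapped.
#' @param value_maps Named list of recodings, e.g.
#'   `list(sex = c(M = 0, F = 1))`.
#' @param age_range,dx_age_min Passed to [validate_cohort()].
#' @return As [validate_cohort()]: `list(cohort, report)`.
#' @export
read_cohort <- function(path, schema = NULL, value_maps = NULL,
                        age_range = c(40, 70), dx_age_min = 20) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0)
      stop("mapped column(s) not in file: ",
           paste(missing_src, collapse = ", "))
    for (canon in names(schema))
      names(raw)[names(raw) == schema[[canon]]] <- canon
  }
  if (!is.null(value_maps)) {
    for (col in names(value_maps)) {
      if (!col %in% names(raw)) next
      map <- value_maps[[col]]
      vals <- as.character(raw[[col]])
      unknown <- setdiff(unique(vals[!is.na(vals)]), names(map))
      if (length(unknown) > 0)
        stop("unmapped value(s) in '", col, "': ",
             paste(unknown, collapse = ", "))
      raw[[col]] <- unname(map[vals])
    }
  }
  validate_cohort(raw, age_range = age_range, dx_age_min = dx_age_min)
}

#' Derive diabetes status from laboratory measurements
#'
#' Applies the diagnostic criteria: fasting glucose >= 126 mg/dL
#' (7.0 mmol/L), 2-hour OGTT glucose >= 200 mg/dL (11.1 mmol/L), or
#' HbA1c >= 6.5%, in addition to any recorded previous diagnosis or
#' treatment (`prior_dx`). Glucose units are declared, never guessed.
#'
#' @param cohort Data frame with any of `fg`, `ogtt2h`, `hba1c`,
#'   `prior_dx`.
#' @param glucose_units `"mmol"` (mmol/L) or `"mgdl"` (mg/dL).
#' @return The cohort with a `dm` column (0/1) added or overwritten.
#' @export
derive_diabetes <- function(cohort, glucose_units = c("mmol", "mgdl")) {
  glucose_units <- match.arg(glucose_units)
  fg_cut <- if (glucose_units == "mmol") 7.0 else 126
  ogtt_cut <- if (glucose_units == "mmol") 11.1 else 200
  have <- intersect(c("fg", "ogtt2h", "hba1c", "prior_dx"),
                    names(cohort))
  if (length(have) == 0)
    stop("no diagnostic columns (fg, ogtt2h, hba1c, prior_dx) present")
  crit <- matrix(FALSE, nrow(cohort), 4)
  if ("fg" %in% have) crit[, 1] <- !is.na(cohort$fg) & cohort$fg >= fg_cut
  if ("ogtt2h" %in% have)
    crit[, 2] <- !is.na(cohort$ogtt2h) & cohort$ogtt2h >= ogtt_cut
  if ("hba1c" %in% have)
    crit[, 3] <- !is.na(cohort$hba1c) & cohort$hba1c >= 6.5
  if ("prior_dx" %in% have)
    crit[, 4] <- !is.na(cohort$prior_dx) & cohort$prior_dx == 1
  cohort$dm <- as.integer(rowSums(crit) > 0)
  cohort
}

#' Derive hypertension status from blood pressure and medication
#'
#' Positive when systolic pressure is at least 140 mmHg, diastolic
#' pressure at least 90 mmHg, or antihypertensive medication is
#' recorded.
#'
#' @param cohort Data frame with any of `sbp`, `dbp`, `htn_med`.
#' @return The cohort with an `htn` column added or overwritten.
#' @export
derive_hypertension <- function(cohort) {
  have <- intersect(c("sbp", "dbp", "htn_med"), names(cohort))
  if (length(have) == 0)
    stop("no blood-pressure or medication columns present")
  crit <- matrix(FALSE, nrow(cohort), 3)
  if ("sbp" %in% have) crit[, 1] <- !is.na(cohort$sbp) & cohort$sbp >= 140
  if ("dbp" %in% have) crit[, 2] <- !is.na(cohort$dbp) & cohort$dbp >= 90
  if ("htn_med" %in% have)
    crit[, 3] <- !is.na(cohort$htn_med) & cohort$htn_med == 1
  cohort$htn <- as.integer(rowSums(crit) > 0)
  cohort
}

#' Write analysis artefacts to disk
#'
#' Serialises result objects with a fixed, documented layout so that
#' reloading reproduces the object: prevalence tables as CSV with a
#' `status` column and clusters as columns; k-selection results and
#' heterogeneity tests as JSON; cluster assignments as two-column CSV
#' (`participant_id`, `cluster`); data frames (cohorts) as plain CSV.
#'
#' @param obj Object to write.
#' @param path Output file path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, ...) UseMethod("write_results")

#' @export
write_results.prevalence_table <- function(obj, path, ...) {
  df <- data.frame(status = rownames(obj), unclass(obj),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.k_selection <- function(obj, path, ...) {
  jsonlite::write_json(list(selected_k = obj$selected_k,
                            reason = obj$reason, trace = obj$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.chisq_heterogeneity <- function(obj, path, ...) {
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
write_results.data.frame <- function(obj, path, ...) {
  utils::write.csv(obj, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.default <- function(obj, path, ...) {
  if (is.atomic(obj) && !is.null(names(obj))) {
    utils::write.csv(data.frame(participant_id = names(obj),
                                cluster = unname(unclass(obj))),
                     path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}
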