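#' Construct and validate a paired-evaluator cohort
#'
#' A cohort is a long-format tibble with one row per (case, evaluator):
#' columns `case_id`, `reference_category`, `reference_metabolic`,
#' `reference_respiratory`, `evaluator`, `predicted_category`,
#' `predicted_metabolic`, `predicted_respiratory`. Component flags are
#' logical; categories use the canonical tokens of [abg_categories()].
#' Reference columns must agree across the rows of a case, and every case
#' must carry exactly one row for every evaluator in the roster.
#'
#' `as_cohort()` validates a data frame (filling missing component columns
#' from the categories via [derive_components()]) and stamps it with class
#' `"abg_cohort"` and a `provenance` attribute (`"fixture"`, `"synthetic"`
#' or `"user"`).
#'
#' @param data A data frame in the cohort schema.
#' @param provenance Free-text origin label stored as an attribute.
#' @return A validated cohort tibble of class `"abg_cohort"`.
#' @export
as_cohort <- function(data, provenance = "user") {
  data <- tibble::as_tibble(data)
  required <- c("case_id", "reference_category", "evaluator", "predicted_category")
  problems <- character()
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop(sprintf("Cohort is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("reference", "predicted")) {
    for (axis in c("metabolic", "respiratory")) {
      nm <- paste(col, axis, sep = "_")
      if (!nm %in% names(data)) {
        # derive only for valid tokens so bad ones still reach the
        # problem enumeration below instead of failing here
        vals <- data[[paste0(col, "_category")]]
        ok <- vals %in% abg_categories()
        comp <- rep(NA, length(vals))
        comp[ok] <- derive_components(vals[ok])[[axis]]
        data[[nm]] <- comp
      } else if (!is.logical(data[[nm]])) {
        data[[nm]] <- as.logical(as.integer(data[[nm]]))
      }
    }
  }
  data <- data[, c("case_id", "reference_category", "reference_metabolic",
                   "reference_respiratory", "evaluator", "predicted_category",
                   "predicted_metabolic", "predicted_respiratory")]
  problems <- c(problems, cohort_problems(data))
  if (length(problems) > 0) {
    stop(paste0("Invalid cohort:\n", paste0("- ", problems, collapse = "\n")),
         call. = FALSE)
  }
  structure(data, class = c("abg_cohort", class(tibble::tibble())),
            provenance = provenance)
}

# enumerate every schema violation, not just the first
cohort_problems <- function(data) {
  problems <- character()
  bad_ref <- setdiff(unique(data$reference_category), abg_categories())
  if (length(bad_ref) > 0) {
    problems <- c(problems, sprintf("unknown reference_category token(s): %s",
                                    paste(bad_ref, collapse = ", ")))
  }
  bad_pred <- setdiff(unique(data$predicted_category), abg_categories())
  if (length(bad_pred) > 0) {
    problems <- c(problems, sprintf("unknown predicted_category token(s): %s",
                                    paste(bad_pred, collapse = ", ")))
  }
  if (anyNA(data)) problems <- c(problems, "missing values present")
  dup <- data[duplicated(data[, c("case_id", "evaluator")]), ]
  if (nrow(dup) > 0) {
    problems <- c(problems, sprintf("duplicated (case_id, evaluator) pair(s): %s",
                                    paste(unique(dup$case_id), collapse = ", ")))
  }
  tab <- table(data$case_id, data$evaluator)
  if (nrow(tab) > 0 && any(tab == 0)) {
    holes <- which(tab == 0, arr.ind = TRUE)
    problems <- c(problems, sprintf(
      "case(s) missing an evaluator assessment: %s",
      paste(unique(rownames(tab)[holes[, 1]]), collapse = ", ")))
  }
  ref_cols <- c("reference_category", "reference_metabolic", "reference_respiratory")
  n_ref <- dplyr::n_distinct(data[, c("case_id", ref_cols)])
  if (n_ref != dplyr::n_distinct(data$case_id)) {
    problems <- c(problems, "reference columns disagree across rows of a case")
  }
  problems
}

#' @export
print.abg_cohort <- function(x, ...) {
  cat(sprintf("<abg_cohort> %d cases x %d evaluators (provenance: %s)\n",
              dplyr::n_distinct(x$case_id), dplyr::n_distinct(x$evaluator),
              attr(x, "provenance") %||% "unknown"))
  NextMethod()
}

#' Cohort accessors
#'
#' `cohort_cases()` returns the per-case reference table (one row per case);
#' `cohort_evaluators()` the ordered evaluator roster; `cohort_n()` the
#' number of cases.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @return A tibble, character vector, or integer respectively.
#' @export
cohort_cases <- function(cohort) {
  dplyr::distinct(tibble::as_tibble(cohort), .data$case_id,
                  .data$reference_category, .data$reference_metabolic,
                  .data$reference_respiratory)
}

#' @rdname cohort_cases
#' @export
cohort_evaluators <- function(cohort) unique(cohort$evaluator)

#' @rdname cohort_cases
#' @export
cohort_n <- function(cohort) dplyr::n_distinct(cohort$case_id)

evaluator_rows <- function(cohort, evaluator) {
  if (!evaluator %in% cohort$evaluator) {
    stop(sprintf("Unknown evaluator: \"%s\" (cohort has: %s)", evaluator,
                 paste(cohort_evaluators(cohort), collapse = ", ")),
         call. = FALSE)
  }
  rows <- dplyr::filter(tibble::as_tibble(cohort), .data$evaluator == !!evaluator)
  dplyr::arrange(rows, .data$case_id)
}
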