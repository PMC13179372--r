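#' Read and write cohort CSV files
#'
#' The cohort file is long-format CSV with columns `case_id`,
#' `reference_category`, `reference_metabolic`, `reference_respiratory`,
#' `evaluator`, `predicted_category`, `predicted_metabolic`,
#' `predicted_respiratory`; categories as the canonical lower-snake tokens
#' and booleans as 0/1. `read_cohort()` enumerates every schema violation
#' (unknown tokens with their line numbers, duplicated or missing
#' (case, evaluator) pairs) rather than stopping at the first;
#' `write_cohort()` round-trips losslessly.
#'
#' @param path Path to a cohort CSV.
#' @param provenance Provenance label attached to the cohort.
#' @return `read_cohort()`: a validated cohort tibble; `write_cohort()`:
#'   `path`, invisibly.
#' @export
read_cohort <- function(path, provenance = "user") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("case_id", "reference_category", "reference_metabolic",
                "reference_respiratory", "evaluator", "predicted_category",
                "predicted_metabolic", "predicted_respiratory")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("Cohort file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  problems <- character()
  # +1 for the header row so reported lines match the file
  for (col in c("reference_category", "predicted_category")) {
    bad <- which(!raw[[col]] %in% abg_categories())
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "unknown %s token(s): %s", col,
        paste(sprintf("\"%s\" (line %d)", raw[[col]][bad], bad + 1L),
              collapse = ", ")))
    }
  }
  for (col in grep("metabolic|respiratory", required, value = TRUE)) {
    bad <- which(!raw[[col]] %in% c("0", "1", "TRUE", "FALSE"))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("non-boolean %s value(s) at line(s) %s",
                                      col, paste(bad + 1L, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    stop(paste0("Invalid cohort file ", path, ":\n",
                paste0("- ", problems, collapse = "\n")), call. = FALSE)
  }
  for (col in grep("metabolic|respiratory", required, value = TRUE)) {
    raw[[col]] <- raw[[col]] %in% c("1", "TRUE")
  }
  as_cohort(raw, provenance = provenance)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::as_tibble(cohort)
  for (col in grep("metabolic|respiratory", names(out), value = TRUE)) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the tunable settings of [run_pipeline()]: harm weights,
#' bootstrap size and seed, significance level, the optional
#' false-reassurance null rate, the McNemar variant, and the Wilcoxon
#' zero-difference policy.
#'
#' @param weights A [harm_weights()] object.
#' @param b Bootstrap iterations for the harm-difference CI.
#' @param seed Integer RNG seed for every stochastic step.
#' @param alpha Two-sided significance level.
#' @param p0 Optional null rate for the exact false-reassurance test;
#'   `NULL` skips the test.
#' @param mcnemar_variant `"exact"`, `"midp"` or `"chisq"`.
#' @param zero_method Wilcoxon zero handling, `"wilcoxon"` or `"pratt"`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(weights = default_harm_weights(), b = 5000,
                            seed = 1, alpha = 0.05, p0 = NULL,
                            mcnemar_variant = "exact",
                            zero_method = "wilcoxon") {
  stopifnot(inherits(weights, "harm_weights"), b >= 1,
            alpha > 0, alpha < 1)
  structure(list(weights = weights, b = b, seed = seed, alpha = alpha,
                 p0 = p0, mcnemar_variant = mcnemar_variant,
                 zero_method = zero_method),
            class = "pipeline_config")
}

#' Run the full diagnostic-evaluation pipeline on a cohort
#'
#' Computes, per evaluator: overall accuracy, Cohen's kappa,
#' complexity-stratified accuracy, mixed-disorder detection, component
#' detection, and the false-reassurance rate; and, for every ordered pair
#' of evaluators: the paired correctness table with McNemar's test, Cohen's
#' h with post-hoc power, and the harm-weighted comparison (mean harms,
#' Wilcoxon, seeded bootstrap CI). Identical cohort and configuration yield
#' an identical report. With a single evaluator the paired analyses are
#' skipped with a warning.
#'
#' @param cohort A cohort tibble.
#' @param config A [pipeline_config()].
#' @return An object of class `"abg_report"`: a list of tidy tibbles
#'   (`accuracy`, `kappa`, `stratified`, `mixed_detection`,
#'   `component_detection`, `false_reassurance`, `paired`, `power`,
#'   `harm`), the confusion matrices, and the run metadata.
#' @export
#' @examples
#' run_pipeline(build_canonical_fixture(), pipeline_config(b = 200))
run_pipeline <- function(cohort, config = pipeline_config()) {
  evs <- cohort_evaluators(cohort)
  conf_level <- 1 - config$alpha
  per_eval <- function(f, ...) {
    dplyr::bind_rows(purrr::map(evs, function(ev) f(cohort, ev, ...)))
  }
  report <- list(
    accuracy = per_eval(overall_accuracy, conf_level = conf_level),
    kappa = dplyr::bind_rows(purrr::map(
      evs, function(ev) glance(cohens_kappa(cohort, ev, conf_level)))),
    stratified = per_eval(complexity_stratified_accuracy, conf_level = conf_level),
    mixed_detection = per_eval(mixed_detection, conf_level = conf_level),
    component_detection = per_eval(component_detection, conf_level = conf_level),
    false_reassurance = per_eval(false_reassurance, p0 = config$p0,
                                 conf_level = conf_level),
    confusion = purrr::map(stats::setNames(evs, evs),
                           function(ev) confusion_matrix(cohort, ev))
  )
  if (length(evs) >= 2) {
    pairs <- utils::combn(evs, 2, simplify = FALSE)
    paired <- purrr::map(pairs, function(pr) {
      tab <- paired_correctness_table(cohort, pr[1], pr[2])
      mc <- mcnemar_exact(tab, variant = config$mcnemar_variant)
      dplyr::bind_cols(tab, mc[, c("p_value", "method")])
    })
    report$paired <- dplyr::bind_rows(paired)
    report$power <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
      acc <- vapply(unname(pr), function(ev) {
        r <- evaluator_rows(cohort, ev)
        mean(r$predicted_category == r$reference_category)
      }, numeric(1), USE.NAMES = FALSE)
      out <- posthoc_power_two_proportions(cohens_h(acc[1], acc[2]),
                                           cohort_n(cohort), config$alpha)
      dplyr::bind_cols(tibble::tibble(evaluator_a = pr[1],
                                      evaluator_b = pr[2]), out)
    }))
    report$harm <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
      hs <- bootstrap_harm_difference(cohort, pr[1], pr[2],
                                      weights = config$weights, b = config$b,
                                      seed = config$seed,
                                      conf_level = conf_level)
      glance(hs)
    }))
  } else {
    warning("Single evaluator: paired analyses skipped.", call. = FALSE)
  }
  report$meta <- list(
    package_version = as.character(utils::packageVersion("harmdx")),
    n_cases = cohort_n(cohort), evaluators = evs,
    provenance = attr(cohort, "provenance") %||% "unknown",
    seed = config$seed, b = config$b, alpha = config$alpha,
    p0 = config$p0, weights = as.list(unclass(config$weights)),
    mcnemar_variant = config$mcnemar_variant,
    zero_method = config$zero_method
  )
  structure(report, class = "abg_report")
}

#' @export
print.abg_report <- function(x, ...) {
  fmt_p <- function(p) ifelse(is.na(p), "-", sprintf("%.3f", round_half_up(p, 3)))
  cat(sprintf("Diagnostic evaluation report (%d cases, evaluators: %s)\n\n",
              x$meta$n_cases, paste(x$meta$evaluators, collapse = ", ")))
  cat("Overall accuracy:\n")
  acc <- x$accuracy
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-12s %d/%d = %.2f (CI %.2f-%.2f)\n", acc$evaluator[i],
                acc$numerator[i], acc$denominator[i],
                round_half_up(acc$estimate[i], 2),
                round_half_up(acc$ci_low[i], 2),
                round_half_up(acc$ci_high[i], 2)))
  }
  cat("\nCohen's kappa:\n")
  for (i in seq_len(nrow(x$kappa))) {
    cat(sprintf("  %-12s kappa = %.2f (CI %.2f-%.2f)\n",
                x$kappa$evaluator[i], round_half_up(x$kappa$kappa[i], 2),
                round_half_up(x$kappa$ci_low[i], 2),
                round_half_up(x$kappa$ci_high[i], 2)))
  }
  if (!is.null(x$paired)) {
    cat("\nPaired comparisons:\n")
    for (i in seq_len(nrow(x$paired))) {
      p <- x$paired
      cat(sprintf("  %s vs %s: discordant %d/%d, McNemar p = %s\n",
                  p$evaluator_a[i], p$evaluator_b[i], p$a_only[i], p$b_only[i],
                  fmt_p(p$p_value[i])))
    }
    for (i in seq_len(nrow(x$harm))) {
      h <- x$harm
      cat(sprintf("  mean harm %.3f vs %.3f, difference %.2f (CI %.3f-%.3f), Wilcoxon p = %s\n",
                  round_half_up(h$mean_harm_a[i], 3),
                  round_half_up(h$mean_harm_b[i], 3),
                  round_half_up(h$mean_difference[i], 2),
                  round_half_up(h$ci_low[i], 3), round_half_up(h$ci_high[i], 3),
                  fmt_p(h$wilcoxon_p[i])))
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full report at fixed floating-point precision,
#' so identical runs serialize byte-identically) and one CSV per metric
#' table, plus a CSV per confusion matrix in the canonical category order.
#'
#' @param report An `"abg_report"` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("accuracy", "kappa", "stratified", "mixed_detection",
              "component_detection", "false_reassurance", "paired",
              "power", "harm")
  json <- list(meta = report$meta)
  for (nm in tables) {
    if (is.null(report[[nm]])) next
    readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
    json[[nm]] <- report[[nm]]
  }
  for (ev in names(report$confusion)) {
    cm <- report$confusion[[ev]]$counts
    out <- tibble::as_tibble(cbind(predicted = rownames(cm),
                                   as.data.frame(cm)))
    readr::write_csv(out, file.path(dir, paste0("confusion_", ev, ".csv")),
                     progress = FALSE)
    json$confusion[[ev]] <- unname(apply(cm, 1, as.list, simplify = FALSE))
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       null = "null", na = "null")
  invisible(dir)
}
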