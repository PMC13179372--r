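#' Stochastic behavior profile of an evaluator
#'
#' A profile abstracts an evaluator as (i) a row-stochastic confusion
#' kernel — for each reference category, a probability distribution over
#' predicted categories — and (ii) component-detection probabilities: the
#' chance of flagging a truly present metabolic/respiratory component and
#' the chance of falsely flagging an absent one. Component flags are drawn
#' conditionally on the reference components, independent of the predicted
#' category, mirroring independent multi-label coding.
#'
#' @param confusion_rows 6x6 numeric matrix, rows = reference categories,
#'   columns = predicted categories, both named with [abg_categories()]
#'   tokens; each row sums to 1 within 1e-9.
#' @param detect_metabolic,detect_respiratory Detection probability of a
#'   truly present component.
#' @param false_flag_metabolic,false_flag_respiratory Probability of
#'   flagging an absent component.
#' @return An object of class `"evaluator_profile"`.
#' @export
evaluator_profile <- function(confusion_rows, detect_metabolic = 1,
                              detect_respiratory = 1,
                              false_flag_metabolic = 0,
                              false_flag_respiratory = 0) {
  lev <- abg_categories()
  stopifnot(is.matrix(confusion_rows), all(dim(confusion_rows) == 6))
  if (is.null(rownames(confusion_rows))) rownames(confusion_rows) <- lev
  if (is.null(colnames(confusion_rows))) colnames(confusion_rows) <- lev
  confusion_rows <- confusion_rows[lev, lev]
  probs <- c(confusion_rows, detect_metabolic, detect_respiratory,
             false_flag_metabolic, false_flag_respiratory)
  if (any(probs < 0 | probs > 1)) {
    stop("All profile probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (any(abs(rowSums(confusion_rows) - 1) > 1e-9)) {
    stop("Each confusion row must sum to 1 (within 1e-9).", call. = FALSE)
  }
  structure(list(confusion_rows = confusion_rows,
                 detect = c(metabolic = detect_metabolic,
                            respiratory = detect_respiratory),
                 false_flag = c(metabolic = false_flag_metabolic,
                                respiratory = false_flag_respiratory)),
            class = "evaluator_profile")
}

#' Estimate an evaluator profile from an observed cohort
#'
#' Confusion rows are the empirical reference-conditional frequencies of
#' the evaluator's predictions; reference categories with zero support get
#' a uniform row with a warning. Component-detection probabilities are the
#' empirical detection and false-flag rates of the component flags.
#'
#' @param cohort A cohort tibble.
#' @param evaluator Evaluator id.
#' @return An [evaluator_profile()] object.
#' @export
#' @examples
#' profile_from_cohort(build_canonical_fixture(), "chatgpt")
profile_from_cohort <- function(cohort, evaluator) {
  rows <- evaluator_rows(cohort, evaluator)
  lev <- abg_categories()
  counts <- table(factor(rows$reference_category, levels = lev),
                  factor(rows$predicted_category, levels = lev))
  counts <- matrix(as.numeric(counts), 6, 6, dimnames = list(lev, lev))
  support <- rowSums(counts)
  if (any(support == 0)) {
    warning(sprintf("Reference categor%s without support given a uniform confusion row: %s",
                    if (sum(support == 0) > 1) "ies" else "y",
                    paste(lev[support == 0], collapse = ", ")), call. = FALSE)
    counts[support == 0, ] <- 1
  }
  kern <- counts / rowSums(counts)
  rate <- function(pred, ref) if (sum(ref) == 0) 0 else mean(pred[ref])
  evaluator_profile(
    kern,
    detect_metabolic = rate(rows$predicted_metabolic, rows$reference_metabolic),
    detect_respiratory = rate(rows$predicted_respiratory, rows$reference_respiratory),
    false_flag_metabolic = rate(rows$predicted_metabolic, !rows$reference_metabolic),
    false_flag_respiratory = rate(rows$predicted_respiratory, !rows$reference_respiratory)
  )
}

#' Generate a synthetic paired-evaluator cohort
#'
#' Samples reference categories from a six-category distribution, then each
#' evaluator's predicted category from its confusion row conditioned on the
#' reference, and its component flags from the profile's detection and
#' false-flag probabilities conditioned on the reference components.
#' Evaluators are conditionally independent given the reference. Identical
#' seed and configuration yield identical cohorts.
#'
#' @param n Number of cases (>= 1).
#' @param reference_distribution Named probabilities over
#'   [abg_categories()], summing to 1 within 1e-9.
#' @param profiles Named list of [evaluator_profile()] objects; names are
#'   the evaluator ids.
#' @param seed Integer RNG seed.
#' @return A cohort tibble with provenance `"synthetic"`.
#' @export
#' @examples
#' prof <- profile_from_cohort(build_canonical_fixture(), "chatgpt")
#' generate_cohort(20, fixture_reference_distribution(),
#'                 list(ai = prof), seed = 7)
generate_cohort <- function(n, reference_distribution, profiles, seed) {
  lev <- abg_categories()
  stopifnot(n >= 1, length(seed) == 1)
  if (is.null(names(reference_distribution)) ||
      !setequal(names(reference_distribution), lev)) {
    stop("`reference_distribution` must be named with the six category tokens.",
         call. = FALSE)
  }
  reference_distribution <- reference_distribution[lev]
  if (any(reference_distribution < 0) ||
      abs(sum(reference_distribution) - 1) > 1e-9) {
    stop("`reference_distribution` must be non-negative and sum to 1 (within 1e-9).",
         call. = FALSE)
  }
  if (is.null(names(profiles)) || !all(nzchar(names(profiles)))) {
    stop("`profiles` must be a named list of evaluator profiles.", call. = FALSE)
  }
  purrr::walk(profiles, function(p) stopifnot(inherits(p, "evaluator_profile")))
  withr::local_seed(seed)
  ref <- sample(lev, n, replace = TRUE, prob = reference_distribution)
  ref_comp <- derive_components(ref)
  per_eval <- purrr::imap(profiles, function(profile, ev) {
    pred <- vapply(ref, function(rc) {
      sample(lev, 1, prob = profile$confusion_rows[rc, ])
    }, character(1), USE.NAMES = FALSE)
    p_met <- ifelse(ref_comp$metabolic, profile$detect[["metabolic"]],
                    profile$false_flag[["metabolic"]])
    p_resp <- ifelse(ref_comp$respiratory, profile$detect[["respiratory"]],
                     profile$false_flag[["respiratory"]])
    tibble::tibble(
      case_id = sprintf("case_%0*d", nchar(n), seq_len(n)),
      reference_category = ref,
      reference_metabolic = ref_comp$metabolic,
      reference_respiratory = ref_comp$respiratory,
      evaluator = ev,
      predicted_category = pred,
      predicted_metabolic = stats::runif(n) < p_met,
      predicted_respiratory = stats::runif(n) < p_resp
    )
  })
  as_cohort(dplyr::bind_rows(per_eval), provenance = "synthetic")
}

#' Reference category distribution of the canonical fixture
#'
#' The six-category truth distribution of the 50-case cohort
#' (24/8/6/5/4/3 over 50), as probabilities — the default truth model for
#' synthetic cohorts emulating the study conditions.
#'
#' @return Named numeric probabilities over [abg_categories()].
#' @export
fixture_reference_distribution <- function() {
  counts <- study_constraints()$reference_counts
  counts / sum(counts)
}

#' Read a generator configuration from JSON
#'
#' The configuration mirrors [generate_cohort()]'s arguments: `n`, `seed`,
#' `reference_distribution` (named object), and `profiles`, each with a
#' `confusion_rows` matrix (row-major list of rows, reference order
#' [abg_categories()]) and the four component probabilities.
#'
#' @param path Path to a JSON configuration.
#' @return A list suitable for `do.call(generate_cohort, ...)`.
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lev <- abg_categories()
  profiles <- purrr::map(raw$profiles, function(p) {
    m <- matrix(unlist(p$confusion_rows), nrow = 6, byrow = TRUE,
                dimnames = list(lev, lev))
    evaluator_profile(m,
                      detect_metabolic = p$detect_metabolic %||% 1,
                      detect_respiratory = p$detect_respiratory %||% 1,
                      false_flag_metabolic = p$false_flag_metabolic %||% 0,
                      false_flag_respiratory = p$false_flag_respiratory %||% 0)
  })
  list(n = raw$n, reference_distribution = unlist(raw$reference_distribution),
       profiles = profiles, seed = raw$seed)
}

#' @rdname read_generator_config
#' @param config List as returned by `read_generator_config()`.
#' @export
write_generator_config <- function(config, path) {
  lev <- abg_categories()
  out <- list(
    n = config$n, seed = config$seed,
    reference_distribution = as.list(config$reference_distribution[lev]),
    profiles = purrr::map(config$profiles, function(p) {
      list(confusion_rows = apply(p$confusion_rows, 1, as.list,
                                  simplify = FALSE),
           detect_metabolic = p$detect[["metabolic"]],
           detect_respiratory = p$detect[["respiratory"]],
           false_flag_metabolic = p$false_flag[["metabolic"]],
           false_flag_respiratory = p$false_flag[["respiratory"]])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
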