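#' Canonical acid-base diagnostic categories
#'
#' The six harmonized diagnostic categories used throughout the package, in
#' the canonical display order used for confusion matrices and report tables:
#' mixed disorder first, then the four single (primary) disorders interleaved
#' with normal status in decreasing fixture prevalence.
#'
#' @return Character vector of the six category tokens.
#' @export
#' @examples
#' abg_categories()
abg_categories <- function() {
  c("mixed", "metabolic_alkalosis", "respiratory_alkalosis",
    "normal", "respiratory_acidosis", "metabolic_acidosis")
}

#' Error-tier taxonomy for category misclassification
#'
#' @return Character vector of the four error types, most severe
#'   misclassification first.
#' @export
abg_error_types <- function() {
  c("correct", "false_reassurance", "mixed_as_single", "other_misclassification")
}

single_disorders <- function() {
  c("metabolic_acidosis", "metabolic_alkalosis",
    "respiratory_acidosis", "respiratory_alkalosis")
}

assert_categories <- function(x, arg = deparse(substitute(x))) {
  bad <- setdiff(unique(as.character(x)), abg_categories())
  if (length(bad) > 0) {
    stop(sprintf("`%s` contains unknown category token(s): %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Decompose a diagnostic category into physiological components
#'
#' Every category implies presence or absence of a metabolic and a
#' respiratory disturbance: normal implies neither, each single (primary)
#' disorder implies exactly its own axis, and a mixed disorder implies both.
#' This is the default multi-label coding used when an evaluator's component
#' flags are not recorded independently of its category call.
#'
#' @param category Character vector of category tokens (see
#'   [abg_categories()]).
#' @return A tibble with one row per input and logical columns `metabolic`
#'   and `respiratory`.
#' @export
#' @examples
#' derive_components(c("normal", "metabolic_alkalosis", "mixed"))
derive_components <- function(category) {
  category <- as.character(category)
  assert_categories(category, "category")
  tibble::tibble(
    metabolic = category %in% c("metabolic_acidosis", "metabolic_alkalosis", "mixed"),
    respiratory = category %in% c("respiratory_acidosis", "respiratory_alkalosis", "mixed")
  )
}

#' Classify a predicted category against the reference into an error tier
#'
#' The taxonomy has three misclassification tiers ordered by clinical
#' severity: *false reassurance* (a reference-mixed case called normal),
#' *mixed-as-single* (a reference-mixed case called a single primary
#' disorder), and *other misclassification* (every remaining disagreement,
#' including overclassification of a single or normal case as mixed).
#'
#' @param reference Character vector of reference category tokens.
#' @param predicted Character vector of predicted category tokens, recycled
#'   against `reference` if length one.
#' @return Factor vector with levels [abg_error_types()].
#' @export
#' @examples
#' classify_error("mixed", c("mixed", "normal", "respiratory_acidosis"))
classify_error <- function(reference, predicted) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  assert_categories(reference, "reference")
  assert_categories(predicted, "predicted")
  n <- max(length(reference), length(predicted))
  reference <- rep_len(reference, n)
  predicted <- rep_len(predicted, n)
  out <- dplyr::case_when(
    predicted == reference ~ "correct",
    reference == "mixed" & predicted == "normal" ~ "false_reassurance",
    reference == "mixed" & predicted %in% single_disorders() ~ "mixed_as_single",
    .default = "other_misclassification"
  )
  factor(out, levels = abg_error_types())
}

#' Default free-text harmonization rule table
#'
#' An ordered, first-match-wins keyword rule table mapping free-text
#' diagnostic narratives onto the six canonical categories. Matching is
#' case-insensitive on whole disorder phrases, so compensation language
#' ("... with appropriate respiratory compensation") never triggers a second
#' disorder: only full phrases such as "respiratory acidosis" count as a
#' disorder mention. Narratives naming two primary disorders, or using
#' "mixed"/"combined", map to the mixed category.
#'
#' @return A tibble with columns `phrases` (list of character phrase sets),
#'   `match` (`"any"` or `"all"` within a rule), and `target` (category).
#' @seealso [harmonize_interpretation()], [read_harmonization_rules()]
#' @export
default_harmonization_rules <- function() {
  rule <- function(phrases, match, target) {
    tibble::tibble(phrases = list(phrases), match = match, target = target)
  }
  met <- c("metabolic acidosis", "metabolic alkalosis")
  resp <- c("respiratory acidosis", "respiratory alkalosis")
  dual <- purrr::map2(rep(met, each = 2), rep(resp, times = 2), c)
  dplyr::bind_rows(
    rule(c("mixed", "combined"), "any", "mixed"),
    purrr::map(dual, rule, match = "all", target = "mixed"),
    rule("metabolic acidosis", "any", "metabolic_acidosis"),
    rule("metabolic alkalosis", "any", "metabolic_alkalosis"),
    rule("respiratory acidosis", "any", "respiratory_acidosis"),
    rule("respiratory alkalosis", "any", "respiratory_alkalosis"),
    rule(c("normal", "no acid-base disturbance"), "any", "normal")
  )
}

#' Map a free-text diagnostic narrative onto a canonical category
#'
#' Applies an ordered rule table (first match wins) to lower-cased text.
#' A rule matches when any (`match = "any"`) or all (`match = "all"`) of its
#' phrases occur as substrings. Deterministic for a fixed rule table.
#'
#' @param text Character vector of non-empty free-text interpretations.
#' @param rules Rule table as returned by [default_harmonization_rules()].
#' @param default Optional category returned when no rule matches; when
#'   `NULL` (default) an unmappable narrative is an error naming the text.
#' @return Character vector of category tokens.
#' @export
#' @examples
#' harmonize_interpretation("Combined metabolic acidosis and respiratory acidosis")
#' harmonize_interpretation("Metabolic acidosis with appropriate respiratory compensation")
harmonize_interpretation <- function(text, rules = default_harmonization_rules(),
                                     default = NULL) {
  stopifnot(is.character(text))
  if (any(!nzchar(trimws(text)))) {
    stop("`text` must be non-empty.", call. = FALSE)
  }
  if (!is.null(default)) assert_categories(default, "default")
  assert_categories(rules$target, "rules$target")
  # normalize unicode dashes so "acid–base" matches "acid-base" phrases
  txt <- gsub("[\u2010\u2011\u2012\u2013\u2014]", "-", tolower(text))
  vapply(txt, function(one) {
    for (i in seq_len(nrow(rules))) {
      hit <- vapply(rules$phrases[[i]], grepl, logical(1), x = one, fixed = TRUE)
      ok <- if (identical(rules$match[[i]], "all")) all(hit) else any(hit)
      if (ok) return(rules$target[[i]])
    }
    if (!is.null(default)) return(default)
    stop(sprintf("No harmonization rule matches narrative: \"%s\"", one),
         call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Read or write a harmonization rule table as JSON
#'
#' The rule table is plain data, versioned with the package at
#' `system.file("extdata", "harmonization_rules.json", package = "harmdx")`,
#' so the free-text mapping is auditable and editable without code changes.
#'
#' @param path Path to a JSON rule file.
#' @param rules Rule table to serialize.
#' @return `read_harmonization_rules()` returns a rule tibble;
#'   `write_harmonization_rules()` returns `path` invisibly.
#' @export
read_harmonization_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- dplyr::bind_rows(purrr::map(raw, function(r) {
    tibble::tibble(phrases = list(unlist(r$phrases)),
                   match = r$match, target = r$target)
  }))
  assert_categories(rules$target, "target")
  stopifnot(all(rules$match %in% c("any", "all")))
  rules
}

#' @rdname read_harmonization_rules
#' @export
write_harmonization_rules <- function(rules, path) {
  out <- purrr::pmap(rules, function(phrases, match, target) {
    list(phrases = as.list(phrases), match = match, target = target)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
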