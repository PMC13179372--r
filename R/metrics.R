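#' Exact (Clopper-Pearson) binomial confidence bounds
#'
#' Closed-form beta-quantile inversion of the binomial tails. The lower
#' bound is 0 when `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with columns `ci_low`, `ci_high`.
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  stopifnot(all(k >= 0), all(k <= n), conf_level > 0, conf_level < 1)
  a <- (1 - conf_level) / 2
  tibble::tibble(
    ci_low = ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1)),
    ci_high = ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
  )
}

# one DetectionMetrics row: numerator/denominator with exact CI
detection_row <- function(metric, k, n, conf_level = 0.95) {
  if (n == 0) {
    warning(sprintf("Empty denominator for %s; metric undefined.", metric),
            call. = FALSE)
    return(tibble::tibble(metric = metric, numerator = 0L, denominator = 0L,
                          estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_))
  }
  ci <- clopper_pearson(k, n, conf_level)
  tibble::tibble(metric = metric, numerator = as.integer(k),
                 denominator = as.integer(n), estimate = k / n,
                 ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' Confusion matrix of an evaluator against the reference
#'
#' Rows are the evaluator's predicted categories, columns the reference
#' categories, both in the canonical order of [abg_categories()]. Row-wise
#' proportions (each predicted category's distribution over reference
#' categories) accompany the counts.
#'
#' @param cohort A cohort tibble.
#' @param evaluator Evaluator id.
#' @return An object of class `"abg_confusion"`: list with integer `counts`,
#'   `proportions` (row-wise, `NaN` for empty rows), `evaluator`, `n`.
#'   Use [tidy()] for a long tibble and [ggplot2::autoplot()] for a heatmap.
#' @export
#' @examples
#' confusion_matrix(build_canonical_fixture(), "physician")
confusion_matrix <- function(cohort, evaluator) {
  rows <- evaluator_rows(cohort, evaluator)
  lev <- abg_categories()
  counts <- table(factor(rows$predicted_category, levels = lev),
                  factor(rows$reference_category, levels = lev))
  counts <- matrix(as.integer(counts), 6, 6, dimnames = dimnames(counts))
  names(dimnames(counts)) <- c("predicted", "reference")
  structure(list(counts = counts,
                 proportions = counts / rowSums(counts)[row(counts)],
                 evaluator = evaluator, n = nrow(rows)),
            class = "abg_confusion")
}

#' @export
print.abg_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix for %s (n = %d; rows = predicted, columns = reference)\n",
              x$evaluator, x$n))
  print(x$counts)
  invisible(x)
}

#' @method tidy abg_confusion
#' @export
tidy.abg_confusion <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(as.table(x$counts),
                                         responseName = "count"))
  out$proportion <- as.vector(x$proportions)
  out$evaluator <- x$evaluator
  out[, c("evaluator", "predicted", "reference", "count", "proportion")]
}

# kappa estimate + Fleiss-Cohen-Everitt asymptotic variance from a
# predicted (rows) x reference (cols) count matrix
kappa_stats <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  po <- sum(diag(p))
  pr <- rowSums(p)
  pc <- colSums(p)
  pe <- sum(pr * pc)
  if (pe >= 1) {
    stop("Cohen's kappa is undefined: expected agreement is 1 (degenerate single-category marginals).",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  a_term <- sum(diag(p) * ((1 - pe) - (pr + pc) * (1 - po))^2)
  off <- (pc[col(p)] + pr[row(p)])^2 * p
  diag(off) <- 0
  b_term <- (1 - po)^2 * sum(off)
  c_term <- (po * pe - 2 * pe + po)^2
  se <- sqrt((a_term + b_term - c_term) / (n * (1 - pe)^4))
  list(kappa = kappa, p_o = po, p_e = pe, se = se, n = n)
}

#' Cohen's kappa of an evaluator against the reference
#'
#' Unweighted kappa over the six categories, with an asymptotic
#' (Fleiss-Cohen-Everitt) standard error and normal-quantile confidence
#' interval, the standard large-sample interval for a single kappa.
#'
#' @inheritParams confusion_matrix
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"abg_kappa"` with fields `kappa`, `se`,
#'   `ci_low`, `ci_high`, `p_o`, `p_e`, `n`, `evaluator`, `conf_level`.
#'   [tidy()] and [glance()] return one-row tibbles.
#' @export
#' @examples
#' cohens_kappa(build_canonical_fixture(), "physician")
cohens_kappa <- function(cohort, evaluator, conf_level = 0.95) {
  rows <- evaluator_rows(cohort, evaluator)
  if (nrow(rows) < 2) stop("Cohen's kappa needs at least 2 cases.", call. = FALSE)
  # case-wise route: observed and expected agreement straight from the vectors
  n <- nrow(rows)
  po <- mean(rows$predicted_category == rows$reference_category)
  lev <- abg_categories()
  pr <- vapply(lev, function(l) mean(rows$predicted_category == l), numeric(1))
  pc <- vapply(lev, function(l) mean(rows$reference_category == l), numeric(1))
  pe <- sum(pr * pc)
  if (pe >= 1) {
    stop("Cohen's kappa is undefined: expected agreement is 1 (degenerate single-category marginals).",
         call. = FALSE)
  }
  se <- kappa_stats(confusion_matrix(cohort, evaluator)$counts)$se
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  kappa <- (po - pe) / (1 - pe)
  structure(list(kappa = kappa, se = se,
                 ci_low = kappa - z * se, ci_high = min(1, kappa + z * se),
                 p_o = po, p_e = pe, n = n, evaluator = evaluator,
                 conf_level = conf_level),
            class = "abg_kappa")
}

#' @export
print.abg_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa for %s: %.3f (%.0f%% CI %.3f to %.3f), p_o = %.3f, p_e = %.3f, n = %d\n",
              x$evaluator, x$kappa, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$p_o, x$p_e, x$n))
  invisible(x)
}

#' @method tidy abg_kappa
#' @export
tidy.abg_kappa <- function(x, ...) {
  tibble::tibble(evaluator = x$evaluator, kappa = x$kappa, std_error = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @method glance abg_kappa
#' @export
glance.abg_kappa <- function(x, ...) {
  tibble::tibble(evaluator = x$evaluator, kappa = x$kappa, std_error = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 observed_agreement = x$p_o, expected_agreement = x$p_e,
                 n = x$n, conf_level = x$conf_level)
}

#' Overall diagnostic accuracy of an evaluator
#'
#' Proportion of cases whose predicted category matches the reference, with
#' an exact Clopper-Pearson interval by default or a seeded percentile
#' bootstrap interval on request.
#'
#' @inheritParams cohens_kappa
#' @param ci `"exact"` (Clopper-Pearson, default) or `"bootstrap"`
#'   (percentile over case resamples).
#' @param b Bootstrap iterations when `ci = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return One-row tibble of detection metrics (`metric`, `numerator`,
#'   `denominator`, `estimate`, `ci_low`, `ci_high`).
#' @export
#' @examples
#' overall_accuracy(build_canonical_fixture(), "chatgpt")
overall_accuracy <- function(cohort, evaluator, conf_level = 0.95,
                             ci = c("exact", "bootstrap"), b = 5000,
                             seed = NULL) {
  ci <- match.arg(ci)
  rows <- evaluator_rows(cohort, evaluator)
  correct <- rows$predicted_category == rows$reference_category
  out <- detection_row("overall_accuracy", sum(correct), nrow(rows), conf_level)
  if (ci == "bootstrap") {
    boot <- function() {
      stats <- vapply(seq_len(b), function(i) {
        mean(correct[sample.int(length(correct), replace = TRUE)])
      }, numeric(1))
      stats::quantile(stats, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                      names = FALSE)
    }
    q <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
    out$ci_low <- q[1]
    out$ci_high <- q[2]
  }
  out$evaluator <- evaluator
  out[, c("evaluator", setdiff(names(out), "evaluator"))]
}

#' Accuracy stratified by case complexity
#'
#' Splits the cohort by the reference diagnosis into the mixed-disorder
#' stratum (physiologically complex cases) and the non-mixed stratum
#' (single primary disorders plus normal status) and reports accuracy in
#' each; the two numerators sum to the overall correct count.
#'
#' @inheritParams cohens_kappa
#' @param conf_level Confidence level for the exact intervals.
#' @return Two-row tibble of detection metrics with a `stratum` column
#'   (`"mixed"`, `"non_mixed"`).
#' @export
#' @examples
#' complexity_stratified_accuracy(build_canonical_fixture(), "chatgpt")
complexity_stratified_accuracy <- function(cohort, evaluator, conf_level = 0.95) {
  rows <- evaluator_rows(cohort, evaluator)
  out <- purrr::map2(c("mixed", "non_mixed"),
                     list(rows$reference_category == "mixed",
                          rows$reference_category != "mixed"),
                     function(stratum, sel) {
    k <- sum(rows$predicted_category[sel] == rows$reference_category[sel])
    r <- detection_row(paste0("accuracy_", stratum), k, sum(sel), conf_level)
    r$stratum <- stratum
    r
  })
  out <- dplyr::bind_rows(out)
  out$evaluator <- evaluator
  out[, c("evaluator", "stratum", "metric", "numerator", "denominator",
          "estimate", "ci_low", "ci_high")]
}

#' Mixed-disorder detection sensitivity and specificity
#'
#' Treats "predicted mixed" as a binary screen for the complex stratum:
#' sensitivity is the proportion of reference-mixed cases called mixed;
#' specificity the proportion of non-mixed cases not called mixed.
#'
#' @inheritParams complexity_stratified_accuracy
#' @return Two-row tibble of detection metrics (`mixed_sensitivity`,
#'   `mixed_specificity`).
#' @export
#' @examples
#' mixed_detection(build_canonical_fixture(), "physician")
mixed_detection <- function(cohort, evaluator, conf_level = 0.95) {
  rows <- evaluator_rows(cohort, evaluator)
  is_mixed <- rows$reference_category == "mixed"
  pred_mixed <- rows$predicted_category == "mixed"
  out <- dplyr::bind_rows(
    detection_row("mixed_sensitivity", sum(pred_mixed & is_mixed),
                  sum(is_mixed), conf_level),
    detection_row("mixed_specificity", sum(!pred_mixed & !is_mixed),
                  sum(!is_mixed), conf_level)
  )
  out$evaluator <- evaluator
  out[, c("evaluator", setdiff(names(out), "evaluator"))]
}

#' Component-level (multi-label) detection metrics
#'
#' Sensitivity and specificity for recognizing the metabolic and
#' respiratory contributions independently of the exclusive six-category
#' call, using the evaluator's component flags against the reference
#' component flags.
#'
#' @inheritParams complexity_stratified_accuracy
#' @return Four-row tibble of detection metrics with a `component` column.
#' @export
#' @examples
#' component_detection(build_canonical_fixture(), "chatgpt")
component_detection <- function(cohort, evaluator, conf_level = 0.95) {
  rows <- evaluator_rows(cohort, evaluator)
  one <- function(component) {
    ref <- rows[[paste0("reference_", component)]]
    pred <- rows[[paste0("predicted_", component)]]
    out <- dplyr::bind_rows(
      detection_row(paste0(component, "_sensitivity"), sum(pred & ref),
                    sum(ref), conf_level),
      detection_row(paste0(component, "_specificity"), sum(!pred & !ref),
                    sum(!ref), conf_level)
    )
    out$component <- component
    out
  }
  out <- dplyr::bind_rows(one("metabolic"), one("respiratory"))
  out$evaluator <- evaluator
  out[, c("evaluator", "component", "metric", "numerator", "denominator",
          "estimate", "ci_low", "ci_high")]
}

#' False-reassurance rate among mixed cases
#'
#' The highest-severity error: a reference-mixed case classified as normal
#' acid-base status. Reports the rate with its exact interval and, when a
#' null rate `p0` is supplied, an exact one-sample binomial test against
#' it (via [stats::binom.test()]).
#'
#' @inheritParams complexity_stratified_accuracy
#' @param p0 Optional null rate in `[0, 1)` for the exact binomial test;
#'   when `NULL` no test is performed (the choice of null is substantive
#'   and deliberately not defaulted).
#' @param alternative Test alternative, default `"greater"`.
#' @return One-row tibble: detection-metric columns plus `p0` and
#'   `p_value` (`NA` when `p0` is `NULL`).
#' @export
#' @examples
#' false_reassurance(build_canonical_fixture(), "chatgpt", p0 = 0.05)
false_reassurance <- function(cohort, evaluator, p0 = NULL,
                              alternative = c("greater", "two.sided", "less"),
                              conf_level = 0.95) {
  alternative <- match.arg(alternative)
  rows <- evaluator_rows(cohort, evaluator)
  mixed <- rows$reference_category == "mixed"
  if (!any(mixed)) {
    stop("No reference-mixed cases: false-reassurance rate is undefined.",
         call. = FALSE)
  }
  k <- sum(mixed & rows$predicted_category == "normal")
  out <- detection_row("false_reassurance_rate", k, sum(mixed), conf_level)
  out$p0 <- NA_real_
  out$p_value <- NA_real_
  if (!is.null(p0)) {
    if (p0 < 0 || p0 >= 1) stop("`p0` must lie in [0, 1).", call. = FALSE)
    out$p0 <- p0
    out$p_value <- stats::binom.test(k, sum(mixed), p = p0,
                                     alternative = alternative)$p.value
  }
  out$evaluator <- evaluator
  out[, c("evaluator", setdiff(names(out), "evaluator"))]
}
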