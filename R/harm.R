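#' Three-tier harm weights for misclassification severity
#'
#' Weights attach clinical severity to the error taxonomy of
#' [classify_error()]: false reassurance (a mixed disorder called normal)
#' carries the highest weight, misclassifying mixed as a single primary
#' disorder an intermediate weight, and every other disagreement the lowest
#' weight; correct classifications score 0. The strict hierarchy
#' `false_reassurance > mixed_as_single > other >= 0` is enforced at
#' construction.
#'
#' `default_harm_weights()` returns the calibrated triple obtained by
#' anchoring false reassurance at 1 and solving the two-equation linear
#' system that reproduces both published mean harm scores (0.064 and 0.184)
#' from the canonical fixture's tier counts — see [calibrate_weights()].
#'
#' @param false_reassurance,mixed_as_single,other Non-negative tier weights.
#' @return A named numeric vector of class `"harm_weights"` with entries
#'   for the three error tiers and a zero entry for `correct`.
#' @export
#' @examples
#' default_harm_weights()
harm_weights <- function(false_reassurance, mixed_as_single, other) {
  w <- c(correct = 0, false_reassurance = false_reassurance,
         mixed_as_single = mixed_as_single, other_misclassification = other)
  if (any(w < 0) || !(false_reassurance > mixed_as_single &&
                      mixed_as_single > other)) {
    stop("Harm weights must satisfy false_reassurance > mixed_as_single > other >= 0.",
         call. = FALSE)
  }
  structure(w, class = "harm_weights")
}

#' @rdname harm_weights
#' @export
default_harm_weights <- function() {
  w_other <- 2.16 / 7        # from 1*w_ms + 8*w_o = 3.2 and w_ms + w_o = 1.04
  harm_weights(1, 1.04 - w_other, w_other)
}

#' @export
print.harm_weights <- function(x, ...) {
  cat("Harm weights (per error tier):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-case harm score
#'
#' Looks up the tier weight of each (reference, predicted) pair; correct
#' classifications score 0.
#'
#' @inheritParams classify_error
#' @param weights A [harm_weights()] object.
#' @return Numeric vector of non-negative scores.
#' @export
#' @examples
#' harm_score("mixed", c("mixed", "normal"), default_harm_weights())
harm_score <- function(reference, predicted, weights = default_harm_weights()) {
  stopifnot(inherits(weights, "harm_weights"))
  unname(unclass(weights)[as.character(classify_error(reference, predicted))])
}

#' Per-case and mean harm of cohort evaluators
#'
#' `case_harm()` returns the case-by-evaluator harm scores in wide form;
#' `mean_harm()` the arithmetic mean over all cases for one evaluator
#' (correct cases contribute 0).
#'
#' @param cohort A cohort tibble.
#' @param weights A [harm_weights()] object.
#' @return `case_harm()`: a tibble with `case_id` and one score column per
#'   evaluator; `mean_harm()`: a single number.
#' @export
#' @examples
#' mean_harm(build_canonical_fixture(), "chatgpt")
case_harm <- function(cohort, weights = default_harm_weights()) {
  scored <- dplyr::mutate(tibble::as_tibble(cohort),
                          harm = harm_score(.data$reference_category,
                                            .data$predicted_category, weights))
  tidyr::pivot_wider(scored[, c("case_id", "evaluator", "harm")],
                     names_from = "evaluator", values_from = "harm")
}

#' @rdname case_harm
#' @param evaluator Evaluator id.
#' @export
mean_harm <- function(cohort, evaluator, weights = default_harm_weights()) {
  rows <- evaluator_rows(cohort, evaluator)
  mean(harm_score(rows$reference_category, rows$predicted_category, weights))
}

#' Calibrate tier weights from error counts and target mean harms
#'
#' With the top tier anchored, reproducing two evaluators' mean harm scores
#' from their tier counts is a 2x2 linear system in the two remaining
#' weights. Used to recover the package's default weights from the
#' published means; errors if the system is singular or the solution
#' violates the severity hierarchy.
#'
#' @param counts_a,counts_b Named counts (`false_reassurance`,
#'   `mixed_as_single`, `other`) of each evaluator's error tiers.
#' @param target_mean_a,target_mean_b Mean harm scores to reproduce.
#' @param anchor Value fixed for the false-reassurance weight, default 1.
#' @param n Number of cases the means average over.
#' @return A [harm_weights()] object reproducing both targets exactly.
#' @export
#' @examples
#' calibrate_weights(c(false_reassurance = 0, mixed_as_single = 1, other = 8),
#'                   c(false_reassurance = 4, mixed_as_single = 5, other = 5),
#'                   0.064, 0.184, anchor = 1, n = 50)
calibrate_weights <- function(counts_a, counts_b, target_mean_a, target_mean_b,
                              anchor = 1, n) {
  m <- rbind(c(counts_a[["mixed_as_single"]], counts_a[["other"]]),
             c(counts_b[["mixed_as_single"]], counts_b[["other"]]))
  rhs <- c(n * target_mean_a - counts_a[["false_reassurance"]] * anchor,
           n * target_mean_b - counts_b[["false_reassurance"]] * anchor)
  if (abs(det(m)) < 1e-12) {
    stop("Weight calibration system is singular for these tier counts.",
         call. = FALSE)
  }
  sol <- solve(m, rhs)
  harm_weights(anchor, sol[1], sol[2])
}

# exact null distribution of the (doubled, so integer-valued even under
# average ranks) signed-rank statistic: probability vector over 0..sum(u)
signed_rank_null <- function(u) {
  dist <- c(1, numeric(sum(u)))
  for (r in u) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- (dist + shifted) / 2
  }
  dist
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test. Zero differences are discarded
#' before ranking (classic Wilcoxon handling) or ranked jointly and then
#' discarded (`zero_method = "pratt"`). With at most `exact_limit` nonzero
#' differences the null distribution is computed exactly (a convolution
#' over doubled average ranks, valid under ties); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. A vector with no nonzero difference is an explicit error, not a
#' silent p = 1.
#'
#' @param differences Numeric vector of paired differences.
#' @param zero_method `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit Largest nonzero-difference count for the exact path.
#' @return One-row tibble: `statistic` (rank sum of positive differences),
#'   `n_nonzero`, `p_value`, `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 1, 1, 1, 1))
wilcoxon_signed_rank <- function(differences,
                                 zero_method = c("wilcoxon", "pratt"),
                                 exact_limit = 25) {
  zero_method <- match.arg(zero_method)
  d <- differences[!is.na(differences)]
  if (all(d == 0)) {
    stop("All paired differences are zero: the signed-rank test is degenerate.",
         call. = FALSE)
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  m <- length(d)
  w_plus <- sum(r[d > 0])
  if (m <= exact_limit) {
    u <- as.integer(round(2 * r))
    dist <- signed_rank_null(u)
    support <- 0:sum(u)
    w2 <- 2 * w_plus
    mu <- sum(u) / 2
    delta <- abs(w2 - mu)
    p <- sum(dist[support <= mu - delta | support >= mu + delta])
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  tibble::tibble(statistic = w_plus, n_nonzero = m, p_value = min(1, p),
                 method = method)
}

#' Paired harm comparison between two evaluators
#'
#' Scores every case for both evaluators with the same weights and tests
#' the per-case harm differences (B minus A) with the Wilcoxon signed-rank
#' test.
#'
#' @inheritParams case_harm
#' @param evaluator_a,evaluator_b Evaluator ids; differences are
#'   `evaluator_b` minus `evaluator_a`.
#' @inheritParams wilcoxon_signed_rank
#' @return One-row tibble as [wilcoxon_signed_rank()], plus the evaluator
#'   ids.
#' @export
#' @examples
#' paired_harm_test(build_canonical_fixture(), "physician", "chatgpt")
paired_harm_test <- function(cohort, evaluator_a, evaluator_b,
                             weights = default_harm_weights(),
                             zero_method = c("wilcoxon", "pratt"),
                             exact_limit = 25) {
  scores <- case_harm(cohort, weights)
  for (ev in c(evaluator_a, evaluator_b)) {
    if (!ev %in% names(scores)) {
      stop(sprintf("Unknown evaluator: \"%s\"", ev), call. = FALSE)
    }
  }
  out <- wilcoxon_signed_rank(scores[[evaluator_b]] - scores[[evaluator_a]],
                              zero_method = zero_method,
                              exact_limit = exact_limit)
  out$evaluator_a <- evaluator_a
  out$evaluator_b <- evaluator_b
  out[, c("evaluator_a", "evaluator_b", "statistic", "n_nonzero",
          "p_value", "method")]
}

#' Bootstrap the mean paired harm difference
#'
#' Resamples cases with replacement — paired, so both evaluators' scores
#' travel together — and takes percentile bounds of the mean difference.
#' Deterministic under a fixed seed.
#'
#' @inheritParams paired_harm_test
#' @param b Bootstrap iterations, default 5000.
#' @param seed Integer RNG seed.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"abg_harm_summary"`: list with the per-case
#'   score tibble, `mean_a`, `mean_b`, `delta` (B minus A), `ci_low`,
#'   `ci_high`, `wilcoxon_p`, `b`, `seed`, evaluator ids. [tidy()] gives
#'   per-case scores, [glance()] the one-row summary.
#' @export
#' @examples
#' bootstrap_harm_difference(build_canonical_fixture(), "physician", "chatgpt",
#'                           b = 200, seed = 1)
bootstrap_harm_difference <- function(cohort, evaluator_a, evaluator_b,
                                      weights = default_harm_weights(),
                                      b = 5000, seed = 1, conf_level = 0.95) {
  stopifnot(b >= 1)
  scores <- case_harm(cohort, weights)
  diffs <- scores[[evaluator_b]] - scores[[evaluator_a]]
  n <- length(diffs)
  if (n == 1) {
    warning("Single-case cohort: bootstrap interval is degenerate.",
            call. = FALSE)
  }
  means <- withr::with_seed(seed, {
    vapply(seq_len(b), function(i) {
      mean(diffs[sample.int(n, replace = TRUE)])
    }, numeric(1))
  })
  q <- stats::quantile(means, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                       names = FALSE)
  wp <- tryCatch(paired_harm_test(cohort, evaluator_a, evaluator_b,
                                  weights)$p_value,
                 error = function(e) NA_real_)
  structure(list(per_case = scores, evaluator_a = evaluator_a,
                 evaluator_b = evaluator_b,
                 mean_a = mean(scores[[evaluator_a]]),
                 mean_b = mean(scores[[evaluator_b]]),
                 delta = mean(diffs), ci_low = q[1], ci_high = q[2],
                 wilcoxon_p = wp, b = b, seed = seed,
                 conf_level = conf_level),
            class = "abg_harm_summary")
}

#' @export
print.abg_harm_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Harm-weighted comparison (%s vs %s, n = %d cases)\n",
           "  mean harm: %s = %.3f, %s = %.3f\n",
           "  mean paired difference (%s - %s): %.3f\n",
           "  %.0f%% bootstrap CI (B = %d, seed = %d): %.3f to %.3f\n",
           "  Wilcoxon signed-rank p: %.3f\n"),
    x$evaluator_a, x$evaluator_b, nrow(x$per_case),
    x$evaluator_a, round_half_up(x$mean_a, 3),
    x$evaluator_b, round_half_up(x$mean_b, 3),
    x$evaluator_b, x$evaluator_a, round_half_up(x$delta, 3),
    100 * x$conf_level, x$b, x$seed,
    round_half_up(x$ci_low, 3), round_half_up(x$ci_high, 3),
    round_half_up(x$wilcoxon_p, 3)))
  invisible(x)
}

#' @method tidy abg_harm_summary
#' @export
tidy.abg_harm_summary <- function(x, ...) {
  out <- tidyr::pivot_longer(x$per_case, -"case_id",
                             names_to = "evaluator", values_to = "harm")
  dplyr::arrange(out, .data$evaluator, .data$case_id)
}

#' @method glance abg_harm_summary
#' @export
glance.abg_harm_summary <- function(x, ...) {
  tibble::tibble(evaluator_a = x$evaluator_a, evaluator_b = x$evaluator_b,
                 mean_harm_a = x$mean_a, mean_harm_b = x$mean_b,
                 mean_difference = x$delta, ci_low = x$ci_low,
                 ci_high = x$ci_high, wilcoxon_p = x$wilcoxon_p,
                 b = x$b, seed = x$seed, conf_level = x$conf_level)
}
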