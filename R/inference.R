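#' Paired correctness table for two evaluators
#'
#' Cross-classifies every case by whether each evaluator's category call
#' matched the reference: both correct (a), A-only correct (b), B-only
#' correct (c), both wrong (d). The marginals a+b and a+c reproduce the two
#' correct counts.
#'
#' @param cohort A cohort tibble.
#' @param evaluator_a,evaluator_b Evaluator ids.
#' @return One-row tibble: `evaluator_a`, `evaluator_b`, `both_correct`,
#'   `a_only`, `b_only`, `both_wrong`, `n`.
#' @export
#' @examples
#' paired_correctness_table(build_canonical_fixture(), "physician", "chatgpt")
paired_correctness_table <- function(cohort, evaluator_a, evaluator_b) {
  ra <- evaluator_rows(cohort, evaluator_a)
  rb <- evaluator_rows(cohort, evaluator_b)
  ok_a <- ra$predicted_category == ra$reference_category
  ok_b <- rb$predicted_category == rb$reference_category
  tibble::tibble(
    evaluator_a = evaluator_a, evaluator_b = evaluator_b,
    both_correct = sum(ok_a & ok_b), a_only = sum(ok_a & !ok_b),
    b_only = sum(!ok_a & ok_b), both_wrong = sum(!ok_a & !ok_b),
    n = length(ok_a)
  )
}

#' McNemar's test on a paired correctness table
#'
#' The default exact variant doubles the smaller binomial tail of the
#' discordant counts under a fair-coin null, capped at 1:
#' `p = min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' `b + c = 0` gives p = 1. The mid-p variant halves the probability of the
#' observed discordance split; the chi-square variant applies the classic
#' continuity-corrected statistic.
#'
#' @param table One-row tibble from [paired_correctness_table()], or a
#'   numeric vector/list with elements `a_only` and `b_only`.
#' @param variant `"exact"` (default), `"midp"`, or `"chisq"`.
#' @return One-row tibble: `b`, `c`, `p_value`, `method`.
#' @export
#' @examples
#' mcnemar_exact(list(a_only = 9, b_only = 4))
mcnemar_exact <- function(table, variant = c("exact", "midp", "chisq")) {
  variant <- match.arg(variant)
  b <- table[["a_only"]]
  cc <- table[["b_only"]]
  stopifnot(b >= 0, cc >= 0)
  m <- b + cc
  lo <- min(b, cc)
  p <- if (m == 0) {
    1
  } else if (variant == "exact") {
    min(1, 2 * stats::pbinom(lo, m, 0.5))
  } else if (variant == "midp") {
    min(1, 2 * (stats::pbinom(lo - 1, m, 0.5) + 0.5 * stats::dbinom(lo, m, 0.5)))
  } else {
    # continuity correction capped at |b - c|, as in stats::mcnemar.test
    stat <- max(0, abs(b - cc) - 1)^2 / m
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(b = as.integer(b), c = as.integer(cc), p_value = p,
                 method = paste0("mcnemar_", variant))
}

#' Cohen's h effect size for two proportions
#'
#' The arcsine-transformed difference `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @return Numeric effect size (vectorized).
#' @export
#' @examples
#' cohens_h(0.82, 0.72)
cohens_h <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Post-hoc power for a two-proportion comparison at effect size h
#'
#' The standard normal-approximation power of the two-sided two-proportion
#' test at arcsine effect size h with equal group sizes:
#' `power = Phi(|h| sqrt(n/2) - z_{1 - alpha/2})`. At h = 0 this is
#' alpha/2 (the one-tail approximation ignores the opposite rejection
#' region). Note this unpaired form is an approximation when applied to a
#' paired design.
#'
#' @param h Cohen's h effect size.
#' @param n_per_group Cases per group (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return One-row tibble: `h`, `n_per_group`, `alpha`, `power`.
#' @export
#' @examples
#' posthoc_power_two_proportions(cohens_h(0.82, 0.72), 50)
posthoc_power_two_proportions <- function(h, n_per_group, alpha = 0.05) {
  stopifnot(n_per_group >= 2, alpha > 0, alpha < 1)
  power <- stats::pnorm(abs(h) * sqrt(n_per_group / 2) -
                          stats::qnorm(1 - alpha / 2))
  tibble::tibble(h = h, n_per_group = n_per_group, alpha = alpha,
                 power = power)
}
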