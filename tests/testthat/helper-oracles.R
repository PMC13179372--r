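# Independent brute-force oracles used to check the analytic implementations.

# Clopper-Pearson bounds by direct tail inversion with uniroot: the lower
# bound solves P(X >= k | p) = alpha/2, the upper P(X <= k | p) = alpha/2.
oracle_clopper_pearson <- function(k, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lo <- if (k == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}

# Exact two-sided signed-rank p by enumerating all 2^m sign assignments;
# two-sided tail defined point-symmetrically about the null mean.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact McNemar p by summing binomial null probabilities directly
# (doubled smaller tail, capped at 1).
oracle_mcnemar_p <- function(b, c) {
  m <- b + c
  if (m == 0) return(1)
  probs <- choose(m, 0:m) / 2^m
  min(1, 2 * sum(probs[seq_len(min(b, c) + 1)]))
}

# Small cohort from parallel vectors of reference and per-evaluator
# predicted categories; component flags derived from the categories.
make_cohort <- function(reference, ..., provenance = "user") {
  preds <- list(...)
  stopifnot(length(preds) >= 1, !is.null(names(preds)))
  rows <- purrr::imap(preds, function(pred, ev) {
    tibble::tibble(
      case_id = sprintf("c%03d", seq_along(reference)),
      reference_category = reference,
      evaluator = ev,
      predicted_category = pred
    )
  })
  as_cohort(dplyr::bind_rows(rows), provenance = provenance)
}

# Profile of an infallible evaluator: identity confusion kernel and
# perfect component coding.
perfect_profile <- function() {
  evaluator_profile(diag(6), detect_metabolic = 1, detect_respiratory = 1)
}
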