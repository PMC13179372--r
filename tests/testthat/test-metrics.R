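fx <- build_canonical_fixture()

test_that("Clopper-Pearson bounds match tail inversion for all n <= 30", {
  for (n in 1:30) {
    ours <- clopper_pearson(0:n, n)
    for (k in 0:n) {
      expect_equal(c(ours$ci_low[k + 1], ours$ci_high[k + 1]),
                   oracle_clopper_pearson(k, n), tolerance = 1e-8)
    }
  }
})

test_that("overall accuracy reproduces the fixture's correct counts", {
  phys <- overall_accuracy(fx, "physician")
  gpt <- overall_accuracy(fx, "chatgpt")
  expect_identical(phys$numerator, 41L)
  expect_identical(gpt$numerator, 36L)
  expect_equal(phys$estimate, 0.82)
  expect_equal(gpt$estimate, 0.72)
  expect_true(phys$ci_low <= phys$estimate && phys$estimate <= phys$ci_high)
  boot <- overall_accuracy(fx, "physician", ci = "bootstrap", b = 500, seed = 3)
  boot2 <- overall_accuracy(fx, "physician", ci = "bootstrap", b = 500, seed = 3)
  expect_identical(boot, boot2)
  expect_true(boot$ci_low < 0.82 && boot$ci_high > 0.82)
  expect_error(overall_accuracy(fx, "nurse"), "Unknown evaluator")
})

test_that("confusion matrices sum to n with the correct count on the diagonal", {
  cm <- confusion_matrix(fx, "chatgpt")
  expect_identical(sum(cm$counts), 50L)
  expect_identical(sum(diag(cm$counts)), 36L)
  expect_identical(cm$counts["normal", "mixed"], 4L)
  td <- tidy(cm)
  expect_identical(sum(td$count), 50L)
  # row-wise proportions: each non-empty predicted row sums to 1
  sums <- rowSums(cm$proportions)
  expect_equal(unname(sums[rowSums(cm$counts) > 0]),
               rep(1, sum(rowSums(cm$counts) > 0)))
  one <- make_cohort("mixed", solo = "mixed")
  cm1 <- confusion_matrix(one, "solo")
  expect_identical(sum(diag(cm1$counts)), 1L)
  expect_identical(sum(cm1$counts), 1L)
})

test_that("kappa matches the matrix route, the fixture values and limits", {
  for (ev in c("physician", "chatgpt")) {
    kc <- cohens_kappa(fx, ev)
    km <- harmdx:::kappa_stats(confusion_matrix(fx, ev)$counts)
    expect_equal(kc$kappa, km$kappa, tolerance = 1e-12)
    expect_equal(kc$p_o, km$p_o, tolerance = 1e-12)
  }
  expect_equal(round_half_up(cohens_kappa(fx, "physician")$kappa, 2), 0.73)
  expect_equal(round_half_up(cohens_kappa(fx, "chatgpt")$kappa, 2), 0.63)
  # closed forms from the marginals
  expect_equal(cohens_kappa(fx, "physician")$kappa,
               (0.82 - 841 / 2500) / (1 - 841 / 2500), tolerance = 1e-12)
  expect_equal(cohens_kappa(fx, "chatgpt")$kappa,
               (0.72 - 615 / 2500) / (1 - 615 / 2500), tolerance = 1e-12)

  perfect <- make_cohort(c("mixed", "normal", "mixed"),
                         ev = c("mixed", "normal", "mixed"))
  expect_equal(cohens_kappa(perfect, "ev")$kappa, 1)
  # independence by construction: cell counts equal products of marginals / n
  indep <- make_cohort(rep(c("mixed", "normal"), each = 2),
                       ev = rep(c("mixed", "normal"), times = 2))
  expect_equal(cohens_kappa(indep, "ev")$kappa, 0)
  degenerate <- make_cohort(c("mixed", "mixed"), ev = c("mixed", "mixed"))
  expect_error(cohens_kappa(degenerate, "ev"), "undefined")
  expect_identical(glance(cohens_kappa(fx, "physician"))$n, 50L)
})

test_that("complexity strata partition the overall correct count", {
  for (ev in c("physician", "chatgpt")) {
    strat <- complexity_stratified_accuracy(fx, ev)
    expect_identical(sum(strat$numerator), overall_accuracy(fx, ev)$numerator)
  }
  phys <- complexity_stratified_accuracy(fx, "physician")
  expect_identical(phys$numerator[phys$stratum == "mixed"], 23L)
  expect_identical(phys$denominator[phys$stratum == "mixed"], 24L)
  expect_identical(phys$numerator[phys$stratum == "non_mixed"], 18L)
  expect_identical(phys$denominator[phys$stratum == "non_mixed"], 26L)
  gpt <- complexity_stratified_accuracy(fx, "chatgpt")
  expect_identical(gpt$numerator[gpt$stratum == "mixed"], 15L)
  only_mixed <- make_cohort(c("mixed", "mixed"), ev = c("mixed", "normal"))
  expect_warning(complexity_stratified_accuracy(only_mixed, "ev"),
                 "Empty denominator")
})

test_that("mixed-disorder detection reproduces the published fractions", {
  phys <- mixed_detection(fx, "physician")
  gpt <- mixed_detection(fx, "chatgpt")
  get <- function(df, m) df[df$metric == m, ]
  expect_equal(get(phys, "mixed_sensitivity")$estimate, 23 / 24)
  expect_equal(get(phys, "mixed_specificity")$estimate, 19 / 26)
  expect_equal(get(gpt, "mixed_sensitivity")$estimate, 15 / 24)
  expect_equal(get(gpt, "mixed_specificity")$estimate, 23 / 26)
  expect_equal(round_half_up(get(phys, "mixed_sensitivity")$estimate, 2), 0.96)
  expect_equal(round_half_up(get(gpt, "mixed_sensitivity")$estimate, 2), 0.63)
})

test_that("component detection uses the multi-label flags, not the category", {
  phys <- component_detection(fx, "physician")
  gpt <- component_detection(fx, "chatgpt")
  get <- function(df, m) df[df$metric == m, ]
  expect_identical(get(phys, "metabolic_sensitivity")$numerator, 34L)
  expect_identical(get(phys, "metabolic_sensitivity")$denominator, 35L)
  expect_identical(get(phys, "respiratory_sensitivity")$numerator, 34L)
  expect_identical(get(phys, "respiratory_sensitivity")$denominator, 34L)
  expect_identical(get(gpt, "metabolic_sensitivity")$numerator, 31L)
  expect_identical(get(gpt, "respiratory_sensitivity")$numerator, 30L)
  expect_identical(get(gpt, "respiratory_sensitivity")$denominator, 34L)
  # specificities are computed too, over the complements
  expect_identical(get(gpt, "metabolic_specificity")$denominator, 15L)
  expect_identical(get(gpt, "respiratory_specificity")$denominator, 16L)
})

test_that("false-reassurance rate, zero-count CI bound and exact test", {
  gpt <- false_reassurance(fx, "chatgpt")
  expect_identical(gpt$numerator, 4L)
  expect_identical(gpt$denominator, 24L)
  expect_equal(round_half_up(100 * gpt$estimate, 1), 16.7)
  phys <- false_reassurance(fx, "physician")
  expect_identical(phys$numerator, 0L)
  # closed-form Clopper-Pearson upper bound for zero successes
  expect_equal(phys$ci_high, 1 - 0.025^(1 / 24), tolerance = 1e-9)
  expect_identical(phys$ci_low, 0)
  # one-sided exact test against an explicit null rate: binomial tail sum
  tested <- false_reassurance(fx, "chatgpt", p0 = 0.05)
  tail_sum <- sum(stats::dbinom(4:24, 24, 0.05))
  expect_equal(tested$p_value, tail_sum, tolerance = 1e-12)
  expect_error(false_reassurance(fx, "chatgpt", p0 = 1), "p0")
  no_mixed <- make_cohort(c("normal", "normal"), ev = c("normal", "normal"))
  expect_error(false_reassurance(no_mixed, "ev"), "mixed")
})
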