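fx <- build_canonical_fixture()

test_that("weight construction enforces the severity hierarchy", {
  w <- default_harm_weights()
  expect_equal(unname(unclass(w)["false_reassurance"]), 1)
  expect_equal(unname(unclass(w)["mixed_as_single"]), 1.04 - 2.16 / 7)
  expect_equal(unname(unclass(w)["other_misclassification"]), 2.16 / 7)
  expect_error(harm_weights(1, 1, 0.5), "hierarchy|>")
  expect_error(harm_weights(0.5, 0.7, 0.2), ">")
  expect_error(harm_weights(1, 0.5, -0.1), ">")
})

test_that("per-case scores are tier lookups with 0 for correct calls", {
  w <- default_harm_weights()
  expect_equal(harm_score("mixed", "normal", w), 1)
  expect_equal(harm_score("mixed", "metabolic_acidosis", w), 1.04 - 2.16 / 7)
  expect_equal(harm_score("metabolic_acidosis", "mixed", w), 2.16 / 7)
  expect_equal(harm_score("respiratory_alkalosis", "respiratory_alkalosis", w), 0)
})

test_that("fixture mean harms reproduce the published values", {
  expect_equal(mean_harm(fx, "physician"), 0.064, tolerance = 1e-12)
  expect_equal(mean_harm(fx, "chatgpt"), 0.184, tolerance = 1e-12)
  all_right <- make_cohort(c("mixed", "normal"), ev = c("mixed", "normal"))
  expect_equal(mean_harm(all_right, "ev"), 0)
})

test_that("weight calibration inverts the published means and flags degeneracy", {
  w <- calibrate_weights(
    c(false_reassurance = 0, mixed_as_single = 1, other = 8),
    c(false_reassurance = 4, mixed_as_single = 5, other = 5),
    0.064, 0.184, anchor = 1, n = 50)
  expect_equal(unname(unclass(w)[c("false_reassurance", "mixed_as_single",
                                   "other_misclassification")]),
               c(1, 1.04 - 2.16 / 7, 2.16 / 7), tolerance = 1e-12)
  # recovered weights reproduce both targets on the fixture exactly
  expect_equal(mean_harm(fx, "physician", w), 0.064, tolerance = 1e-12)
  expect_equal(mean_harm(fx, "chatgpt", w), 0.184, tolerance = 1e-12)
  expect_error(calibrate_weights(
    c(false_reassurance = 0, mixed_as_single = 2, other = 2),
    c(false_reassurance = 0, mixed_as_single = 1, other = 1),
    0.1, 0.05, anchor = 1, n = 50), "singular")
})

test_that("mean harm is linear in the weights", {
  for (c_scale in c(0.5, 2, 10)) {
    w <- default_harm_weights()
    ws <- harm_weights(c_scale * 1, c_scale * (1.04 - 2.16 / 7),
                       c_scale * 2.16 / 7)
    for (ev in c("physician", "chatgpt")) {
      expect_equal(mean_harm(fx, ev, ws), c_scale * mean_harm(fx, ev, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact signed-rank p equals brute-force enumeration on small instances", {
  cases <- list(
    c(1, 1, 1, 1, 1),
    c(2, -2),
    c(1, -1, 2, 3, -2, 4),
    c(0.5, 0.5, -0.5, 1.5, 1.5, 1.5, -2),   # heavy ties
    c(3, 1, 4, 1, -5, 9, -2, 6, -5, 3, 5),  # ties across signs
    rnorm(12)
  )
  withr::with_seed(42, cases[[6]] <- rnorm(12))
  for (d in cases) {
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, oracle_wilcoxon_p(d), tolerance = 1e-12)
  }
  # all-positive differences: doubled single tail 2/2^5
  expect_equal(wilcoxon_signed_rank(c(1, 1, 1, 1, 1))$p_value, 2 / 32)
  # antisymmetric pair sits at the center of the null
  expect_equal(wilcoxon_signed_rank(c(2, -2))$p_value, 1)
})

test_that("exact signed-rank p agrees with stats::wilcox.test when tie-free", {
  withr::with_seed(7, d <- round(rnorm(15), 3))
  stopifnot(!anyDuplicated(abs(d)), all(d != 0))
  got <- wilcoxon_signed_rank(d)$p_value
  ref <- stats::wilcox.test(d, exact = TRUE)$p.value
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("large samples switch to the tie-corrected normal approximation", {
  withr::with_seed(11, d <- rnorm(60, mean = 0.3))
  got <- wilcoxon_signed_rank(d)
  expect_identical(got$method, "normal_approximation")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-9)
})

test_that("degenerate and zero-handling behavior of the paired harm test", {
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
  all_right <- make_cohort(c("mixed", "normal"),
                           a = c("mixed", "normal"), b = c("mixed", "normal"))
  expect_error(paired_harm_test(all_right, "a", "b"), "degenerate")
  expect_error(paired_harm_test(fx, "physician", "nurse"), "Unknown evaluator")
  res <- paired_harm_test(fx, "physician", "chatgpt")
  expect_identical(res$n_nonzero, 13L)   # 37 of 50 paired differences are 0
  expect_lt(res$p_value, 0.05)
  # Pratt zero-handling ranks zeros first, shifting all nonzero ranks up
  pratt <- paired_harm_test(fx, "physician", "chatgpt", zero_method = "pratt")
  expect_identical(pratt$n_nonzero, 13L)
  expect_true(pratt$statistic > res$statistic)
})

test_that("paired bootstrap is seeded, centered on the mean difference", {
  hs <- bootstrap_harm_difference(fx, "physician", "chatgpt", b = 2000, seed = 5)
  hs2 <- bootstrap_harm_difference(fx, "physician", "chatgpt", b = 2000, seed = 5)
  expect_identical(glance(hs), glance(hs2))
  expect_equal(hs$delta, 0.12, tolerance = 1e-12)
  expect_equal(hs$mean_a, 0.064, tolerance = 1e-12)
  expect_equal(hs$mean_b, 0.184, tolerance = 1e-12)
  expect_true(hs$ci_low > 0)
  expect_true(hs$ci_low < 0.12 && 0.12 < hs$ci_high)
  # constant paired differences collapse the interval to a point
  const <- make_cohort(rep("mixed", 3),
                       a = rep("mixed", 3), b = rep("normal", 3))
  hc <- bootstrap_harm_difference(const, "a", "b", b = 50, seed = 1)
  expect_equal(hc$ci_low, 1)
  expect_equal(hc$ci_high, 1)
  one <- make_cohort("mixed", a = "mixed", b = "normal")
  expect_warning(bootstrap_harm_difference(one, "a", "b", b = 10, seed = 1),
                 "degenerate")
})

test_that("bootstrap interval tightens around the truth as n grows", {
  prof_a <- perfect_profile()
  rows <- diag(6)
  rows[1, ] <- c(0.8, 0.05, 0.05, 0.1, 0, 0)  # imperfect on mixed only
  prof_b <- evaluator_profile(rows)
  wide <- generate_cohort(200, fixture_reference_distribution(),
                          list(a = prof_a, b = prof_b), seed = 21)
  big <- generate_cohort(2000, fixture_reference_distribution(),
                         list(a = prof_a, b = prof_b), seed = 22)
  hs_wide <- bootstrap_harm_difference(wide, "a", "b", b = 400, seed = 3)
  hs_big <- bootstrap_harm_difference(big, "a", "b", b = 400, seed = 3)
  expect_lt(hs_big$ci_high - hs_big$ci_low, hs_wide$ci_high - hs_wide$ci_low)
  expect_true(hs_big$ci_low <= hs_big$delta && hs_big$delta <= hs_big$ci_high)
})
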