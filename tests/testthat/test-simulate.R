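test_that("profile estimation recovers the fixture's conditional rates", {
  fx <- build_canonical_fixture()
  gpt <- profile_from_cohort(fx, "chatgpt")
  expect_equal(gpt$confusion_rows["mixed", "normal"], 4 / 24, tolerance = 1e-12)
  expect_equal(gpt$confusion_rows["mixed", "mixed"], 15 / 24, tolerance = 1e-12)
  phys <- profile_from_cohort(fx, "physician")
  expect_equal(phys$confusion_rows["mixed", "mixed"], 23 / 24, tolerance = 1e-12)
  expect_equal(unname(rowSums(gpt$confusion_rows)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(gpt$detect["metabolic"]), 31 / 35, tolerance = 1e-12)
  expect_equal(unname(gpt$detect["respiratory"]), 30 / 34, tolerance = 1e-12)
  # an always-correct evaluator yields identity confusion rows
  all_right <- make_cohort(abg_categories(), ev = abg_categories())
  expect_equal(unname(profile_from_cohort(all_right, "ev")$confusion_rows),
               diag(6), tolerance = 1e-12)
})

test_that("zero-support reference categories get a uniform row with a warning", {
  small <- make_cohort(c("mixed", "normal"), ev = c("mixed", "normal"))
  expect_warning(prof <- profile_from_cohort(small, "ev"), "without support")
  expect_equal(unname(prof$confusion_rows["metabolic_acidosis", ]),
               rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("generator validates distributions before sampling", {
  prof <- perfect_profile()
  expect_error(generate_cohort(10, c(mixed = 0.9), list(a = prof), seed = 1),
               "named")
  bad <- fixture_reference_distribution()
  bad[1] <- bad[1] + 0.1
  expect_error(generate_cohort(10, bad, list(a = prof), seed = 1), "sum to 1")
  rows <- diag(6); rows[1, 1] <- 0.5
  expect_error(evaluator_profile(rows), "sum to 1")
  expect_error(evaluator_profile(diag(6), detect_metabolic = 1.2), "\\[0, 1\\]")
  expect_error(generate_cohort(10, fixture_reference_distribution(),
                               list(prof), seed = 1), "named")
})

test_that("generation is deterministic under a fixed seed", {
  prof <- profile_from_cohort(build_canonical_fixture(), "chatgpt")
  cfg <- list(n = 40, reference_distribution = fixture_reference_distribution(),
              profiles = list(ai = prof), seed = 99)
  expect_identical(do.call(generate_cohort, cfg), do.call(generate_cohort, cfg))
  other <- cfg; other$seed <- 100
  expect_false(identical(do.call(generate_cohort, cfg),
                         do.call(generate_cohort, other)))
})

test_that("degenerate point-mass configuration yields all-mixed, all-correct", {
  rows <- matrix(0, 6, 6); rows[, 1] <- 1  # always predict mixed
  prof <- evaluator_profile(rows)
  dist <- c(mixed = 1, metabolic_alkalosis = 0, respiratory_alkalosis = 0,
            normal = 0, respiratory_acidosis = 0, metabolic_acidosis = 0)
  coh <- generate_cohort(25, dist, list(a = prof), seed = 4)
  expect_true(all(coh$reference_category == "mixed"))
  expect_true(all(coh$predicted_category == "mixed"))
  expect_equal(overall_accuracy(coh, "a")$estimate, 1)
})

test_that("always-correct profiles give perfect downstream metrics", {
  coh <- generate_cohort(300, fixture_reference_distribution(),
                         list(a = perfect_profile()), seed = 12)
  expect_equal(overall_accuracy(coh, "a")$estimate, 1)
  md <- mixed_detection(coh, "a")
  expect_equal(md$estimate, c(1, 1))
  cd <- component_detection(coh, "a")
  expect_equal(cd$estimate, rep(1, 4))
  expect_equal(cohens_kappa(coh, "a")$kappa, 1)
  expect_equal(mean_harm(coh, "a"), 0)
})

test_that("metrics on large synthetic cohorts recover the profile conditionals", {
  # n = 50,000 cases; binomial standard error on the mixed stratum
  # (~24,000 cases) is about 0.003, so +/-0.02 is a 6-sigma band
  fx <- build_canonical_fixture()
  profs <- list(physician = profile_from_cohort(fx, "physician"),
                chatgpt = profile_from_cohort(fx, "chatgpt"))
  coh <- generate_cohort(50000, fixture_reference_distribution(), profs,
                         seed = 2024)
  for (ev in names(profs)) {
    sens <- mixed_detection(coh, ev)
    expect_equal(sens$estimate[sens$metric == "mixed_sensitivity"],
                 profs[[ev]]$confusion_rows["mixed", "mixed"],
                 tolerance = 0.02)
    acc <- overall_accuracy(coh, ev)$estimate
    expected_acc <- sum(fixture_reference_distribution() *
                          diag(profs[[ev]]$confusion_rows))
    expect_equal(acc, expected_acc, tolerance = 0.02)
    cd <- component_detection(coh, ev)
    expect_equal(cd$estimate[cd$metric == "metabolic_sensitivity"],
                 unname(profs[[ev]]$detect["metabolic"]), tolerance = 0.02)
    expect_equal(cd$estimate[cd$metric == "respiratory_sensitivity"],
                 unname(profs[[ev]]$detect["respiratory"]), tolerance = 0.02)
  }
})

test_that("generator configuration round-trips through JSON", {
  prof <- profile_from_cohort(build_canonical_fixture(), "chatgpt")
  cfg <- list(n = 30, reference_distribution = fixture_reference_distribution(),
              profiles = list(ai = prof), seed = 17)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, tmp)
  back <- read_generator_config(tmp)
  expect_equal(back$n, 30)
  expect_equal(back$seed, 17)
  expect_equal(back$reference_distribution, cfg$reference_distribution,
               tolerance = 1e-12)
  expect_equal(back$profiles$ai$confusion_rows, prof$confusion_rows,
               tolerance = 1e-12)
  expect_identical(do.call(generate_cohort, back), do.call(generate_cohort, cfg))
})
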