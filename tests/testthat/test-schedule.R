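test_that("perceptual schedule realises the stated design counts", {
  sch <- generate_perceptual_schedule(seed = 1)
  combos <- unique(sch[, c("phi1", "phi2")])
  expect_equal(nrow(combos), 23L)
  # the two maximally conflicting pairs are absent
  expect_false(any(combos$phi1 == -20 & combos$phi2 == 20))
  expect_false(any(combos$phi1 == 20 & combos$phi2 == -20))
  counts <- table(paste(sch$phi1, sch$phi2), sch$condition)
  expect_true(all(counts[, "choice"] == 45L))
  expect_true(all(counts[, "nochoice"] == 45L))
  expect_equal(nrow(sch), 23L * 90L)

  # feedback-terminated trials double the Choice count when appended
  full <- generate_perceptual_schedule(seed = 1, include_feedback_trials = TRUE)
  expect_equal(sum(full$feedback_terminated), 23L * 45L)

  # 2 levels, nothing excluded: plain 2x2 grid
  d2 <- perceptual_design(direction_levels = c(-10, 10),
                          excluded_pairs = list(),
                          trials_per_combination = 4)
  expect_equal(nrow(unique(generate_perceptual_schedule(d2)[, c("phi1", "phi2")])),
               4L)

  # off-grid excluded pair is a configuration error
  expect_error(perceptual_design(excluded_pairs = list(c(-20, 15))),
               "not on the direction-level grid")
})

test_that("schedules are exactly reproducible from (design, seed)", {
  expect_identical(generate_perceptual_schedule(seed = 42),
                   generate_perceptual_schedule(seed = 42))
  a <- generate_numerical_schedule(200, seed = 42)
  b <- generate_numerical_schedule(200, seed = 42)
  expect_identical(a, b)
})

test_that("triangular number sampler matches stated means, support and no-repeat rule", {
  # solved apexes reproduce the stated expectations exactly
  for (m in c(40, 46, 54, 60)) {
    w <- triangular_weights(m)
    expect_equal(sum(w$support * w$prob), m, tolerance = 1e-9)
    expect_true(all(w$support >= 10 & w$support <= 90))
  }
  # large simulation from the mean-60 distribution
  set.seed(7)
  draws <- replicate(12500, sample_interval_numbers(60))  # 1e5 samples
  expect_lt(abs(mean(draws) - 60), 0.5)
  expect_gte(min(draws), 10)
  expect_lte(max(draws), 90)
  # no-repeat property over many seeds
  for (s in 1:100) {
    x <- sample_interval_numbers(46, seed = s)
    expect_equal(length(x), 8L)
    expect_false(any(diff(x) == 0))
  }
  expect_error(sample_interval_numbers(45), "distribution means")
})

test_that("numerical schedule allocates trial types in the stated fractions", {
  sch <- generate_numerical_schedule(4000, seed = 3)
  est <- !sch$feedback_terminated
  expect_equal(mean(est), 0.5)                            # estimation trials
  expect_equal(mean(sch$condition == "nochoice"), 0.25)   # No-Choice fraction
  expect_true(all(sch$mean1_id %in% c(46, 54)))
  expect_true(all(sch$mean2_id %in% c(40, 46, 54, 60)))
  # evidence coding: phi_i = mean(samples_i) - reference
  expect_equal(sch$phi1, vapply(sch$samples1, mean, 0) - 50, tolerance = 1e-9)
  i <- which(est)[1]
  expect_equal(sch$phi2[i], mean(sch$samples2[[i]]) - 50, tolerance = 1e-9)

  all_fb <- generate_numerical_schedule(
    4, numerical_design(trial_type_fractions = c(choice_feedback = 1,
                                                 choice_estimation = 0,
                                                 nochoice_estimation = 0)),
    seed = 1)
  expect_true(all(all_fb$feedback_terminated))
})
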