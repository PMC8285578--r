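test_that("global-gain fit recovers a simulated subject and is a local optimum", {
  kept <- small_subject(seed = 31)
  psych <- fit_psychometric(kept)
  fit <- fit_gain_model(kept, psych, model = "global", starts = 1)
  truth <- c(w1c = 0.7, w2c = 0.3, xi_c = 3, w1nc = 0.5, w2nc = 0.5,
             xi_nc = 3)
  # reduced-n unit check; the full-scale recovery harness lives in the
  # acceptance suite
  expect_lt(max(abs(fit$params[c("w1c", "w2c", "w1nc", "w2nc")] -
                      truth[c("w1c", "w2c", "w1nc", "w2nc")])), 0.2)
  # optimality: fitted loglik beats the generative parameters on this data
  expect_gte(fit$loglik, model_loglik(kept, psych, as.list(truth), "global"))
  # fixed point: refitting from the fitted values reproduces them
  refit <- fit_gain_model(kept, psych, model = "global", starts = 1,
                          start = as.list(fit$params))
  expect_equal(refit$params, fit$params, tolerance = 0.02)
  # methods
  expect_equal(coef(fit), fit$params)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "Global gain model fit")
  expect_output(print(summary(fit)), "nonselective")
})

test_that("selective-gain fit separates consistent and inconsistent weights", {
  w <- list(w1cc = 0.7, w2cc = 0.5, xi_cc = 3, w1ic = 0.7, w2ic = 0.2,
            xi_ic = 3, w1nc = 0.5, w2nc = 0.5, xi_nc = 3)
  obs <- observer_params(0.1, 0, w, model = "selective")
  kept <- small_subject(seed = 32, trials_per_combination = 40, obs = obs)
  psych <- fit_psychometric(kept)
  ch <- kept[kept$condition == "choice" & kept$consistency != "undefined", ]
  fit <- fit_gain_model(ch, psych, model = "selective", starts = 1)
  cb <- confirmation_bias(fit)
  expect_gt(cb, 0.1)          # generative index is 0.3
  expect_lt(cb, 0.5)
  expect_gt(fit$params["w2cc"], fit$params["w2ic"])
  # trivial index arithmetic and sign symmetry
  fake <- structure(list(model = "selective",
                         params = c(w2cc = 0.6, w2ic = 0.4)),
                    class = "gainfit")
  expect_equal(confirmation_bias(fake), 0.2)
  swapped <- structure(list(model = "selective",
                            params = c(w2cc = 0.4, w2ic = 0.6)),
                       class = "gainfit")
  expect_equal(confirmation_bias(swapped), -0.2)
})

test_that("bootstrap CIs are well-formed and degenerate data collapse them", {
  kept <- small_subject(seed = 33, trials_per_combination = 10)
  psych <- fit_psychometric(kept)
  fit <- fit_gain_model(kept, psych, "global", starts = 1)
  bt <- bootstrap_fit(fit, n_boot = 25, seed = 1)
  for (ci in bt$ci) {
    expect_equal(dim(ci), c(2L, length(fit$params)))
    expect_true(all(ci[1, ] <= ci[2, ] + 1e-12))
  }
  # all trials identical: every resample is the same data set, zero width
  one <- kept[rep(which(kept$condition == "nochoice")[1], 60), ]
  psy1 <- list(sigma = 10, delta_e = 0, alpha = 0.1, delta = 0)
  f1 <- fit_gain_model(one, psy1, "global", starts = 1)
  b1 <- bootstrap_fit(f1, n_boot = 8, seed = 2)
  expect_lt(max(b1$ci[["95%"]][2, ] - b1$ci[["95%"]][1, ]), 1e-6)
})

test_that("bootstrap CI width shrinks with sample size", {
  obs <- default_observer()
  widths <- vapply(c(10, 40), function(tpc) {
    kept <- small_subject(seed = 34, trials_per_combination = tpc, obs = obs)
    nc <- kept[kept$condition == "nochoice", ]
    psych <- fit_psychometric(kept)
    fit <- fit_gain_model(nc, psych, "global", starts = 1)
    bt <- bootstrap_fit(fit, n_boot = 40, seed = 3)
    m <- bt$ci[["95%"]]
    median(m[2, c("w1nc", "w2nc")] - m[1, c("w1nc", "w2nc")])
  }, 0)
  expect_lt(widths[2], widths[1])
})

test_that("simulate() from a fit is choice-matched", {
  kept <- small_subject(seed = 35, trials_per_combination = 10)
  psych <- fit_psychometric(kept)
  fit <- fit_gain_model(kept, psych, "global", starts = 1)
  sim <- simulate(fit, seed = 4)
  ch <- sim$condition == "choice"
  expect_true(all(sign(sim$X1[ch]) == sim$D[ch]))

  # half-normal mean of the constrained representation
  tr <- trial_frame(phi1 = 0, phi2 = 0, condition = "choice", D = 1,
                    y = 0)[rep(1, 4e4), ]
  fit$data <- tr
  psy0 <- list(sigma = 10, delta_e = 0)
  fit$psych <- psy0
  sim2 <- simulate(fit, seed = 5, trials = tr)
  expect_lt(abs(mean(sim2$X1) - 10 * sqrt(2 / pi)), 0.15)

  # xi = 0, w2 = 0: y is exactly the scaled truncated representation
  fit$params[c("w1c", "w2c", "xi_c")] <- c(0.5, 0, 0)
  sim3 <- simulate(fit, seed = 6, trials = tr)
  expect_equal(sim3$y, 0.5 * sim3$X1)
})
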