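test_that("blink interpolation is exact on linear segments and merges overlaps", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  ramp <- 2 + 0.3 * tt
  x <- ramp
  x[tt > 4 & tt < 4.3] <- -5              # artefact on a linear ramp
  tr <- pupil_trace(tt, x, fs,
                    events = data.frame(time = 4.05, type = "blink",
                                        duration = 0.2))
  out <- interpolate_blinks(tr)
  expect_equal(out$diameter, ramp, tolerance = 1e-9)

  # two abutting blinks form a single interpolation span
  x2 <- ramp; x2[tt > 3 & tt < 3.8] <- -5
  tr2 <- pupil_trace(tt, x2, fs,
                     events = data.frame(time = c(3.1, 3.45), type = "blink",
                                         duration = 0.25))
  expect_equal(interpolate_blinks(tr2)$diameter, ramp, tolerance = 1e-9)

  # blink at the trace edge: nearest-value extension
  x3 <- ramp; x3[tt < 0.2] <- -5
  tr3 <- pupil_trace(tt, x3, fs,
                     events = data.frame(time = 0.02, type = "blink",
                                         duration = 0.15))
  out3 <- interpolate_blinks(tr3)
  expect_true(all(is.finite(out3$diameter)))
  expect_lt(max(abs(out3$diameter - ramp)[tt < 0.31]), 0.3)
})

test_that("FIR deconvolution recovers the event kernel and empties the event-locked average", {
  fx <- deconv_fixture(seed = 71)
  out <- remove_event_responses(fx$trace, window = 3, res = 0.05,
                                event_types = "blink")
  k <- attr(out, "kernels")
  expect_gt(cor(k$kernels[, "blink"], fx$kernel(k$lags)), 0.95)
  # residual (demeaned) event-locked average is near zero at kernel latencies
  fs <- out$fs
  res <- out$diameter - mean(out$diameter)
  locked <- sapply(out$events$time, function(t0) {
    j <- round(t0 * fs) + 1L
    res[j:(j + 2 * fs)]
  })
  expect_lt(max(abs(rowMeans(locked))), 0.15)

  # no events: identity transform
  tr0 <- pupil_trace(fx$trace$time, fx$trace$diameter, fx$trace$fs)
  expect_identical(remove_event_responses(tr0)$diameter, fx$trace$diameter)
})

test_that("band-pass design matches the analytic Butterworth response", {
  fs <- 1000
  tt <- seq(0, 120, by = 1 / fs)
  gain_db <- function(f) {
    y <- bandpass_butter(sin(2 * pi * f * tt), fs)
    mid <- tt > 40 & tt < 80
    20 * log10(sqrt(mean(y[mid]^2)) * sqrt(2))
  }
  expect_lt(gain_db(0.001), -20)           # slow drift strongly attenuated
  expect_gt(gain_db(5), -1)                # passband intact within 1 dB
  expect_lt(gain_db(20), -20)              # above-band tone rejected
  # analytic check: forward-backward 2nd-order low-pass gain at f/fc = 2
  # is (1 + (f/fc)^4)^-1, i.e. -24.6 dB relative passband
  expect_equal(gain_db(20), -10 * log10(1 + (20 / 10)^4) * 2, tolerance = 1)
})

test_that("filter-normalize yields z-scored 50 Hz traces", {
  sch <- trial_frame(phi1 = 0, phi2 = 0, condition = "choice", D = 1, y = 0)
  sch <- sch[rep(1, 10), ]; sch$trial_id <- 1:10
  tr <- simulate_pupil(sch, fs = 500, seed = 72)
  out <- filter_normalize(tr)
  expect_equal(out$fs, 50)
  expect_lt(abs(mean(out$diameter)), 0.05)
  expect_lt(abs(sd(out$diameter) - 1), 0.05)
  expect_error(filter_normalize(tr, fs_out = 43), "integer")
})

test_that("epoching, baselining and re-locking behave as specified", {
  sch <- trial_frame(phi1 = 0, phi2 = 0, condition = "choice", D = 1, y = 0)
  sch <- sch[rep(1, 12), ]; sch$trial_id <- 1:12
  tr <- filter_normalize(simulate_pupil(sch, fs = 500, seed = 73,
                                        blink_rate = 0))
  ep <- epoch_and_baseline(tr)
  expect_s3_class(ep, "pupil_epochs")
  expect_equal(nrow(ep$data), 12L)
  # baseline window averages to exactly 0 after correction
  bidx <- ep$time >= -0.5 & ep$time < 0
  expect_lt(max(abs(rowMeans(ep$data[, bidx], na.rm = TRUE))), 1e-12)
  # epochs never exceed 6 s post-lock
  expect_lte(max(ep$time), 6)
  # re-locking to the estimation response preserves sample values: the
  # overlap of the two epochs holds identical samples, shifted by the
  # lock-to-lock lag
  ep2 <- epoch_and_baseline(tr, lock = "estimation_response")
  ev <- tr$events
  ok <- !is.na(ev$trial_id) & ev$trial_id == 1
  t_lock <- ev$time[ev$type == "estimation_response" & ok]
  t_on <- ev$time[ev$type == "interval1_onset" & ok]
  shift <- which.min(abs(tr$time - t_lock)) - which.min(abs(tr$time - t_on))
  common2 <- which(ep2$time >= 0 & ep2$time <= 1)
  expect_equal(ep2$data[1, common2], ep$data[1, common2 + shift],
               tolerance = 1e-12)
})

test_that("condition averages recover injected amplitude differences", {
  sch <- trial_frame(phi1 = 0, phi2 = 0,
                     condition = rep(c("choice", "nochoice"), each = 15),
                     D = 1, y = 0)
  sch$trial_id <- seq_len(nrow(sch))
  tr <- filter_normalize(simulate_pupil(
    sch, fs = 500, seed = 74, noise_sd = 0.02, blink_rate = 0,
    amp_intermittent = c(choice = 1, nochoice = 0.5)))
  ep <- epoch_and_baseline(tr)
  ca <- condition_average(ep)
  # window around the intermittent-response dilation peak
  win <- ep$time > 1.5 & ep$time < 3
  diffs <- ca$choice$mean[win] - ca$nochoice$mean[win]
  # injected amplitudes 1.0 vs 0.5: after undoing the block z-scoring the
  # recovered peak condition difference is about the 0.5 gap
  expect_equal(max(diffs) * attr(tr, "scale"), 0.5, tolerance = 0.2)
  # single epoch: average equals it
  ca1 <- condition_average(ep$data[1, , drop = FALSE], labels = "only")
  expect_equal(ca1$only$mean, ep$data[1, ])
  # SE shrinks as 1/sqrt(n)
  m <- matrix(rnorm(400), 40)
  ca40 <- condition_average(m, labels = rep("a", 40))
  ca10 <- condition_average(m[1:10, ], labels = rep("a", 10))
  expect_equal(median(ca10$a$se / ca40$a$se), 2, tolerance = 0.35)
})

test_that("cluster permutation test finds injected windows and is symmetric", {
  set.seed(75)
  ns <- 12; nt <- 150
  A <- matrix(rnorm(ns * nt), ns)
  B <- matrix(rnorm(ns * nt), ns)
  inject <- 60:90                          # 1-s difference window
  A[, inject] <- A[, inject] + 1.2
  res <- cluster_permutation_timecourse(A, B, n_perm = 500, seed = 1)
  expect_false(is.null(res$clusters))
  best <- res$clusters[which.min(res$clusters$p), ]
  expect_lt(best$p, 0.05)
  expect_true(best$start <= max(inject) && best$end >= min(inject))

  flipped <- cluster_permutation_timecourse(B, A, n_perm = 500, seed = 1)
  fbest <- flipped$clusters[which.min(flipped$clusters$p), ]
  expect_equal(fbest$mass, -best$mass, tolerance = 1e-9)
  expect_equal(fbest$p, best$p)

  # identical conditions: typically no suprathreshold cluster survives
  null_res <- cluster_permutation_timecourse(B, B + 0, n_perm = 100, seed = 2)
  expect_true(is.null(null_res$clusters))
})

test_that("scalar window responses are plain window means", {
  ep <- structure(list(time = seq(-0.5, 5.5, by = 0.02),
                       data = matrix(3, 4, 301),
                       condition = rep(c("a", "b"), 2), fs = 50,
                       lock = "interval1_onset"),
                  class = "pupil_epochs")
  expect_equal(unname(scalar_response(ep, c(1, 2))), rep(3, 4))
  by_lab <- scalar_response(ep, c(1, 2), labels = ep$condition)
  expect_equal(as.numeric(by_lab), c(3, 3))
  expect_error(scalar_response(ep, c(2, 2)), "positive length")
  expect_error(scalar_response(ep, c(40, 50)), "outside")
})
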