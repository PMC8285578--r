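test_that("sign-flip permutation test: exhaustive path, edge cases, MC agreement", {
  set.seed(51)
  x <- rnorm(10, 0.8); y <- rnorm(10)
  ex <- paired_permutation_test(x, y)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 1024L)          # 2^10 unique sign patterns
  expect_equal(ex$statistic, mean(x - y))

  # identical data: p = 1
  expect_equal(paired_permutation_test(x, x)$p, 1)
  expect_error(paired_permutation_test(1, 2), "at least 2")

  # Monte-Carlo agrees with the exhaustive answer within binomial error
  x13 <- c(x, 0.1, -0.4, 0.6); y13 <- c(y, 0, 0.2, -0.1)
  mc <- paired_permutation_test(x13, y13, n_perm = 5000, seed = 1)
  ex2 <- paired_permutation_test(x13, y13, n_perm = 2^13)
  expect_true(ex2$exhaustive); expect_false(mc$exhaustive)
  expect_lt(abs(mc$p - ex2$p), 3 * sqrt(ex2$p * (1 - ex2$p) / 5000) + 1e-3)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(52)
  ps <- replicate(1000, paired_permutation_test(rnorm(10), rnorm(10))$p)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # super-uniformity at the conventional level
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("2x2 repeated-measures interaction equals the double-difference t and aov", {
  set.seed(53)
  n <- 14
  cells <- cbind(rnorm(n, 0.7), rnorm(n, 0.5), rnorm(n, 0.3), rnorm(n, 0.5))
  res <- rm_anova_2x2(cells)
  # algebraic identity: F = squared paired t on the double difference
  d <- (cells[, 1] - cells[, 2]) - (cells[, 3] - cells[, 4])
  expect_equal(res$F, unname(t.test(d)$statistic^2), tolerance = 1e-10)
  # independent oracle: aov with a within-subject error stratum
  df <- data.frame(v = as.vector(cells),
                   subject = factor(rep(seq_len(n), 4)),
                   interval = factor(rep(c(1, 1, 2, 2), each = n)),
                   condition = factor(rep(c(1, 2, 1, 2), each = n)))
  av <- summary(stats::aov(v ~ interval * condition +
                             Error(subject / (interval * condition)),
                           data = df))
  Fa <- av[["Error: subject:interval:condition"]][[1]]["interval:condition",
                                                       "F value"]
  expect_equal(res$F, Fa, tolerance = 1e-8)

  # additive data: no interaction
  base <- rnorm(n)
  add <- cbind(base, base + 1, base + 2, base + 3)
  expect_equal(rm_anova_2x2(add)$F, 0)
  expect_error(rm_anova_2x2(cells[, 1:3]), "ncol")
})

test_that("crossover weights yield a detectable interaction at n = 20", {
  set.seed(54)
  hits <- 0L
  for (r in 1:50) {
    cells <- cbind(rnorm(20, 0.7, 0.1), rnorm(20, 0.5, 0.1),
                   rnorm(20, 0.3, 0.1), rnorm(20, 0.5, 0.1))
    if (rm_anova_2x2(cells)$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 50, 0.8)
})

test_that("bootstrap correlations behave at the edges and cover the null", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  r1 <- bootstrap_correlation(x, x, n_rep = 200, seed = 1)
  expect_equal(r1$r, 1)
  expect_true(all(abs(r1$boot_r - 1) < 1e-8))
  expect_true(all(r1$ci >= -1 & r1$ci <= 1 & diff(r1$ci) >= 0))
  expect_error(bootstrap_correlation(1:2, 1:2), "at least 3")

  # replicate-set interface: degenerate sets reproduce the point estimate
  xb <- matrix(rep(x, 5), ncol = 5)
  yb <- matrix(rep(rev(x), 5), ncol = 5)
  r2 <- bootstrap_correlation(x, rev(x), x_boot = xb, y_boot = yb,
                              n_rep = 50, seed = 2)
  expect_true(all(abs(r2$boot_r - r2$r) < 1e-12))

  # coverage under independence, reduced scale
  set.seed(55)
  cover <- 0L
  for (r in 1:100) {
    xx <- rnorm(15); yy <- rnorm(15)
    ci <- bootstrap_correlation(xx, yy, n_rep = 400)$ci
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1L
  }
  expect_gt(cover / 100, 0.85)
})

test_that("Fisher pooling and correlation-difference test match hand oracles", {
  expect_equal(pool_correlations(c(0.5, 0.5), c(10, 20))$r, 0.5,
               tolerance = 1e-12)
  # hand-computed Fisher oracle
  zbar <- (7 * atanh(0.8) + 17 * atanh(0.2)) / 24
  expect_equal(pool_correlations(c(0.8, 0.2), c(10, 20))$r, tanh(zbar),
               tolerance = 1e-12)
  expect_error(pool_correlations(c(1, 0.5), c(10, 10)), "infinite")

  # pooled bootstrap CI machinery
  set.seed(56)
  pc <- pool_correlations(c(0.6, 0.4), c(12, 18),
                          boot_list = list(rnorm(2000, 0.6, 0.05),
                                           rnorm(2000, 0.4, 0.05)),
                          n_rep = 2000)
  expect_true(pc$ci[1] <= pc$r && pc$r <= pc$ci[2])

  expect_equal(correlation_difference_test(0.4, 30, 0.4, 50)$p, 1)
  expect_lt(correlation_difference_test(0.9, 50, 0, 50)$p, 0.001)
  a <- correlation_difference_test(0.7, 40, 0.2, 25)
  b <- correlation_difference_test(0.2, 25, 0.7, 40)
  expect_equal(a$p, b$p)
  expect_equal(a$z, -b$z)
})

test_that("slope screening utilities run on simulated cohorts", {
  co <- simulate_cohort(4, "perceptual", seed = 57,
                        design = perceptual_design(trials_per_combination = 20))
  trs <- lapply(co$subjects, `[[`, "trials")
  st <- estimation_slope_test(trs, n_perm = 2000, seed = 1)
  expect_equal(nrow(st$slopes), 4L)
  expect_true(st$test$p > 0 && st$test$p <= 1)
  sp <- spearman_screen(trs[[1]], "nochoice")
  expect_gt(sp$estimate, 0.3)   # a working observer tracks the evidence
})
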