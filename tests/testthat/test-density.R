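psy <- function(sigma = 10, delta_e = 0) list(sigma = sigma, delta_e = delta_e)

test_that("No-Choice density matches the closed-form Gaussian", {
  d <- nochoice_density(-20, 20, psy(), w1 = 0.5, w2 = 0.5, xi = 2)
  m <- density_mean(d)
  expect_equal(m, 0, tolerance = 1e-8)
  expect_equal(density_mean(d, m, 2), 0.5 * 100 + 4, tolerance = 1e-3)
  expect_equal(sum(d$density) * d$spacing, 1, tolerance = 1e-6)

  # w2 = 0, xi = 0: collapses to the interval-1 representation
  d2 <- nochoice_density(7, 99, psy(sigma = 4, delta_e = 1), 1, 0, 0)
  expect_equal(density_mean(d2), 8, tolerance = 1e-6)
  expect_equal(d2$density, dnorm(d2$grid, 8, 4), tolerance = 1e-6)

  expect_error(nochoice_density(0, 0, psy(), 0, 0, 0), "degenerate")
})

test_that("Choice density reproduces truncated-normal moments", {
  # phi1 = 0, delta = 0, D = +1, w2 = 0, xi = 0: scaled half-normal
  d <- choice_density(0, 5, 1, psy(), w1 = 0.7, w2 = 0, xi = 0)
  expect_equal(density_mean(d), 0.7 * 10 * sqrt(2 / pi), tolerance = 1e-2)
  expect_true(all(d$grid[d$density > 1e-12] >= -d$spacing))

  # sigma -> 0 with sign(phi1 + delta) = D: truncation inert, plain Gaussian
  d3 <- choice_density(10, -5, 1, psy(sigma = 1e-3), w1 = 0.6, w2 = 0.4,
                       xi = 2)
  expect_equal(density_mean(d3), 0.6 * 10 + 0.4 * -5, tolerance = 1e-3)
  m3 <- density_mean(d3)
  expect_equal(density_mean(d3, m3, 2), 4, tolerance = 1e-2)

  # negative w1 mirrors the scaled support
  dneg <- choice_density(0, 0, 1, psy(), w1 = -0.7, w2 = 0, xi = 0)
  expect_equal(density_mean(dneg), -0.7 * 10 * sqrt(2 / pi), tolerance = 1e-2)

  # near-impossible choice is flagged, density still proper
  dimp <- choice_density(-90, 0, 1, psy(sigma = 5), w1 = 0.5, w2 = 0.5,
                         xi = 1)
  expect_true(dimp$flagged)
  expect_equal(sum(dimp$density) * dimp$spacing, 1, tolerance = 1e-6)
})

test_that("Choice density matches a large Monte-Carlo simulation of the generative process", {
  set.seed(21)
  n <- 2e5
  p <- psy(sigma = 10, delta_e = 1)
  w1 <- 0.6; w2 <- 0.4; xi <- 3; phi1 <- 10; phi2 <- -10; D <- -1
  mu1 <- phi1 + p$delta_e
  x1 <- rnorm(ceiling(3 * n / pnorm(D * mu1 / p$sigma)), mu1, p$sigma)
  x1 <- x1[sign(x1) == D][1:n]
  y <- w1 * x1 + w2 * rnorm(n, phi2 + p$delta_e, p$sigma) + xi * rnorm(n)
  d <- choice_density(phi1, phi2, D, p, w1, w2, xi)
  br <- seq(min(d$grid), max(d$grid), length.out = 41)
  hh <- hist(y[y >= br[1] & y <= br[41]], breaks = br, plot = FALSE)
  cdf <- cumsum(d$density) * d$spacing
  p_bin <- diff(approx(d$grid + d$spacing / 2, cdf, xout = br,
                       yleft = 0, yright = 1)$y)
  se <- sqrt(pmax(p_bin * (1 - p_bin), 1e-12) / n)
  expect_lt(max(abs(hh$counts / n - p_bin)), max(3 * se))
})

test_that("convolution engine reproduces the analytic Gaussian convolution", {
  h <- 0.05
  g1 <- seq(-6, 6, by = h)                 # N(0, 1) component
  g2 <- seq(-4.5, 4.5, by = h)             # N(0, 0.75) kernel
  fa <- dnorm(g1, 0, 1)
  fk <- dnorm(g2, 0, 0.75)
  cv <- choicegain:::conv_open(fa, fk, h)
  grid <- (g1[1] + g2[1]) + h * (seq_along(cv) - 1)
  truth <- dnorm(grid, 0, sqrt(1 + 0.75^2))
  keep <- abs(grid) < 4                    # away from the finite-support edges
  expect_lt(max(abs(cv - truth)[keep]), 1e-6)
})

test_that("grid refinement leaves trial log-densities stable", {
  p <- psy(sigma = 10, delta_e = 0.5)
  y <- c(-8, -2, 0, 3.5, 12)
  d1 <- choice_density(5, -10, 1, p, 0.7, 0.3, 3, y_cover = range(y),
                       spacing = 0.3)
  d2 <- choice_density(5, -10, 1, p, 0.7, 0.3, 3, y_cover = range(y),
                       spacing = 0.15)
  l1 <- log(choicegain:::density_at(d1, y))
  l2 <- log(choicegain:::density_at(d2, y))
  expect_lt(max(abs(l1 - l2)), 1e-4)
})

test_that("model log-likelihood is exact on No-Choice trials and additive", {
  p <- list(sigma = 10, delta_e = 0)
  tr <- trial_frame(phi1 = c(-10, 0, 10), phi2 = c(10, 0, -10),
                    condition = "nochoice", y = c(-2, 1, 4))
  pars <- list(w1nc = 0.5, w2nc = 0.4, xi_nc = 2)
  ll <- model_loglik(tr, p, pars, "global")
  v <- 100 * (0.25 + 0.16) + 4
  ll_oracle <- sum(dnorm(tr$y, 0.5 * tr$phi1 + 0.4 * tr$phi2, sqrt(v),
                         log = TRUE))
  expect_equal(ll, ll_oracle, tolerance = 1e-6)

  # duplicating a Choice trial adds exactly its own log-density
  trc <- trial_frame(phi1 = 10, phi2 = -10, condition = "choice", D = 1,
                     y = 5)
  pars_c <- list(w1c = 0.7, w2c = 0.3, xi_c = 3)
  one <- model_loglik(trc, p, pars_c, "global")
  two <- model_loglik(rbind(trc, trc), p, pars_c, "global")
  expect_equal(two, 2 * one, tolerance = 1e-9)

  # selective path refuses undefined-consistency trials
  trs <- trial_frame(phi1 = 5, phi2 = 0, condition = "choice", D = 1, y = 1)
  trs$consistency <- "undefined"
  expect_error(model_loglik(trs, p, list(), "selective"), "undefined")
})
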