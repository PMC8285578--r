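#' Probit choice probability
#'
#' The psychometric function for the binary intermittent choice: the
#' probability of a positive choice given interval-1 evidence `phi1` is the
#' cumulative Gaussian `pnorm(delta + alpha * phi1)`, with slope `alpha`
#' (sensitivity) and horizontal shift `delta` (bias, probit units).
#'
#' @param phi1 Interval-1 evidence (signed, relative to the reference).
#' @param params A `psychfit` object or a list with `alpha` and `delta`.
#' @return Choice probabilities in (0, 1).
#' @examples
#' probit_choice_prob(10, list(alpha = 0.1, delta = 0))  # pnorm(1)
#' @export
probit_choice_prob <- function(phi1, params) {
  stats::pnorm(params$delta + params$alpha * phi1)
}

psych_negloglik <- function(par, phi1, d_pos) {
  # par = (alpha, delta); Bernoulli log-likelihood under the probit model
  p <- stats::pnorm(par[2] + par[1] * phi1)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(ifelse(d_pos, log(p), log1p(-p)))
}

#' Fit the probit psychometric function by maximum likelihood
#'
#' Maximises the Bernoulli log-likelihood of the binary choices under the
#' probit model over `(alpha, delta)` using a multi-start Nelder-Mead
#' simplex. For the numerical task, fit on binned evidence by passing the
#' bin centres as `phi1` (see [bin_numerical_evidence()]).
#'
#' The fitted object carries both parameterisations of the bias: `delta`
#' (probit units, as in the psychometric equation) and `delta_e = delta /
#' alpha` (evidence units), the latter being the additive bias of the noisy
#' evidence representation `X_i = phi_i + delta_e + N(0, sigma^2)` with
#' `sigma = 1/alpha`, used by the estimation models.
#'
#' @param trials Trial data frame with Choice rows carrying `phi1` and `D`
#'   (+1/-1), or `NULL` when `phi1`/`D` vectors are given directly.
#' @param phi1,D Optional explicit evidence / choice vectors.
#' @param starts Number of simplex starts.
#' @param alpha_cap Upper bound applied to `alpha` when the data are
#'   completely (or quasi-) separated.
#' @return An object of class `"psychfit"` with elements `alpha`, `delta`,
#'   `sigma`, `delta_e`, `loglik`, `n_trials`, `separated`, `convergence`.
#' @examples
#' sched <- generate_perceptual_schedule(seed = 2)
#' obs <- observer_params(0.1, 0, list(w1c = .7, w2c = .3, xi_c = 3,
#'                                     w1nc = .5, w2nc = .5, xi_nc = 3))
#' sim <- simulate_observer(sched, obs, seed = 2)
#' fit_psychometric(sim)
#' @export
fit_psychometric <- function(trials = NULL, phi1 = NULL, D = NULL,
                             starts = 3, alpha_cap = 10) {
  if (!is.null(trials)) {
    ch <- trials$condition == "choice" & !is.na(trials$D)
    phi1 <- trials$phi1[ch]
    D <- trials$D[ch]
  }
  stopifnot(length(phi1) == length(D), length(phi1) >= 2)
  d_pos <- D > 0
  if (length(unique(phi1)) < 2)
    stop("need at least 2 distinct phi1 levels")
  separated <- length(unique(d_pos)) < 2
  if (separated) {
    # all choices on one side: alpha unidentified, cap and centre delta
    warning("complete separation: all choices identical; alpha capped")
    alpha <- alpha_cap
    delta <- if (all(d_pos)) 5 else -5
    ll <- -psych_negloglik(c(alpha, delta), phi1, d_pos)
    fit <- list(par = c(alpha, delta), value = -ll, convergence = 0L)
  } else {
    # moment-style start: slope from the phi1 range, bias from the grand mean
    a0 <- 2 / max(diff(range(phi1)), 1)
    d0 <- stats::qnorm(pmin(pmax(mean(d_pos), 0.05), 0.95))
    fit <- simplex_multistart(c(a0, d0), psych_negloglik, starts = starts,
                              phi1 = phi1, d_pos = d_pos)
    if (fit$par[1] > alpha_cap) {
      separated <- TRUE
      warning("quasi-separation: alpha capped at ", alpha_cap)
      fit$par[1] <- alpha_cap
      fit$value <- psych_negloglik(fit$par, phi1, d_pos)
    }
    if (fit$par[1] <= 0) {
      fit$par[1] <- max(fit$par[1], 1e-6)
      fit$value <- psych_negloglik(fit$par, phi1, d_pos)
    }
  }
  alpha <- fit$par[1]; delta <- fit$par[2]
  structure(list(alpha = alpha, delta = delta,
                 sigma = 1 / alpha, delta_e = delta / alpha,
                 loglik = -fit$value, n_trials = length(phi1),
                 separated = separated, convergence = fit$convergence),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Probit psychometric fit (", x$n_trials, " choices)\n", sep = "")
  cat(sprintf("  alpha = %.4f (sigma = %.3f)\n  delta = %.4f (probit) = %.3f (evidence units)\n",
              x$alpha, x$sigma, x$delta, x$delta_e))
  cat(sprintf("  log-likelihood = %.2f%s\n", x$loglik,
              if (x$separated) "  [separated: alpha capped]" else ""))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(alpha = object$alpha, delta = object$delta)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_trials, class = "logLik")
}

#' @export
predict.psychfit <- function(object, newdata = NULL, phi1 = NULL, ...) {
  if (is.null(phi1)) phi1 <- newdata$phi1
  probit_choice_prob(phi1, object)
}
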