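# Per-component negative log-likelihoods on the optimiser scale
# (par = (w1, w2, log xi); xi on the log scale enforces positivity).
negll_nochoice <- function(par, a, b, y, sigma) {
  w1 <- par[1]; w2 <- par[2]; xi <- exp(par[3])
  v <- sigma^2 * (w1^2 + w2^2) + xi^2
  -sum(stats::dnorm(y, w1 * a + w2 * b, sqrt(v), log = TRUE))
}

negll_choice <- function(par, cells, psych) {
  -choice_cells_loglik(cells, psych, par[1], par[2], exp(par[3]))
}

# OLS of y on (phi1 + delta_e, phi2 + delta_e) without intercept: cheap,
# slightly biased (truncation), but a sound simplex start.
ols_start <- function(trials, psych) {
  a <- trials$phi1 + psych$delta_e
  b <- trials$phi2 + psych$delta_e
  co <- tryCatch(unname(stats::coef(stats::lm(trials$y ~ 0 + a + b))),
                 error = function(e) c(0.5, 0.5))
  co[!is.finite(co)] <- 0.5
  r <- trials$y - co[1] * a - co[2] * b
  xi0 <- sqrt(max(stats::var(r) - psych$sigma^2 * sum(co^2), 1))
  c(co[1], co[2], log(xi0))
}

fit_component <- function(trials, psych, truncated, starts, start = NULL) {
  if (is.null(start)) start <- ols_start(trials, psych)
  if (truncated) {
    cells <- make_choice_cells(trials)
    res <- simplex_multistart(start, negll_choice, starts = starts,
                              cells = cells, psych = psych)
  } else {
    res <- simplex_multistart(start, negll_nochoice, starts = starts,
                              a = trials$phi1 + psych$delta_e,
                              b = trials$phi2 + psych$delta_e,
                              y = trials$y, sigma = psych$sigma)
  }
  list(par = c(res$par[1], res$par[2], exp(res$par[3])),
       loglik = -res$value, converged = res$convergence == 0L,
       n_trials = nrow(trials), n_restarts = res$n_restarts)
}

#' Fit a gain model of estimation reports by maximum likelihood
#'
#' Fits either the Global Gain model (interval weights and estimation noise
#' free to differ between Choice and No-Choice trials) or the choice-based
#' Selective Gain model (interval weights and estimation noise free to
#' differ between Choice trials whose interval-2 evidence is Consistent vs
#' Inconsistent with the binary choice). The per-trial likelihood is the
#' model-predicted estimation density evaluated at the observed estimation:
#' closed-form Gaussian on No-Choice trials, and the choice-conditioned
#' truncated-Gaussian convolution density on Choice trials (see
#' [choice_density()]). The likelihood factorises over trial subsets, so
#' each 3-parameter component (w1, w2, xi) is maximised separately with a
#' restarted Nelder-Mead simplex, xi on the log scale.
#'
#' @param trials Preprocessed trial data frame (kept estimation trials). For
#'   the selective model, consistency labels are added via
#'   [label_consistency()] if absent, and consistency-undefined trials are
#'   dropped from the fit.
#' @param psych A [fit_psychometric()] fit for the same subject, supplying
#'   `sigma = 1/alpha` and the evidence-scale bias.
#' @param model `"global"` or `"selective"`.
#' @param starts Simplex starts per component.
#' @param start Optional named list/vector of starting parameter values (as
#'   in the fitted parameter vector); used by the bootstrap.
#' @param seed Optional seed (jittered starts draw from the RNG).
#' @return An object of class `"gainfit"`: fitted parameter vector
#'   (`coef()`), per-component details, total log-likelihood (`logLik()`),
#'   the data and psychometric fit (for `confint()`/`simulate()`).
#' @examples
#' \donttest{
#' sched <- generate_perceptual_schedule(seed = 3)
#' obs <- observer_params(0.1, 0, list(w1c = .7, w2c = .3, xi_c = 3,
#'                                     w1nc = .5, w2nc = .5, xi_nc = 3))
#' sim <- simulate_observer(sched, obs, seed = 3)
#' kept <- apply_exclusions(sim)$trials
#' psych <- fit_psychometric(kept)
#' fit <- fit_gain_model(kept, psych, model = "global", starts = 1)
#' coef(fit)
#' }
#' @export
fit_gain_model <- function(trials, psych, model = c("global", "selective"),
                           starts = 3, start = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  est <- trials[!trials$feedback_terminated & !is.na(trials$y), , drop = FALSE]
  comp_start <- function(nms) {
    if (is.null(start)) NULL
    else c(start[[nms[1]]], start[[nms[2]]], log(start[[nms[3]]]))
  }
  components <- list()
  if (model == "global") {
    ch <- est[est$condition == "choice", , drop = FALSE]
    nc <- est[est$condition == "nochoice", , drop = FALSE]
    if (nrow(ch) < 2 && nrow(nc) < 2) stop("no trials to fit")
    if (nrow(ch))
      components$choice <- fit_component(ch, psych, TRUE, starts,
                                         comp_start(c("w1c", "w2c", "xi_c")))
    if (nrow(nc))
      components$nochoice <- fit_component(nc, psych, FALSE, starts,
                                           comp_start(c("w1nc", "w2nc", "xi_nc")))
    par_names <- list(choice = c("w1c", "w2c", "xi_c"),
                      nochoice = c("w1nc", "w2nc", "xi_nc"))
  } else {
    if (!"consistency" %in% names(est)) est <- label_consistency(est)
    n_undef <- sum(est$consistency == "undefined", na.rm = TRUE)
    est_sel <- est[is.na(est$consistency) | est$consistency != "undefined", ,
                   drop = FALSE]
    cc <- est_sel[!is.na(est_sel$consistency) &
                    est_sel$consistency == "consistent", , drop = FALSE]
    ic <- est_sel[!is.na(est_sel$consistency) &
                    est_sel$consistency == "inconsistent", , drop = FALSE]
    nc <- est_sel[est_sel$condition == "nochoice", , drop = FALSE]
    if (nrow(cc) < 2 || nrow(ic) < 2)
      stop("selective model needs both consistent and inconsistent trials")
    components$consistent <- fit_component(cc, psych, TRUE, starts,
                                           comp_start(c("w1cc", "w2cc", "xi_cc")))
    components$inconsistent <- fit_component(ic, psych, TRUE, starts,
                                             comp_start(c("w1ic", "w2ic", "xi_ic")))
    if (nrow(nc))
      components$nochoice <- fit_component(nc, psych, FALSE, starts,
                                           comp_start(c("w1nc", "w2nc", "xi_nc")))
    par_names <- list(consistent = c("w1cc", "w2cc", "xi_cc"),
                      inconsistent = c("w1ic", "w2ic", "xi_ic"),
                      nochoice = c("w1nc", "w2nc", "xi_nc"))
    attr(components, "n_undefined_dropped") <- n_undef
    est <- est_sel
  }
  params <- numeric(0)
  for (nm in names(components)) {
    p <- components[[nm]]$par
    names(p) <- par_names[[nm]]
    params <- c(params, p)
  }
  structure(list(model = model, params = params, components = components,
                 loglik = sum(vapply(components, `[[`, 0, "loglik")),
                 converged = all(vapply(components, `[[`, TRUE, "converged")),
                 n_trials = nrow(est), psych = psych, data = est,
                 boot = NULL, call = match.call()),
            class = "gainfit")
}

#' @export
print.gainfit <- function(x, ...) {
  cat(sprintf("%s gain model fit (%d trials, log-likelihood %.2f)\n",
              if (x$model == "global") "Global" else "Selective",
              x$n_trials, x$loglik))
  print(round(x$params, 4))
  if (!x$converged) cat("  warning: at least one component did not converge\n")
  invisible(x)
}

#' @export
coef.gainfit <- function(object, ...) object$params

#' @export
logLik.gainfit <- function(object, ...) {
  structure(object$loglik, df = length(object$params),
            nobs = object$n_trials, class = "logLik")
}

#' @export
summary.gainfit <- function(object, ...) {
  out <- list(fit = object,
              effects = c(
                if (object$model == "global" &&
                    all(c("w2c", "w2nc") %in% names(object$params)))
                  c(nonselective_w2 = unname(object$params["w2nc"] -
                                               object$params["w2c"]))
                else NULL,
                if (object$model == "selective")
                  c(confirmation_bias = confirmation_bias(object))
                else NULL),
              components = object$components)
  class(out) <- "summary.gainfit"
  out
}

#' @export
print.summary.gainfit <- function(x, ...) {
  print(x$fit)
  if (length(x$effects)) {
    cat("Derived effects:\n")
    print(round(x$effects, 4))
  }
  for (nm in names(x$components)) {
    comp <- x$components[[nm]]
    cat(sprintf("  %s: n = %d, loglik = %.2f, converged = %s\n",
                nm, comp$n_trials, comp$loglik, comp$converged))
  }
  invisible(x)
}

#' Confirmation-bias index of a selective-gain fit
#'
#' The selective over-weighting of choice-consistent interval-2 evidence,
#' quantified as `w2cc - w2ic`.
#'
#' @param fit A `gainfit` with `model = "selective"`.
#' @return Scalar index (positive = confirmation bias).
#' @export
confirmation_bias <- function(fit) {
  stopifnot(inherits(fit, "gainfit"), fit$model == "selective")
  unname(fit$params["w2cc"] - fit$params["w2ic"])
}

#' Bootstrap a fitted gain model
#'
#' Resamples trials with replacement within the subject, refits each
#' replicate starting from the best-fitting parameters of the actual data
#' (one simplex start), and returns percentile confidence intervals.
#' Non-converged replicates are dropped and counted.
#'
#' @param fit A `gainfit`.
#' @param n_boot Number of bootstrap replicates (500 in the reference
#'   procedure; reduce for quick checks).
#' @param seed Integer seed.
#' @param levels Confidence levels for the percentile intervals.
#' @return A list with `draws` (replicates x parameters matrix), `ci` (a
#'   list per level of 2 x parameters matrices), `n_dropped`.
#' @export
bootstrap_fit <- function(fit, n_boot = 500, seed = NULL,
                          levels = c(0.66, 0.95)) {
  stopifnot(inherits(fit, "gainfit"))
  if (!is.null(seed)) set.seed(seed)
  start <- as.list(fit$params)
  draws <- matrix(NA_real_, n_boot, length(fit$params),
                  dimnames = list(NULL, names(fit$params)))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(fit$data), replace = TRUE)
    rep_fit <- tryCatch(
      fit_gain_model(fit$data[idx, , drop = FALSE], fit$psych,
                     model = fit$model, starts = 1, start = start),
      error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) { dropped <- dropped + 1L; next }
    draws[b, names(rep_fit$params)] <- rep_fit$params
  }
  ok <- stats::complete.cases(draws)
  ci <- lapply(levels, function(lv) {
    apply(draws[ok, , drop = FALSE], 2, stats::quantile,
          probs = c((1 - lv) / 2, 1 - (1 - lv) / 2), names = FALSE)
  })
  names(ci) <- paste0(levels * 100, "%")
  list(draws = draws[ok, , drop = FALSE], ci = ci, n_dropped = dropped)
}

#' @export
confint.gainfit <- function(object, parm, level = 0.95, n_boot = 500,
                            seed = NULL, boot = NULL, ...) {
  if (is.null(boot)) boot <- bootstrap_fit(object, n_boot, seed,
                                           levels = level)
  ci <- boot$ci[[1]]
  out <- t(ci)
  colnames(out) <- paste0(format(c((1 - level) / 2, 1 - (1 - level) / 2) * 100,
                                 trim = TRUE), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

# Truncated-normal draw on the half-line sign-matching D, by rejection with
# an analytic inverse-CDF fallback when acceptance is vanishingly small.
rtrunc_sign <- function(n, mu, sigma, D, max_tries = 50) {
  out <- rep(NA_real_, n)
  left <- seq_len(n)
  for (i in seq_len(max_tries)) {
    if (!length(left)) break
    z <- stats::rnorm(length(left), mu[left], sigma)
    ok <- sign(z) == D[left] | z == 0
    out[left[ok]] <- z[ok]
    left <- left[!ok]
  }
  if (length(left)) {
    # acceptance too low for rejection: sample the standardized tail
    # Z | Z > a directly (inverse CDF for moderate a, Robert's
    # exponential-rejection sampler for the far tail where pnorm underflows)
    mu_l <- mu[left]; d_l <- D[left]
    a <- -d_l * mu_l / sigma
    z <- numeric(length(left))
    mod <- a <= 6
    if (any(mod)) {
      u <- stats::runif(sum(mod))
      pa <- stats::pnorm(a[mod], lower.tail = FALSE)
      z[mod] <- stats::qnorm(pmin(pmax(u * pa, 1e-300), 1), lower.tail = FALSE)
    }
    if (any(!mod)) {
      aa <- a[!mod]
      zz <- rep(NA_real_, length(aa))
      todo <- seq_along(aa)
      while (length(todo)) {
        cand <- aa[todo] + stats::rexp(length(todo)) / aa[todo]
        acc <- stats::runif(length(todo)) < exp(-(cand - aa[todo])^2 / 2)
        zz[todo[acc]] <- cand[acc]
        todo <- todo[!acc]
      }
      z[!mod] <- zz
    }
    out[left] <- mu_l + d_l * sigma * z
  }
  out
}

#' Simulate estimations from a fitted gain model
#'
#' Generates synthetic estimation reports from the fitted parameters over
#' the fit's own trial schedule (or a supplied one), conditioning the
#' interval-1 representation on the recorded binary choice: `X1` is drawn
#' from `N(phi1 + delta_e, sigma^2)` by rejection until its sign matches
#' `D` (with an analytic truncated-normal fallback when the acceptance
#' probability is vanishingly small), `X2` is unconstrained, and
#' `y = w1 X1 + w2 X2 + xi * noise` with the condition-appropriate fitted
#' weights. This is the generative engine of the model-recovery control.
#'
#' @param object A `gainfit`.
#' @param nsim Number of simulated data sets.
#' @param seed Optional seed.
#' @param trials Trial schedule (defaults to the fit's data; Choice rows
#'   must carry `D`).
#' @param ... Unused.
#' @return For `nsim = 1` a trial data frame with simulated `X1`, `X2`, `y`;
#'   otherwise a list of such frames.
#' @export
simulate.gainfit <- function(object, nsim = 1, seed = NULL, trials = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trials)) trials <- object$data
  psych <- object$psych
  p <- as.list(object$params)
  one <- function() {
    tr <- trials
    n <- nrow(tr)
    mu1 <- tr$phi1 + psych$delta_e
    choice <- tr$condition == "choice"
    tr$X1 <- NA_real_
    tr$X1[!choice] <- stats::rnorm(sum(!choice), mu1[!choice], psych$sigma)
    if (any(choice))
      tr$X1[choice] <- rtrunc_sign(sum(choice), mu1[choice], psych$sigma,
                                   tr$D[choice])
    tr$X2 <- stats::rnorm(n, tr$phi2 + psych$delta_e, psych$sigma)
    w1 <- w2 <- xi <- numeric(n)
    if (object$model == "global") {
      w1[choice] <- p$w1c; w2[choice] <- p$w2c; xi[choice] <- p$xi_c
    } else {
      if (!"consistency" %in% names(tr)) tr <- label_consistency(tr)
      cc <- choice & tr$consistency == "consistent"
      ic <- choice & tr$consistency == "inconsistent"
      ud <- choice & tr$consistency == "undefined"
      w1[cc] <- p$w1cc; w2[cc] <- p$w2cc; xi[cc] <- p$xi_cc
      w1[ic] <- p$w1ic; w2[ic] <- p$w2ic; xi[ic] <- p$xi_ic
      w1[ud] <- (p$w1cc + p$w1ic) / 2
      w2[ud] <- (p$w2cc + p$w2ic) / 2
      xi[ud] <- (p$xi_cc + p$xi_ic) / 2
    }
    if (!is.null(p$w1nc)) {
      w1[!choice] <- p$w1nc; w2[!choice] <- p$w2nc; xi[!choice] <- p$xi_nc
    }
    tr$y <- w1 * tr$X1 + w2 * tr$X2 + xi * stats::rnorm(n)
    tr
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
fitted.gainfit <- function(object, ...) {
  # model-predicted mean estimation per trial (numerical mean of the
  # trial's estimation density)
  tr <- object$data
  p <- as.list(object$params)
  psych <- object$psych
  out <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (tr$condition[i] == "nochoice") {
      out[i] <- p$w1nc * (tr$phi1[i] + psych$delta_e) +
        p$w2nc * (tr$phi2[i] + psych$delta_e)
    } else {
      w <- if (object$model == "global") c(p$w1c, p$w2c, p$xi_c)
           else if (tr$consistency[i] == "consistent")
             c(p$w1cc, p$w2cc, p$xi_cc)
           else c(p$w1ic, p$w2ic, p$xi_ic)
      d <- choice_density(tr$phi1[i], tr$phi2[i], tr$D[i], psych,
                          w[1], w[2], w[3])
      out[i] <- density_mean(d)
    }
  }
  out
}

#' @export
residuals.gainfit <- function(object, ...) {
  object$data$y - fitted.gainfit(object)
}
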