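#' Generative observer parameters
#'
#' Bundles the parameters of the generative observer used to simulate
#' behaviour: the probit sensitivity `alpha` (slope of the choice
#' psychometric function), the additive evidence-scale bias `delta`
#' (interval evidence is internally represented as
#' `X_i = phi_i + delta + N(0, sigma^2)` with `sigma = 1/alpha`), and the
#' interval weights / estimation-noise SDs of the estimation model used to
#' turn the two noisy representations into a continuous report.
#'
#' On Choice trials the binary report is the deterministic sign readout of
#' the interval-1 representation, `D = sign(X1)`, so that the choice and the
#' later estimation share a single noisy representation; the long-run choice
#' probability is then the probit `pnorm(alpha * (phi1 + delta))`.
#'
#' @param alpha Probit slope, in 1/evidence-units; `sigma = 1/alpha`.
#' @param delta Evidence-scale bias (same units as `phi`).
#' @param weights For `model = "global"` a list with `w1c`, `w2c`, `xi_c`
#'   (Choice trials) and `w1nc`, `w2nc`, `xi_nc` (No-Choice trials). For
#'   `model = "selective"` a list with `w1cc`, `w2cc`, `xi_cc` (Consistent),
#'   `w1ic`, `w2ic`, `xi_ic` (Inconsistent) and `w1nc`, `w2nc`, `xi_nc`
#'   (No-Choice trials, which have no consistency split).
#' @param model Generative estimation model tag.
#' @return An object of class `"observer_params"`.
#' @examples
#' obs <- observer_params(alpha = 0.1, delta = 0,
#'                        weights = list(w1c = 0.7, w2c = 0.3, xi_c = 3,
#'                                       w1nc = 0.5, w2nc = 0.5, xi_nc = 3))
#' @export
observer_params <- function(alpha, delta = 0, weights,
                            model = c("global", "selective")) {
  model <- match.arg(model)
  stopifnot(alpha > 0)
  need <- if (model == "global")
    c("w1c", "w2c", "xi_c", "w1nc", "w2nc", "xi_nc")
  else
    c("w1cc", "w2cc", "xi_cc", "w1ic", "w2ic", "xi_ic",
      "w1nc", "w2nc", "xi_nc")
  miss <- setdiff(need, names(weights))
  if (length(miss))
    stop("weights is missing: ", paste(miss, collapse = ", "))
  xi <- unlist(weights[grep("^xi", names(weights))])
  if (any(xi < 0)) stop("estimation-noise SDs must be nonnegative")
  sigma <- 1 / alpha
  stopifnot(abs(sigma * alpha - 1) < 1e-12)
  structure(list(alpha = alpha, delta = delta, sigma = sigma,
                 weights = weights[need], model = model),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Generative observer (", x$model, " gain)\n", sep = "")
  cat("  alpha =", format(x$alpha), " delta =", format(x$delta),
      " sigma =", format(x$sigma), "\n")
  w <- unlist(x$weights)
  cat("  ", paste(names(w), format(w), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

rt_lognormal <- function(n, shift = 0.1, meanlog = -1, sdlog = 0.5) {
  shift + stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate behaviour from a generative observer
#'
#' Runs the generative model over a trial schedule: draws the noisy interval
#' representations `X_i = phi_i + delta + sigma * z_i`, reads out the binary
#' choice on Choice trials as `D = sign(X1)`, labels consistency of the
#' interval-2 evidence with the choice (`sign(phi2) == D`), and generates the
#' continuous estimation as a weighted sum of the two representations plus
#' estimation noise, using the condition-appropriate weights. Trials with
#' `phi2 == 0` have undefined consistency and are generated with the average
#' of the Consistent/Inconsistent weights under the selective model.
#'
#' Response times are drawn from a shifted log-normal and a small fraction of
#' wrong-button trials can be injected, solely so exclusion rules are
#' exercisable; no scientific claim rests on either.
#'
#' @param trials Trial data frame from a schedule generator.
#' @param obs An [observer_params()] object.
#' @param seed Optional integer seed.
#' @param p_wrong_button Probability of a wrong intermittent button press.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted log-normal RT parameters
#'   (seconds).
#' @return The trial frame with added columns `X1`, `X2`, filled `D`, `y`,
#'   response times, `consistency` and `wrong_button`.
#' @export
simulate_observer <- function(trials, obs, seed = NULL,
                              p_wrong_button = 0,
                              rt_shift = 0.1, rt_meanlog = -1, rt_sdlog = 0.5) {
  stopifnot(inherits(obs, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  tr <- trials
  tr$X1 <- tr$phi1 + obs$delta + obs$sigma * stats::rnorm(n)
  tr$X2 <- ifelse(tr$feedback_terminated, NA_real_,
                  tr$phi2 + obs$delta + obs$sigma * stats::rnorm(n))
  choice <- tr$condition == "choice"
  tr$D <- NA_real_
  tr$D[choice] <- sign(tr$X1[choice])
  tr$D[choice & tr$D == 0] <- 1  # measure-zero tie broken to +1

  tr$consistency <- NA_character_
  est_choice <- choice & !tr$feedback_terminated
  tr$consistency[est_choice] <-
    ifelse(tr$phi2[est_choice] == 0, "undefined",
           ifelse(sign(tr$phi2[est_choice]) == tr$D[est_choice],
                  "consistent", "inconsistent"))

  w <- obs$weights
  w1 <- w2 <- xi <- numeric(n)
  nc <- tr$condition == "nochoice"
  w1[nc] <- w$w1nc; w2[nc] <- w$w2nc; xi[nc] <- w$xi_nc
  if (obs$model == "global") {
    w1[choice] <- w$w1c; w2[choice] <- w$w2c; xi[choice] <- w$xi_c
  } else {
    cc <- est_choice & tr$consistency == "consistent"
    ic <- est_choice & tr$consistency == "inconsistent"
    ud <- est_choice & tr$consistency == "undefined"
    w1[cc] <- w$w1cc; w2[cc] <- w$w2cc; xi[cc] <- w$xi_cc
    w1[ic] <- w$w1ic; w2[ic] <- w$w2ic; xi[ic] <- w$xi_ic
    w1[ud] <- (w$w1cc + w$w1ic) / 2
    w2[ud] <- (w$w2cc + w$w2ic) / 2
    xi[ud] <- (w$xi_cc + w$xi_ic) / 2
  }
  est <- !tr$feedback_terminated
  tr$y <- NA_real_
  tr$y[est] <- w1[est] * tr$X1[est] + w2[est] * tr$X2[est] +
    xi[est] * stats::rnorm(sum(est))

  tr$rt_intermittent <- rt_lognormal(n, rt_shift, rt_meanlog, rt_sdlog)
  tr$rt_estimation <- ifelse(est, rt_lognormal(n, rt_shift + 0.2,
                                               rt_meanlog, rt_sdlog), NA_real_)
  tr$wrong_button <- stats::runif(n) < p_wrong_button
  tr
}

#' Simulate a cohort of observers on fresh schedules
#'
#' Convenience wrapper used throughout the validation suites: draws
#' per-subject observer parameters around stated group means, generates a
#' schedule per subject and simulates behaviour.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param task `"perceptual"` or `"numerical"`.
#' @param seed Integer seed.
#' @param alpha_mean,alpha_sd Across-subject distribution of probit slope
#'   (truncated below at 0.02).
#' @param weight_means Named numeric vector of generative weight means (names
#'   as in [observer_params()] for the chosen `model`).
#' @param weight_sd Across-subject SD of each weight.
#' @param xi_mean,xi_sd Across-subject distribution of estimation-noise SDs
#'   (truncated below at 0.5).
#' @param model Generative model tag.
#' @param design Optional task design (defaults per task).
#' @param n_trials Numerical-task schedule length (ignored for perceptual).
#' @return A list with elements `subjects` (list of per-subject lists holding
#'   `obs`, `trials`) and `params` (data frame of generative parameters).
#' @export
simulate_cohort <- function(n_subjects, task = c("perceptual", "numerical"),
                            seed = 1,
                            alpha_mean = if (task == "perceptual") 0.1 else 0.06,
                            alpha_sd = 0.015,
                            weight_means = c(w1c = 0.7, w2c = 0.3,
                                             w1nc = 0.5, w2nc = 0.5),
                            weight_sd = 0.1,
                            xi_mean = 3, xi_sd = 0.5,
                            model = c("global", "selective"),
                            design = NULL, n_trials = 4000) {
  task <- match.arg(task)
  model <- match.arg(model)
  set.seed(seed)
  if (is.null(design))
    design <- if (task == "perceptual") perceptual_design() else numerical_design()
  subjects <- vector("list", n_subjects)
  prm <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    alpha <- max(0.02, stats::rnorm(1, alpha_mean, alpha_sd))
    wm <- weight_means + stats::rnorm(length(weight_means), 0, weight_sd)
    names(wm) <- names(weight_means)
    w <- as.list(wm)
    xis <- pmax(0.5, stats::rnorm(3, xi_mean, xi_sd))
    if (model == "global") {
      w$xi_c <- xis[1]; w$xi_nc <- xis[2]
    } else {
      w$xi_cc <- xis[1]; w$xi_ic <- xis[2]; w$xi_nc <- xis[3]
    }
    obs <- observer_params(alpha, delta = 0, weights = w, model = model)
    sub_seed <- (seed * 1000L + s) %% .Machine$integer.max
    trials <- if (task == "perceptual")
      generate_perceptual_schedule(design, seed = sub_seed)
    else
      generate_numerical_schedule(n_trials, design, seed = sub_seed)
    trials <- simulate_observer(trials, obs)
    subjects[[s]] <- list(obs = obs, trials = trials)
    prm[[s]] <- data.frame(subject = s, alpha = alpha, t(unlist(w)))
  }
  list(subjects = subjects, params = do.call(rbind, prm))
}
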