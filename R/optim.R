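# Derivative-free maximisation backend: restarted Nelder-Mead with jittered
# multi-starts, plus one re-initialised run from the incumbent best (the
# re-started simplex plays the role of a subspace-searching simplex variant).
simplex_multistart <- function(par0, fn, starts = 3, jitter_sd = 0.2,
                               reltol = 1e-6, maxit = 2000, ...) {
  p <- length(par0)
  best <- NULL
  for (s in seq_len(starts)) {
    st <- if (s == 1) par0
          else par0 * (1 + stats::rnorm(p, 0, jitter_sd)) +
               stats::rnorm(p, 0, jitter_sd / 2)
    f0 <- fn(st, ...)
    if (!is.finite(f0)) next
    res <- stats::optim(st, fn, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit), ...)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("objective non-finite at every start")
  # restart from incumbent: fresh simplex around the current optimum
  res <- stats::optim(best$par, fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit), ...)
  if (res$value < best$value) best <- res
  best$n_restarts <- starts
  best
}
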