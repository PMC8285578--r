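# Shared fixtures, built in code at test time.

default_global_weights <- function(xi = 3) {
  list(w1c = 0.7, w2c = 0.3, xi_c = xi, w1nc = 0.5, w2nc = 0.5, xi_nc = xi)
}

default_observer <- function(alpha = 0.1, delta = 0, xi = 3) {
  observer_params(alpha, delta, default_global_weights(xi))
}

# A small simulated perceptual subject (reduced trial counts for unit tests).
small_subject <- function(seed = 1, trials_per_combination = 30,
                          obs = default_observer()) {
  des <- perceptual_design(trials_per_combination = trials_per_combination)
  sim <- simulate_observer(generate_perceptual_schedule(des, seed = seed),
                           obs, seed = seed)
  label_consistency(apply_exclusions(sim)$trials)
}

# Bare trial frame for handcrafted cases.
trial_frame <- function(phi1, phi2, condition = "nochoice", D = NA_real_,
                        y = NA_real_, rt = 0.5, task = "perceptual") {
  n <- max(length(phi1), length(phi2), length(condition), length(D),
           length(y))
  data.frame(trial_id = seq_len(n), task = task,
             phi1 = rep_len(phi1, n), phi2 = rep_len(phi2, n),
             condition = rep_len(condition, n),
             feedback_terminated = FALSE,
             D = rep_len(D, n), y = rep_len(y, n),
             rt_intermittent = rep_len(rt, n), rt_estimation = rep_len(rt, n),
             excluded = FALSE, exclude_reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Clean deconvolution fixture: known kernel convolved with events plus white
# noise; returns the trace and the generating kernel.
deconv_fixture <- function(seed = 1, fs = 100, dur = 60, n_events = 25,
                          noise_sd = 0.1) {
  set.seed(seed)
  n <- dur * fs
  ev_t <- sort(stats::runif(n_events, 2, dur - 10))
  kl <- seq(0, 3, by = 1 / fs)
  kern <- pupil_kernel(kl)
  x <- stats::rnorm(n, 0, noise_sd)
  for (t0 in ev_t) {
    j <- round(t0 * fs) + 1L
    idx <- j:min(j + length(kern) - 1L, n)
    x[idx] <- x[idx] + kern[seq_along(idx)]
  }
  list(trace = pupil_trace(seq(0, by = 1 / fs, length.out = n), x, fs,
                           events = data.frame(time = ev_t, type = "blink",
                                               duration = 0)),
       kernel = function(l) pupil_kernel(l))
}
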