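#' Construct a pupil trace
#'
#' A continuous pupil-diameter recording for one block of trials, with an
#' event table (blinks, saccades and task events) in seconds.
#'
#' @param time Strictly increasing sample times in seconds.
#' @param diameter Pupil diameter (arbitrary units), same length.
#' @param fs Sampling rate in Hz.
#' @param block_id Block identifier.
#' @param events Data frame with columns `time`, `type`, `duration` (and
#'   optionally `trial_id`, `condition`).
#' @return An object of class `"pupil_trace"`.
#' @export
pupil_trace <- function(time, diameter, fs, block_id = 1L,
                        events = data.frame(time = numeric(0),
                                            type = character(0),
                                            duration = numeric(0))) {
  stopifnot(length(time) == length(diameter), all(diff(time) > 0))
  if (nrow(events) &&
      (min(events$time) < time[1] || max(events$time) > time[length(time)]))
    stop("events outside the trace time span")
  structure(list(time = time, diameter = diameter, fs = fs,
                 block_id = block_id, events = events),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("Pupil trace: block %s, %.1f s at %g Hz, %d events\n",
              x$block_id, diff(range(x$time)), x$fs, nrow(x$events)))
  invisible(x)
}

#' Canonical pupil impulse response
#'
#' The standard gamma-family impulse response used for task-evoked pupil
#' modelling: `h(t) = t^n exp(-n t / t_max)`, peak-normalised to 1 at
#' `t = t_max` (defaults n = 10.1, t_max = 0.93 s).
#'
#' @param t Time in seconds (nonnegative).
#' @param n Shape parameter.
#' @param t_max Time-to-peak in seconds.
#' @return Kernel values, 0 for `t < 0`.
#' @export
pupil_kernel <- function(t, n = 10.1, t_max = 0.93) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(n * log(t[pos] / t_max) + n * (1 - t[pos] / t_max))
  out
}

pink_noise <- function(n, sd = 1) {
  # 1/f amplitude spectrum via frequency-domain shaping
  if (sd == 0) return(numeric(n))
  m <- 2^ceiling(log2(n))
  f <- c(1, seq_len(m / 2), seq(m / 2 - 1, 1))  # avoid DC blow-up
  spec <- (stats::rnorm(m) + 1i * stats::rnorm(m)) / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x * sd / stats::sd(x)
}

#' Simulate an event-locked pupil trace for a block of trials
#'
#' Test-fixture generator: lays the trials of a schedule out in time, builds
#' the trace as a sum of event-locked canonical impulse responses (amplitude
#' per event type, with the intermittent-response amplitude set by condition
#' and the estimation-response amplitude by choice-consistency), adds pink
#' noise, and inserts blink and saccade artefacts at known times. The
#' ground-truth event table (including task events with trial ids and
#' condition labels) is attached to the trace.
#'
#' @param trials Trial data frame (a simulated schedule; rows in block order).
#' @param fs Sampling rate in Hz (native recordings are 1000 Hz).
#' @param seed Optional seed.
#' @param amp_interval1 Amplitude of the interval-onset response (negative
#'   values emulate the light-driven constriction).
#' @param amp_intermittent Named amplitudes `c(choice = , nochoice = )` of
#'   the intermittent-response dilation.
#' @param amp_estimation Named amplitudes `c(consistent = , inconsistent = )`
#'   of the estimation-response dilation (the mean is used when consistency
#'   is undefined or absent).
#' @param noise_sd Pink-noise SD.
#' @param baseline Constant baseline diameter.
#' @param blink_rate Blinks per second (Poisson).
#' @param blink_duration,blink_depth Blink artefact length (s) and depth.
#' @param saccade_rate Saccades per second; artefact depth is
#'   `blink_depth / 10` over 20 ms.
#' @param iti Inter-trial interval appended after the estimation response (s).
#' @return A `pupil_trace`; attribute `"truth"` holds the noiseless trace,
#'   the kernel function parameters and the per-event amplitudes.
#' @export
simulate_pupil <- function(trials, fs = 1000, seed = NULL,
                           amp_interval1 = -0.5,
                           amp_intermittent = c(choice = 1, nochoice = 0.5),
                           amp_estimation = c(consistent = 1,
                                              inconsistent = 0.7),
                           noise_sd = 0.1, baseline = 5,
                           blink_rate = 0.02, blink_duration = 0.15,
                           blink_depth = -3, saccade_rate = 0.05,
                           iti = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  n_tr <- nrow(trials)
  rows <- vector("list", n_tr)
  t0 <- 1
  stim_dur <- 0.75; delay <- 2
  for (i in seq_len(n_tr)) {
    rt1 <- if (!is.na(trials$rt_intermittent[i])) trials$rt_intermittent[i] else 0.5
    rt2 <- if (!is.na(trials$rt_estimation[i])) trials$rt_estimation[i] else 0.7
    cond <- trials$condition[i]
    cons <- if ("consistency" %in% names(trials)) trials$consistency[i]
            else NA_character_
    amp_est <- if (!is.na(cons) && cons %in% names(amp_estimation))
      amp_estimation[[cons]] else mean(amp_estimation)
    ev <- data.frame(
      time = t0 + c(0, stim_dur + rt1, stim_dur + delay,
                    stim_dur + delay + stim_dur + rt2),
      type = c("interval1_onset", "intermittent_response",
               "interval2_onset", "estimation_response"),
      duration = 0,
      amplitude = c(amp_interval1, amp_intermittent[[cond]],
                    amp_interval1, amp_est),
      trial_id = trials$trial_id[i], condition = cond,
      consistency = cons, stringsAsFactors = FALSE)
    rows[[i]] <- ev
    t0 <- max(ev$time) + iti
  }
  events <- do.call(rbind, rows)
  total <- t0 + 4
  time <- seq(0, total, by = 1 / fs)
  n <- length(time)
  clean <- rep(baseline, n)
  kl <- seq(0, 4, by = 1 / fs)
  kern <- pupil_kernel(kl)
  for (i in seq_len(nrow(events))) {
    j0 <- round(events$time[i] * fs) + 1L
    idx <- j0:min(j0 + length(kern) - 1L, n)
    clean[idx] <- clean[idx] + events$amplitude[i] * kern[seq_along(idx)]
  }
  x <- clean + pink_noise(n, noise_sd)

  art <- function(rate, dur, depth, type) {
    k <- stats::rpois(1, rate * total)
    if (k == 0) return(NULL)
    data.frame(time = sort(stats::runif(k, 1, total - 2)), type = type,
               duration = dur, amplitude = depth, trial_id = NA, condition = NA,
               consistency = NA, stringsAsFactors = FALSE)
  }
  blinks <- art(blink_rate, blink_duration, blink_depth, "blink")
  saccades <- art(saccade_rate, 0.02, blink_depth / 10, "saccade")
  for (a in list(blinks, saccades)) {
    if (is.null(a)) next
    for (i in seq_len(nrow(a))) {
      idx <- which(time >= a$time[i] & time <= a$time[i] + a$duration[i])
      x[idx] <- x[idx] + a$amplitude[i]
      # artefact-evoked pupil response, what deconvolution must remove
      j0 <- round(a$time[i] * fs) + 1L
      jj <- j0:min(j0 + length(kern) - 1L, n)
      x[jj] <- x[jj] + 0.3 * a$amplitude[i] * kern[seq_along(jj)]
    }
  }
  events <- rbind(events, blinks, saccades)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  tr <- pupil_trace(time, x, fs, block_id = 1L, events = events)
  attr(tr, "truth") <- list(clean = clean, kernel = kern,
                            kernel_lags = kl, events = events)
  tr
}

merge_windows <- function(w) {
  # w: matrix with columns start, end; overlapping/abutting windows merged
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- list(w[1, ])
  for (i in seq_len(nrow(w) - 1L) + 1L) {
    last <- out[[length(out)]]
    if (w[i, 1] <= last[2]) out[[length(out)]] <- c(last[1], max(last[2], w[i, 2]))
    else out[[length(out) + 1L]] <- w[i, ]
  }
  do.call(rbind, out)
}

#' Interpolate blinks in a pupil trace
#'
#' Linearly interpolates the diameter across each annotated blink, from
#' `margin` seconds before blink onset to `margin` seconds after blink
#' offset (default 150 ms each side). Overlapping or abutting interpolation
#' windows are merged; windows at the trace edge are filled with the nearest
#' valid value.
#'
#' @param trace A `pupil_trace` with blink events annotated.
#' @param margin Margin in seconds around each blink.
#' @return The trace with interpolated diameter.
#' @export
interpolate_blinks <- function(trace, margin = 0.15) {
  ev <- trace$events
  bl <- ev[ev$type == "blink", , drop = FALSE]
  if (!nrow(bl)) return(trace)
  win <- merge_windows(cbind(bl$time - margin, bl$time + bl$duration + margin))
  x <- trace$diameter; tt <- trace$time; n <- length(x)
  for (i in seq_len(nrow(win))) {
    idx <- which(tt > win[i, 1] & tt < win[i, 2])
    if (!length(idx)) next
    i0 <- min(idx) - 1L; i1 <- max(idx) + 1L
    if (i0 < 1 && i1 > n) next
    if (i0 < 1) x[idx] <- x[i1]                    # edge: nearest value
    else if (i1 > n) x[idx] <- x[i0]
    else x[idx] <- x[i0] + (x[i1] - x[i0]) *
        (tt[idx] - tt[i0]) / (tt[i1] - tt[i0])
  }
  trace$diameter <- x
  trace
}

#' Remove blink- and saccade-evoked responses by deconvolution
#'
#' Estimates the pupil impulse response to blinks and saccades with a
#' finite-impulse-response (FIR) deconvolution — least squares on a design
#' of boxcar regressors covering 0 to `window` seconds post-event at `res`
#' resolution, one set per event type — and removes the predicted
#' contribution from the trace by linear regression. With no events the
#' trace is returned unchanged.
#'
#' @param trace A `pupil_trace`.
#' @param window FIR window length in seconds post-event.
#' @param res FIR bin width in seconds.
#' @param event_types Event types to deconvolve.
#' @return The residual trace; attribute `"kernels"` holds the estimated
#'   per-type impulse responses (matrix lags x types) and their lag centres.
#' @export
remove_event_responses <- function(trace, window = 6, res = 0.05,
                                   event_types = c("blink", "saccade")) {
  ev <- trace$events
  ev <- ev[ev$type %in% event_types, , drop = FALSE]
  if (!nrow(ev)) return(trace)
  fs <- trace$fs
  n <- length(trace$diameter)
  lags <- seq(0, window - res, by = res)
  nl <- length(lags)
  bin <- max(1L, round(res * fs))
  ii <- list(); jj <- list()
  col0 <- 0L
  for (ty in event_types) {
    times <- ev$time[ev$type == ty]
    if (!length(times)) { col0 <- col0 + nl; next }
    for (k in seq_len(nl)) {
      for (t0 in times) {
        s0 <- round((t0 - trace$time[1] + lags[k]) * fs) + 1L
        s1 <- min(s0 + bin - 1L, n)
        if (s0 > n) next
        ii[[length(ii) + 1L]] <- s0:s1
        jj[[length(jj) + 1L]] <- rep(col0 + k, s1 - s0 + 1L)
      }
    }
    col0 <- col0 + nl
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(n, nl * length(event_types)))
  keep <- which(Matrix::colSums(X) > 0)
  if (!length(keep)) return(trace)
  # intercept column so the event regressors need not absorb the trace mean
  Xk <- cbind(Matrix::Matrix(1, n, 1, sparse = TRUE), X[, keep, drop = FALSE])
  beta <- as.numeric(Matrix::solve(Matrix::crossprod(Xk),
                                   Matrix::crossprod(Xk, trace$diameter)))
  pred <- as.numeric(X[, keep, drop = FALSE] %*% beta[-1])
  trace$diameter <- trace$diameter - pred
  full <- numeric(nl * length(event_types)); full[keep] <- beta[-1]
  kernels <- matrix(full, nl, length(event_types),
                    dimnames = list(NULL, event_types))
  attr(trace, "kernels") <- list(lags = lags + res / 2, kernels = kernels)
  trace
}

#' Band-pass filter, z-score per block and downsample a pupil trace
#'
#' Applies the zero-phase second-order Butterworth band-pass (0.01-10 Hz by
#' default), z-scores the diameter within each block (mean 0, SD 1), and
#' decimates to `fs_out` (the band-pass low-pass acts as the anti-aliasing
#' filter; the decimation factor must be an integer).
#'
#' @param trace A `pupil_trace`.
#' @param f_lo,f_hi Band edges in Hz.
#' @param fs_out Output sampling rate in Hz (default 50).
#' @return The filtered, normalised trace at `fs_out`.
#' @export
filter_normalize <- function(trace, f_lo = 0.01, f_hi = 10, fs_out = 50) {
  fs <- trace$fs
  dec <- fs / fs_out
  if (abs(dec - round(dec)) > 1e-9) stop("fs / fs_out must be an integer")
  dec <- as.integer(round(dec))
  if (length(trace$diameter) < 4 * fs / f_hi)
    warning("block shorter than a few filter time constants")
  x <- bandpass_butter(trace$diameter, fs, f_lo, f_hi)
  ctr <- mean(x); scl <- stats::sd(x)
  x <- (x - ctr) / scl
  idx <- seq(1L, length(x), by = dec)
  out <- pupil_trace(trace$time[idx], x[idx], fs_out, trace$block_id,
                     trace$events)
  # block normalisation recorded so fixtures can be checked in raw units
  attr(out, "scale") <- scl
  attr(out, "center") <- ctr
  out
}

#' Epoch a preprocessed pupil trace and baseline-correct
#'
#' Cuts per-trial epochs locked to a task event (interval-1 onset by
#' default, or re-lockable to the estimation response), spanning `-pre`
#' seconds to at most `max_dur` seconds post-lock, truncated at the next
#' trial's interval-1 onset. Each epoch is baseline corrected by subtracting
#' the mean diameter in the 500 ms before the trial's interval-1 onset
#' (regardless of the lock event, so re-locking preserves sample values).
#'
#' @param trace A preprocessed `pupil_trace` with task events carrying
#'   `trial_id` (and optionally `condition`, `consistency`).
#' @param lock Event type to lock epochs to.
#' @param pre Seconds before the lock event to include.
#' @param max_dur Maximum epoch length post-lock in seconds.
#' @param baseline_window Window (s, relative to interval-1 onset) whose mean
#'   is subtracted.
#' @return An object of class `"pupil_epochs"`: `time` (relative to lock),
#'   `data` (trials x time matrix, NA beyond each trial's support),
#'   `trial_id`, `condition`, `consistency`, `baseline`.
#' @export
epoch_and_baseline <- function(trace, lock = "interval1_onset", pre = 0.5,
                               max_dur = 6, baseline_window = c(-0.5, 0)) {
  ev <- trace$events
  onsets <- ev[ev$type == "interval1_onset", , drop = FALSE]
  locks <- ev[ev$type == lock, , drop = FALSE]
  if (!nrow(locks)) stop("no ", lock, " events in trace")
  fs <- trace$fs
  n_pre <- round(pre * fs)
  n_post <- round(max_dur * fs)
  rel_time <- (seq_len(n_pre + n_post + 1L) - n_pre - 1L) / fs
  rows <- list(); ids <- integer(0); conds <- character(0)
  cons <- character(0); bases <- numeric(0)
  for (i in seq_len(nrow(locks))) {
    id <- locks$trial_id[i]
    on <- onsets$time[match(id, onsets$trial_id)]
    if (is.na(on)) next
    # baseline: mean diameter in the window before interval-1 onset,
    # indexed in samples so the corrected pre-onset window averages to 0
    i_on <- which.min(abs(trace$time - on))
    bidx <- i_on + seq(round(baseline_window[1] * fs),
                       round(baseline_window[2] * fs) - 1L)
    bidx <- bidx[bidx >= 1 & bidx <= length(trace$time)]
    if (!length(bidx)) next
    base <- mean(trace$diameter[bidx])
    t_lock <- locks$time[i]
    nxt <- onsets$time[onsets$time > on + 1e-9]
    t_end <- min(t_lock + max_dur, if (length(nxt)) min(nxt) else Inf)
    i0 <- which.min(abs(trace$time - t_lock))
    idx <- (i0 - n_pre):(i0 + n_post)
    valid <- idx >= 1 & idx <= length(trace$time)
    row <- rep(NA_real_, length(rel_time))
    row[valid] <- trace$diameter[idx[valid]] - base
    row[rel_time > (t_end - t_lock) + 1e-9] <- NA
    rows[[length(rows) + 1L]] <- row
    ids <- c(ids, id); bases <- c(bases, base)
    conds <- c(conds, if ("condition" %in% names(locks))
      as.character(locks$condition[i]) else NA_character_)
    cons <- c(cons, if ("consistency" %in% names(locks))
      as.character(locks$consistency[i]) else NA_character_)
  }
  if (!length(rows)) stop("no epochs could be formed")
  structure(list(time = rel_time, data = do.call(rbind, rows),
                 trial_id = ids, condition = conds, consistency = cons,
                 baseline = bases, lock = lock, fs = fs),
            class = "pupil_epochs")
}

#' @export
print.pupil_epochs <- function(x, ...) {
  cat(sprintf("Pupil epochs: %d trials x %d samples at %g Hz, locked to %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$lock))
  invisible(x)
}

#' Condition-averaged pupil time courses
#'
#' Averages epochs within each label (trial mean), reporting the mean, the
#' standard error and the per-time trial count; ragged epochs are averaged
#' over the common support. For group-level curves, feed the per-subject
#' means into this function again with one "epoch" per subject.
#'
#' @param epochs A `pupil_epochs` object or a plain trials x time matrix.
#' @param labels Label per epoch (defaults to the epochs' condition).
#' @return A list per label with `mean`, `se`, `n` (vectors over time), plus
#'   the common `time` axis.
#' @export
condition_average <- function(epochs, labels = NULL) {
  if (inherits(epochs, "pupil_epochs")) {
    m <- epochs$data
    if (is.null(labels)) labels <- epochs$condition
    tt <- epochs$time
  } else {
    m <- as.matrix(epochs)
    tt <- seq_len(ncol(m))
  }
  stopifnot(length(labels) == nrow(m))
  out <- list(time = tt, labels = sort(unique(stats::na.omit(labels))))
  for (lb in out$labels) {
    sub <- m[which(labels == lb), , drop = FALSE]
    n <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 2, stats::sd, na.rm = TRUE)
    mu[n == 0] <- NA; sdv[n < 2] <- NA
    out[[lb]] <- list(mean = mu, se = sdv / sqrt(pmax(n, 1)), n = n)
  }
  out
}

#' Cluster-based permutation test between paired pupil time courses
#'
#' Compares two conditions' subject-level mean time courses: a pointwise
#' paired t statistic is computed, contiguous runs of |t| above the
#' two-sided alpha = 0.05 t criterion form clusters with mass equal to the
#' sum of t inside, and the null distribution of the maximum absolute
#' cluster mass is built by flipping each subject's condition labels
#' (sign-flipping the paired difference curves). Cluster p-values are the
#' fraction of permutations with a larger maximum mass (add-one smoothed).
#'
#' @param A,B Subjects x time matrices, paired by row.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param alpha Pointwise cluster-forming threshold.
#' @return A list with `t` (pointwise statistics), `threshold`, `clusters`
#'   (data frame: start, end indices, mass, p), `n_perm`.
#' @export
cluster_permutation_timecourse <- function(A, B, n_perm = 1000, seed = NULL,
                                           alpha = 0.05) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  if (!is.null(seed)) set.seed(seed)
  d <- A - B
  ns <- nrow(d); nt <- ncol(d)
  thr <- stats::qt(1 - alpha / 2, ns - 1)
  q <- colSums(d^2)                       # invariant under sign flips
  tstat_from_mean <- function(m) {
    v <- (q - ns * m^2) / (ns - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / ns)
  }
  find_clusters <- function(tv) {
    above <- abs(tv) > thr & is.finite(tv)
    if (!any(above)) return(NULL)
    state <- ifelse(above, sign(tv), 0)   # runs split at sign changes
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values != 0)
    do.call(rbind, lapply(keep, function(k) {
      idx <- starts[k]:ends[k]
      data.frame(start = starts[k], end = ends[k], mass = sum(tv[idx]))
    }))
  }
  tobs <- tstat_from_mean(colMeans(d))
  clusters <- find_clusters(tobs)
  signs <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), n_perm, ns)
  perm_means <- signs %*% d / ns
  max_mass <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    cp <- find_clusters(tstat_from_mean(perm_means[p, ]))
    max_mass[p] <- if (is.null(cp)) 0 else max(abs(cp$mass))
  }
  if (!is.null(clusters)) {
    clusters$p <- vapply(clusters$mass, function(m)
      (sum(max_mass >= abs(m)) + 1) / (n_perm + 1), 0)
    rownames(clusters) <- NULL
  }
  list(t = tobs, threshold = thr, clusters = clusters, n_perm = n_perm)
}

#' Scalar pupil response in a time window
#'
#' Mean diameter within a configured window of each epoch (the windowed
#' task-evoked response used for across-subject correlations with model
#' weights), optionally averaged per condition label.
#'
#' @param epochs A `pupil_epochs` object.
#' @param window Two-element window in seconds relative to the lock event.
#' @param labels Optional label per epoch; if given, a named vector of
#'   per-label means is returned.
#' @return Per-epoch means, or per-label means.
#' @export
scalar_response <- function(epochs, window, labels = NULL) {
  stopifnot(inherits(epochs, "pupil_epochs"), length(window) == 2)
  if (window[2] <= window[1]) stop("window must have positive length")
  idx <- which(epochs$time >= window[1] & epochs$time <= window[2])
  if (!length(idx)) stop("window outside epoch support")
  per <- rowMeans(epochs$data[, idx, drop = FALSE], na.rm = TRUE)
  if (is.null(labels)) return(per)
  tapply(per, labels, mean, na.rm = TRUE)
}
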