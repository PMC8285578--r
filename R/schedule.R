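new_trial_frame <- function(n) {
  data.frame(trial_id = integer(n),
             task = character(n),
             phi1 = numeric(n), phi2 = numeric(n),
             condition = character(n),
             feedback_terminated = logical(n),
             D = rep(NA_real_, n),
             y = rep(NA_real_, n),
             rt_intermittent = rep(NA_real_, n),
             rt_estimation = rep(NA_real_, n),
             excluded = logical(n),
             exclude_reason = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

#' Generate a perceptual-task trial schedule
#'
#' Builds the full balanced schedule of the perceptual task: every retained
#' `(phi1, phi2)` direction combination appears `trials_per_combination` times
#' as an estimation trial, split between Choice and No-Choice conditions per
#' `choice_fraction` (45/45 under the defaults). Optionally the
#' feedback-terminated Choice trials (those ending after the binary choice,
#' with no second interval and no estimation) are appended, one per Choice
#' estimation trial, matching the half/half split of Choice trials.
#'
#' @param design A [perceptual_design()].
#' @param seed Integer seed controlling the trial shuffle.
#' @param include_feedback_trials Append feedback-terminated Choice trials?
#' @return A trial data frame (one row per trial) with columns `trial_id`,
#'   `task`, `phi1`, `phi2`, `condition`, `feedback_terminated`, `D`, `y`,
#'   `rt_intermittent`, `rt_estimation`, `excluded`, `exclude_reason`.
#' @export
generate_perceptual_schedule <- function(design = perceptual_design(),
                                         seed = NULL,
                                         include_feedback_trials = FALSE) {
  stopifnot(inherits(design, "perceptual_design"))
  combos <- design_combinations(design)
  n_est <- design$trials_per_combination
  n_choice <- as.integer(round(n_est * design$choice_fraction))
  per_combo <- function(i) {
    tr <- new_trial_frame(n_est)
    tr$task <- "perceptual"
    tr$phi1 <- combos$phi1[i]; tr$phi2 <- combos$phi2[i]
    tr$condition <- rep(c("choice", "nochoice"), c(n_choice, n_est - n_choice))
    tr
  }
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), per_combo))
  if (include_feedback_trials) {
    fb <- out[out$condition == "choice", , drop = FALSE]
    fb$feedback_terminated <- TRUE
    out <- rbind(out, fb)
  }
  if (!is.null(seed)) {
    set.seed(seed)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  }
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Draw one interval's number sequence
#'
#' Draws `samples_per_interval` integers from the triangular distribution with
#' the requested mean, subject to the task constraint that two identical
#' numbers are never shown in succession (an offending draw is replaced by a
#' draw from the same distribution with the previous value removed and the
#' weights renormalised).
#'
#' @param mean_id One of `design$distribution_means`.
#' @param design A [numerical_design()].
#' @param seed Optional integer seed.
#' @return Integer vector of length `design$samples_per_interval`.
#' @export
sample_interval_numbers <- function(mean_id, design = numerical_design(),
                                    seed = NULL) {
  stopifnot(inherits(design, "numerical_design"))
  if (!mean_id %in% design$distribution_means)
    stop("mean_id must be one of the design's distribution means")
  if (!is.null(seed)) set.seed(seed)
  w <- triangular_weights(mean_id, design$sample_range)
  n <- design$samples_per_interval
  out <- integer(n)
  out[1] <- sample(w$support, 1L, prob = w$prob)
  for (i in seq_len(n - 1L) + 1L) {
    keep <- w$support != out[i - 1L]
    out[i] <- sample(w$support[keep], 1L, prob = w$prob[keep])
  }
  out
}

#' Generate a numerical-task trial schedule
#'
#' Allocates trial types deterministically in the stated fractions (50%
#' feedback-terminated Choice, 25% Choice estimation, 25% No-Choice
#' estimation under the defaults), draws the interval-1 generating mean from
#' the restricted subset and the interval-2 mean from all four distributions,
#' and samples both number sequences. Evidence is coded as
#' `phi_i = mean(samples_i) - reference`.
#'
#' @param n_trials Total number of trials (all types).
#' @param design A [numerical_design()].
#' @param seed Integer seed.
#' @return A trial data frame as in [generate_perceptual_schedule()], plus
#'   list columns `samples1`, `samples2` and columns `mean1_id`, `mean2_id`
#'   (the generating distribution means).
#' @export
generate_numerical_schedule <- function(n_trials, design = numerical_design(),
                                        seed = NULL) {
  stopifnot(inherits(design, "numerical_design"), n_trials > 0)
  if (!is.null(seed)) set.seed(seed)
  fr <- design$trial_type_fractions
  n_fb <- round(n_trials * fr[["choice_feedback"]])
  n_ce <- round(n_trials * fr[["choice_estimation"]])
  n_ne <- n_trials - n_fb - n_ce
  type <- rep(c("choice_feedback", "choice_estimation", "nochoice_estimation"),
              c(n_fb, n_ce, n_ne))
  type <- sample(type)

  out <- new_trial_frame(n_trials)
  out$task <- "numerical"
  out$condition <- ifelse(type == "nochoice_estimation", "nochoice", "choice")
  out$feedback_terminated <- type == "choice_feedback"
  out$mean1_id <- sample(design$interval1_means, n_trials, replace = TRUE)
  out$mean2_id <- sample(design$distribution_means, n_trials, replace = TRUE)
  out$samples1 <- lapply(out$mean1_id, sample_interval_numbers, design = design)
  out$samples2 <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    if (!out$feedback_terminated[i])
      out$samples2[[i]] <- sample_interval_numbers(out$mean2_id[i], design)
  }
  out$phi1 <- vapply(out$samples1, mean, 0) - design$reference
  out$phi2 <- vapply(out$samples2,
                     function(s) if (is.null(s)) NA_real_ else mean(s), 0) -
    design$reference
  out$trial_id <- seq_len(n_trials)
  out
}
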