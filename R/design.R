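#' Perceptual task design
#'
#' Describes the two-interval random-dot motion task: on each trial two motion
#' stimuli are shown whose directions (relative to a reference line) are drawn
#' from a small set of signed angles, an intermittent response (binary
#' direction choice, or a choice-independent button press) is made after the
#' first interval, and a continuous estimate of the mean direction is reported
#' at the end.
#'
#' @param direction_levels Signed directions in degrees relative to the
#'   reference. Must be symmetric about 0.
#' @param excluded_pairs List of `c(phi1, phi2)` combinations never presented
#'   (by default the two maximally conflicting ones).
#' @param trials_per_combination Number of estimation trials per retained
#'   `(phi1, phi2)` combination.
#' @param choice_fraction Fraction of estimation trials that are Choice trials
#'   (the rest are No-Choice trials).
#' @param coherence Motion coherence, metadata only.
#' @return An object of class `"perceptual_design"`.
#' @examples
#' d <- perceptual_design()
#' nrow(design_combinations(d))  # 23
#' @export
perceptual_design <- function(direction_levels = c(-20, -10, 0, 10, 20),
                              excluded_pairs = list(c(-20, 20), c(20, -20)),
                              trials_per_combination = 90,
                              choice_fraction = 0.5,
                              coherence = NULL) {
  direction_levels <- sort(direction_levels)
  if (!isTRUE(all.equal(direction_levels, -rev(direction_levels))))
    stop("direction_levels must be symmetric about 0")
  for (p in excluded_pairs) {
    if (length(p) != 2L || !all(p %in% direction_levels))
      stop("excluded pair (", paste(p, collapse = ", "),
           ") is not on the direction-level grid")
  }
  n_choice <- trials_per_combination * choice_fraction
  if (abs(n_choice - round(n_choice)) > 1e-9)
    stop("trials_per_combination * choice_fraction must be an integer")
  structure(list(direction_levels = direction_levels,
                 excluded_pairs = excluded_pairs,
                 trials_per_combination = as.integer(trials_per_combination),
                 choice_fraction = choice_fraction,
                 coherence = coherence),
            class = "perceptual_design")
}

#' Retained direction combinations of a perceptual design
#'
#' @param design A [perceptual_design()].
#' @return A data frame with columns `phi1`, `phi2`, one row per retained
#'   combination (23 for the default design).
#' @export
design_combinations <- function(design) {
  stopifnot(inherits(design, "perceptual_design"))
  g <- expand.grid(phi1 = design$direction_levels,
                   phi2 = design$direction_levels,
                   KEEP.OUT.ATTRS = FALSE)
  drop <- rep(FALSE, nrow(g))
  for (p in design$excluded_pairs)
    drop <- drop | (g$phi1 == p[1] & g$phi2 == p[2])
  g <- g[!drop, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Numerical task design
#'
#' Describes the number-integration task: two streams of eight integers, each
#' stream drawn from one of four triangular distributions; the observer
#' compares the first-stream mean against a reference (50), and on estimation
#' trials reports the mean of all sixteen numbers.
#'
#' @param distribution_means Means of the four generating distributions.
#' @param sample_range Inclusive integer support of the samples.
#' @param samples_per_interval Numbers shown per interval.
#' @param interval1_means Subset of `distribution_means` allowed in interval 1.
#' @param trial_type_fractions Named fractions (summing to 1) of
#'   `choice_feedback` (binary choice then feedback, no estimation),
#'   `choice_estimation` and `nochoice_estimation` trials.
#' @param reference Comparison reference; evidence is coded as mean - reference.
#' @return An object of class `"numerical_design"`.
#' @export
numerical_design <- function(distribution_means = c(40, 46, 54, 60),
                             sample_range = c(10, 90),
                             samples_per_interval = 8,
                             interval1_means = c(46, 54),
                             trial_type_fractions = c(choice_feedback = 0.5,
                                                      choice_estimation = 0.25,
                                                      nochoice_estimation = 0.25),
                             reference = 50) {
  if (!all(interval1_means %in% distribution_means))
    stop("interval1_means must be a subset of distribution_means")
  if (abs(sum(trial_type_fractions) - 1) > 1e-9)
    stop("trial_type_fractions must sum to 1")
  need <- c("choice_feedback", "choice_estimation", "nochoice_estimation")
  if (!all(need %in% names(trial_type_fractions)))
    stop("trial_type_fractions must be named ",
         paste(need, collapse = ", "))
  lo <- sample_range[1]; hi <- sample_range[2]
  for (m in distribution_means)
    if (m <= lo || m >= hi)
      stop("distribution mean ", m, " unreachable on support [", lo, ", ", hi, "]")
  structure(list(distribution_means = distribution_means,
                 sample_range = as.integer(sample_range),
                 samples_per_interval = as.integer(samples_per_interval),
                 interval1_means = interval1_means,
                 trial_type_fractions = trial_type_fractions[need],
                 reference = reference),
            class = "numerical_design")
}

#' Discrete triangular sampling weights with a stated mean
#'
#' The task generator draws integers from a triangular ("skewed-density")
#' distribution on a fixed support whose expectation must equal a stated mean.
#' A triangular density is fully determined on a fixed support by its apex;
#' the apex is therefore solved numerically so that the discrete expectation
#' over the integer support equals `mean`.
#'
#' @param mean Target expectation.
#' @param range Inclusive integer support, default `c(10, 90)`.
#' @return A list with `support` (integer values), `prob` (sampling weights),
#'   and `apex` (the solved apex location).
#' @examples
#' w <- triangular_weights(60)
#' sum(w$support * w$prob)  # 60
#' @export
triangular_weights <- function(mean, range = c(10, 90)) {
  lo <- range[1]; hi <- range[2]
  if (mean <= lo || mean >= hi) stop("mean outside open support interval")
  support <- seq.int(lo, hi)
  tri <- function(x, apex) {
    up <- x <= apex
    d <- numeric(length(x))
    # height chosen so the continuous density integrates to 1; only the shape
    # matters, the discrete weights are renormalised below
    d[up] <- (x[up] - lo) / max(apex - lo, .Machine$double.eps)
    d[!up] <- (hi - x[!up]) / max(hi - apex, .Machine$double.eps)
    pmax(d, 0)
  }
  mean_at <- function(apex) {
    w <- tri(support, apex)
    if (sum(w) == 0) return(NA_real_)
    sum(support * w) / sum(w)
  }
  f <- function(apex) mean_at(apex) - mean
  apex <- stats::uniroot(f, lower = lo + 1e-6, upper = hi - 1e-6,
                         tol = 1e-10)$root
  w <- tri(support, apex)
  list(support = support, prob = w / sum(w), apex = apex)
}
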