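#' Apply trial-exclusion rules
#'
#' Flags and removes, in this order of reporting: trials with a wrong
#' intermittent button press, trials with an intermittent response time
#' strictly below 200 ms, and estimation outliers — trials whose estimation
#' `y` lies above `Q3 + 1.5 IQR` or below `Q1 - 1.5 IQR` of the subject's
#' estimation distribution (pooled across conditions). Feedback-terminated
#' trials are excluded from analysis tables as a matter of course since they
#' carry no estimation. Nothing is silently deleted: the full table with
#' `excluded` flags and reasons is returned alongside the kept subset.
#'
#' @param trials Trial data frame with `rt_intermittent` and `y` (and
#'   optionally `wrong_button`).
#' @param rt_min Response-time cut in seconds (strict inequality).
#' @param iqr_mult Fence multiplier for the estimation outlier rule.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (recorded option; default 7, R's default interpolation).
#' @return A list with `trials` (kept rows), `all` (every row, flagged) and
#'   `report` (an `exclusion_report`: counts per rule and overall fraction).
#' @examples
#' sched <- generate_perceptual_schedule(seed = 1)
#' obs <- observer_params(0.1, 0, list(w1c = .7, w2c = .3, xi_c = 3,
#'                                     w1nc = .5, w2nc = .5, xi_nc = 3))
#' sim <- simulate_observer(sched, obs, seed = 1)
#' apply_exclusions(sim)$report
#' @export
apply_exclusions <- function(trials, rt_min = 0.2, iqr_mult = 1.5,
                             quantile_type = 7) {
  tr <- trials
  est <- !tr$feedback_terminated
  tr$excluded <- FALSE
  tr$exclude_reason <- NA_character_
  tr$excluded[!est] <- TRUE
  tr$exclude_reason[!est] <- "feedback_terminated"

  wrong <- if ("wrong_button" %in% names(tr)) tr$wrong_button & est
            else rep(FALSE, nrow(tr))
  tr$excluded[wrong] <- TRUE
  tr$exclude_reason[wrong] <- "wrong_button"

  fast <- est & !wrong & !is.na(tr$rt_intermittent) & tr$rt_intermittent < rt_min
  tr$excluded[fast] <- TRUE
  tr$exclude_reason[fast] <- "fast_rt"

  cand <- est & !tr$excluded & !is.na(tr$y)
  n_out <- 0L
  if (sum(cand) >= 4) {
    q <- stats::quantile(tr$y[cand], c(0.25, 0.75), type = quantile_type,
                         names = FALSE)
    fence <- iqr_mult * (q[2] - q[1])
    out <- cand & (tr$y > q[2] + fence | tr$y < q[1] - fence)
    tr$excluded[out] <- TRUE
    tr$exclude_reason[out] <- "outlier"
    n_out <- sum(out)
  } else if (sum(cand) > 0) {
    warning("fewer than 4 estimation trials; IQR outlier rule skipped")
  }

  n_est <- sum(est)
  report <- structure(list(n_total = n_est,
                           n_wrong_button = sum(wrong),
                           n_fast_rt = sum(fast),
                           n_outlier = n_out,
                           fraction_excluded =
                             if (n_est) sum(tr$excluded & est) / n_est else 0),
                      class = "exclusion_report")
  list(trials = tr[!tr$excluded, , drop = FALSE], all = tr, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Trial exclusions (", x$n_total, " estimation trials)\n", sep = "")
  cat(sprintf("  wrong button: %d\n  fast RT (<200 ms): %d\n  outliers (1.5 IQR): %d\n",
              x$n_wrong_button, x$n_fast_rt, x$n_outlier))
  cat(sprintf("  fraction excluded: %.3f\n", x$fraction_excluded))
  invisible(x)
}

#' Label choice-consistency of interval-2 evidence
#'
#' A Choice trial is Consistent when the sign of the interval-2 evidence
#' matches the binary choice (`sign(phi2) == D`), Inconsistent when it is
#' opposite, and undefined when `phi2 == 0` (perceptual task: 0 deg;
#' numerical task: interval-2 mean exactly at the reference). Undefined
#' trials are dropped from selective-gain fits downstream.
#'
#' @param trials Trial data frame; Choice rows must have `D`.
#' @return `trials` with a `consistency` column (`NA` on No-Choice trials).
#' @export
label_consistency <- function(trials) {
  tr <- trials
  choice <- tr$condition == "choice" & !tr$feedback_terminated
  if (any(choice & is.na(tr$D)))
    stop("Choice trials without a recorded binary choice D")
  tr$consistency <- NA_character_
  tr$consistency[choice] <-
    ifelse(tr$phi2[choice] == 0, "undefined",
           ifelse(sign(tr$phi2[choice]) == tr$D[choice],
                  "consistent", "inconsistent"))
  tr
}

#' Bin numerical-task interval-1 evidence
#'
#' Bins the interval-1 evidence (`phi1`, sample mean minus reference) into
#' `n_bins` bins, half on each side of 0, for psychometric fitting; also adds
#' binarized evidence columns (`phi1_sign`, `phi2_sign`, the sign of the mean
#' relative to the reference) used by the ROC analysis.
#'
#' @param trials Numerical-task trial data frame.
#' @param n_bins Total bin count (even; default 6, three per side).
#' @param scheme `"width"` for equal-width bins within each side (default) or
#'   `"count"` for equal-count bins within each side.
#' @return `trials` with added columns `phi1_bin` (integer bin index,
#'   negative side first), `phi1_bin_center` (mean evidence in the bin) and
#'   `phi1_sign`, `phi2_sign`.
#' @export
bin_numerical_evidence <- function(trials, n_bins = 6,
                                   scheme = c("width", "count")) {
  scheme <- match.arg(scheme)
  stopifnot(n_bins %% 2 == 0)
  tr <- trials
  half <- n_bins / 2
  neg <- !is.na(tr$phi1) & tr$phi1 < 0
  pos <- !is.na(tr$phi1) & tr$phi1 >= 0
  if (!any(neg) || !any(pos))
    stop("evidence must be present on both sides of the reference")
  side_bins <- function(x, k) {
    if (scheme == "width") {
      br <- seq(min(x) - 1e-9, max(x) + 1e-9, length.out = k + 1)
    } else {
      br <- stats::quantile(x, probs = seq(0, 1, length.out = k + 1),
                            names = FALSE)
      br[1] <- br[1] - 1e-9; br[k + 1] <- br[k + 1] + 1e-9
      br <- cummax(br + seq(0, 1e-12, length.out = k + 1))  # ensure increasing
    }
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  tr$phi1_bin <- NA_integer_
  tr$phi1_bin[neg] <- side_bins(tr$phi1[neg], half)
  tr$phi1_bin[pos] <- side_bins(tr$phi1[pos], half) + half
  centers <- tapply(tr$phi1, tr$phi1_bin, mean)
  tr$phi1_bin_center <- as.numeric(centers[as.character(tr$phi1_bin)])
  tr$phi1_sign <- sign(tr$phi1)
  tr$phi2_sign <- sign(tr$phi2)
  tr
}
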