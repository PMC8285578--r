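#' ROC separability index between two estimation samples
#'
#' The probability that a random draw from the higher-evidence ("signal")
#' sample exceeds a random draw from the lower-evidence sample, ties counted
#' one-half (the Mann-Whitney construction of the area under the ROC curve).
#' 0.5 means the distributions are identical in this sense; 1 means
#' completely separable with the signal sample above.
#'
#' @param samples_low Estimations from the lower-evidence trials.
#' @param samples_high Estimations from the higher-evidence trials.
#' @return Index in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 2, 3), c(1, 2, 3))  # 0.5
#' roc_auc(c(1, 2), c(5, 6))        # 1
#' @export
roc_auc <- function(samples_low, samples_high) {
  if (!length(samples_low) || !length(samples_high))
    stop("both samples must be non-empty")
  nl <- as.numeric(length(samples_low)); nh <- as.numeric(length(samples_high))
  r <- rank(c(samples_low, samples_high))           # midranks handle ties
  (sum(r[nl + seq_len(nh)]) - nh * (nh + 1) / 2) / (nl * nh)
}

#' Trial-count-weighted ROC sensitivity to interval-2 evidence
#'
#' Model-free sensitivity of the estimations to the evidence in interval 2,
#' within one condition of one subject. Perceptual task: trials are sorted by
#' `phi1`; for each `phi1` level, ROC indices are computed between the
#' estimation distributions of each adjacent pair of `phi2` levels (-20 vs
#' -10, -10 vs 0, 0 vs 10, 10 vs 20 under the default design, higher `phi2`
#' as the signal class), averaged within `phi1` weighted by the number of
#' trials entering each comparison, then averaged (unweighted) across `phi1`.
#' Numerical task: interval evidence is binarized at the reference (sign of
#' the sample mean minus 50) and the same logic applied to the single pair
#' per `phi1` bin; a 4-bin variant (two equal-count bins per side, adjacent
#' pairs) is available.
#'
#' @param trials Preprocessed trial data frame of one subject.
#' @param condition `"choice"` or `"nochoice"` (rows are filtered to it).
#' @param task Task tag; defaults to the `task` column.
#' @param n_bins Numerical-task bins per interval (2 or 4).
#' @return An object of class `"roc_result"`: `overall` index, `per_phi1`
#'   data frame (level, weighted index, n), `n_trials`, `skipped` (pairs with
#'   an empty cell).
#' @export
weighted_roc_index <- function(trials, condition = c("choice", "nochoice"),
                               task = NULL, n_bins = 2) {
  condition <- match.arg(condition)
  if (is.null(task)) task <- trials$task[1]
  tr <- trials[trials$condition == condition & !trials$feedback_terminated &
                 !is.na(trials$y), , drop = FALSE]
  if (!nrow(tr)) stop("no estimation trials in condition ", condition)

  if (task == "perceptual") {
    g1 <- tr$phi1
    g2 <- tr$phi2
    lev2 <- sort(unique(trials$phi2[!is.na(trials$phi2)]))
  } else {
    stopifnot(n_bins %in% c(2, 4))
    bin_side <- function(x, k) {
      # k bins per side of the reference, equal-count within side
      s <- ifelse(x < 0, 0L, k)
      if (k == 1) return(ifelse(x < 0, 1L, 2L))
      out <- integer(length(x))
      for (side in c(TRUE, FALSE)) {
        idx <- if (side) x < 0 else x >= 0
        if (!any(idx)) next
        br <- stats::quantile(x[idx], probs = seq(0, 1, length.out = k + 1),
                              names = FALSE)
        br[1] <- br[1] - 1e-9; br[k + 1] <- br[k + 1] + 1e-9
        out[idx] <- findInterval(x[idx], br, all.inside = TRUE) +
          if (side) 0L else k
      }
      out
    }
    k <- n_bins / 2
    g1 <- bin_side(tr$phi1, k)
    g2 <- bin_side(tr$phi2, k)
    lev2 <- sort(unique(g2))
  }

  per <- list(); skipped <- 0L
  for (l1 in sort(unique(g1))) {
    sub <- g1 == l1
    idx <- numeric(0); wt <- numeric(0)
    for (j in seq_len(length(lev2) - 1L)) {
      lo <- tr$y[sub & g2 == lev2[j]]
      hi <- tr$y[sub & g2 == lev2[j + 1L]]
      if (!length(lo) || !length(hi)) { skipped <- skipped + 1L; next }
      idx <- c(idx, roc_auc(lo, hi))
      wt <- c(wt, length(lo) + length(hi))
    }
    if (!length(idx)) next
    per[[length(per) + 1L]] <-
      data.frame(phi1 = l1, index = sum(idx * wt) / sum(wt), n = sum(wt))
  }
  if (!length(per)) stop("no phi2 pair had trials on both sides")
  per <- do.call(rbind, per)
  structure(list(overall = mean(per$index), per_phi1 = per,
                 condition = condition, task = task,
                 n_trials = nrow(tr), skipped = skipped),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC sensitivity to interval-2 evidence (%s task, %s trials)\n",
              x$task, x$condition))
  cat(sprintf("  overall index = %.4f over %d trials (%d pairs skipped)\n",
              x$overall, x$n_trials, x$skipped))
  invisible(x)
}
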