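#' Paired sign-flip permutation test
#'
#' Tests whether the mean paired difference between two conditions differs
#' from zero by randomly switching the condition labels of individual
#' observations (equivalently, flipping the signs of the paired differences).
#' The statistic is `mean(x - y)`; the two-sided p-value is the fraction of
#' permutations whose absolute statistic is at least the observed one. When
#' the number of unique sign patterns `2^n` is within the permutation
#' budget, the test switches to exhaustive enumeration (e.g. 1,024 patterns
#' at n = 10); otherwise Monte-Carlo sampling with add-one smoothing is used
#' so p is never exactly 0.
#'
#' @param x,y Equal-length paired vectors.
#' @param n_perm Permutation budget (100,000 in the reference procedure).
#' @param seed Optional seed (Monte-Carlo path only).
#' @return An object of class `"perm_test"`: `statistic`, `p`, `n_perm`,
#'   `exhaustive`.
#' @examples
#' paired_permutation_test(rnorm(10, 1), rnorm(10))
#' @export
paired_permutation_test <- function(x, y, n_perm = 100000, seed = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  obs <- mean(d)
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    m <- 2^n
    # all sign patterns: bit j of pattern i
    signs <- matrix(1, m, n)
    for (j in seq_len(n))
      signs[bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0, j] <- -1
    stat <- as.vector(signs %*% d) / n
    p <- mean(abs(stat) >= abs(obs) - 1e-12)
    n_used <- m
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    stat <- as.vector(signs %*% d) / n
    p <- (sum(abs(stat) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = obs, p = p, n_perm = n_used,
                 exhaustive = exhaustive),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Paired sign-flip permutation test (%s, %d permutations)\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm))
  cat(sprintf("  mean difference = %.4f, two-sided p = %.4g\n",
              x$statistic, x$p))
  invisible(x)
}

#' Interaction of a 2x2 repeated-measures ANOVA
#'
#' Tests the interval-by-condition interaction in a complete within-subject
#' 2x2 design (e.g. model weights for interval 1/2 in Choice/No-Choice
#' trials). With one observation per cell per subject, the interaction F
#' with (1, n-1) degrees of freedom equals the squared paired t statistic on
#' the per-subject double difference
#' `(x11 - x12) - (x21 - x22)`; that identity is used directly.
#'
#' @param values An n x 4 matrix or data frame of cell values with columns
#'   ordered `(interval1.condition1, interval1.condition2,
#'   interval2.condition1, interval2.condition2)`, or an array
#'   `[subject, interval, condition]`.
#' @return A list with `F`, `df`, `p`, and the per-subject double
#'   differences `contrast`.
#' @export
rm_anova_2x2 <- function(values) {
  if (is.array(values) && length(dim(values)) == 3) {
    stopifnot(dim(values)[2] == 2, dim(values)[3] == 2)
    values <- cbind(values[, 1, 1], values[, 1, 2],
                    values[, 2, 1], values[, 2, 2])
  }
  values <- as.matrix(values)
  stopifnot(ncol(values) == 4)
  if (anyNA(values)) stop("missing cell in the 2x2 design")
  d <- (values[, 1] - values[, 2]) - (values[, 3] - values[, 4])
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    # exactly additive data: zero interaction contrast in every subject
    Fstat <- if (abs(mean(d)) < 1e-12) 0 else Inf
  } else {
    Fstat <- (mean(d) / (sdd / sqrt(n)))^2
  }
  list(F = Fstat, df = c(1, n - 1),
       p = stats::pf(Fstat, 1, n - 1, lower.tail = FALSE),
       contrast = d)
}

#' Bootstrap correlation between two subject-level measures
#'
#' Builds the sampling distribution of a Pearson correlation from
#' per-subject bootstrap replicate sets: each of `n_rep` replicates draws,
#' for every subject, one value at random (with replacement) from that
#' subject's bootstrap distribution of x and of y, computes the Pearson
#' correlation across subjects, and the confidence interval is read off the
#' percentiles of the replicate correlations. Point r is the correlation of
#' the observed values.
#'
#' @param x,y Observed per-subject values.
#' @param x_boot,y_boot Matrices (subjects x bootstrap draws) of per-subject
#'   bootstrap replicates; if `NULL`, subject resampling is used instead.
#' @param n_rep Number of bootstrap correlations (10,000 in the reference
#'   procedure).
#' @param seed Optional seed.
#' @param level Confidence level.
#' @return An object of class `"corr_result"`: `r`, `n`, `ci`, `boot_r`
#'   (the replicate correlations).
#' @export
bootstrap_correlation <- function(x, y, x_boot = NULL, y_boot = NULL,
                                  n_rep = 10000, seed = NULL, level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 subjects")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(x, y)
  boot_r <- numeric(n_rep)
  if (!is.null(x_boot)) {
    stopifnot(nrow(x_boot) == n, nrow(y_boot) == n)
    kx <- ncol(x_boot); ky <- ncol(y_boot)
    for (b in seq_len(n_rep)) {
      xi <- x_boot[cbind(seq_len(n), sample.int(kx, n, replace = TRUE))]
      yi <- y_boot[cbind(seq_len(n), sample.int(ky, n, replace = TRUE))]
      boot_r[b] <- stats::cor(xi, yi)
    }
  } else {
    for (b in seq_len(n_rep)) {
      idx <- sample.int(n, replace = TRUE)
      boot_r[b] <- suppressWarnings(stats::cor(x[idx], y[idx]))
    }
    boot_r <- boot_r[is.finite(boot_r)]
  }
  ci <- stats::quantile(boot_r, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(r = r, n = n, ci = ci, level = level, boot_r = boot_r),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), %d%% bootstrap CI [%.3f, %.3f]\n",
              x$r, x$n, round(x$level * 100), x$ci[1], x$ci[2]))
  invisible(x)
}

fisher_z <- function(r) atanh(r)
fisher_z_inv <- function(z) tanh(z)

#' Pool correlations across tasks via the Fisher transform
#'
#' Fisher-transforms the per-task correlation coefficients, averages them
#' weighted by `n - 3` (inverse variance of z), and back-transforms. When
#' per-task bootstrap correlation distributions are supplied, the pooled
#' confidence interval is obtained by combining one randomly sampled
#' bootstrap correlation per task in each of `n_rep` replicates, pooling
#' each combination the same way.
#'
#' @param r_per_task Correlation per task.
#' @param n_per_task Subjects per task.
#' @param boot_list Optional list of per-task bootstrap correlation vectors.
#' @param n_rep Pooled bootstrap replicates.
#' @param seed Optional seed.
#' @param level Confidence level.
#' @return A list with `r` (pooled), `z` (pooled Fisher z), and `ci` when
#'   bootstrap distributions were supplied.
#' @export
pool_correlations <- function(r_per_task, n_per_task, boot_list = NULL,
                              n_rep = 10000, seed = NULL, level = 0.95) {
  stopifnot(length(r_per_task) == length(n_per_task))
  if (any(abs(r_per_task) >= 1)) stop("|r| = 1 has infinite Fisher z")
  if (any(n_per_task <= 3)) stop("need n > 3 per task")
  w <- n_per_task - 3
  zbar <- sum(w * fisher_z(r_per_task)) / sum(w)
  out <- list(r = fisher_z_inv(zbar), z = zbar)
  if (!is.null(boot_list)) {
    if (!is.null(seed)) set.seed(seed)
    draws <- vapply(seq_len(n_rep), function(b) {
      rb <- vapply(boot_list, function(v) v[sample.int(length(v), 1)], 0)
      rb <- pmin(pmax(rb, -1 + 1e-12), 1 - 1e-12)
      fisher_z_inv(sum(w * fisher_z(rb)) / sum(w))
    }, 0)
    out$ci <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                              names = FALSE)
    out$boot_r <- draws
  }
  out
}

#' Test the difference between two independent correlations
#'
#' Two-sided p-value for the difference between two correlation
#' coefficients from independent samples, via the normal approximation to
#' the difference of Fisher z transforms with standard error
#' `sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Correlations.
#' @param n1,n2 Sample sizes.
#' @return A list with `z` (standardised difference) and `p`.
#' @export
correlation_difference_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| = 1 has infinite Fisher z")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (fisher_z(r1) - fisher_z(r2)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman screening correlation between estimations and mean evidence
#'
#' Thin utility for the subject-inclusion screen: the rank correlation
#' between the estimation reports and the mean evidence across both
#' intervals, per condition.
#'
#' @param trials Trial data frame of one subject.
#' @param condition Condition to screen.
#' @return `cor.test` result (Spearman).
#' @export
spearman_screen <- function(trials, condition = c("nochoice", "choice")) {
  condition <- match.arg(condition)
  tr <- trials[trials$condition == condition & !is.na(trials$y), , drop = FALSE]
  suppressWarnings(
    stats::cor.test(tr$y, (tr$phi1 + tr$phi2) / 2, method = "spearman"))
}

#' Compare estimation-vs-evidence regression slopes between conditions
#'
#' Per-subject ordinary least-squares slope of the estimation on the mean
#' evidence across both intervals, computed separately for Choice and
#' No-Choice trials; the condition difference is tested with the paired
#' sign-flip permutation test. (The published scalar this mirrors is not
#' fully specified; this per-subject-slope interpretation is recorded in the
#' methods vignette.)
#'
#' @param trials_by_subject List of per-subject trial data frames.
#' @param n_perm Permutations.
#' @param seed Optional seed.
#' @return A list with `slopes` (per subject x condition), `difference`
#'   (mean Choice - No-Choice slope) and `test` (a `perm_test`).
#' @export
estimation_slope_test <- function(trials_by_subject, n_perm = 100000,
                                  seed = NULL) {
  slope <- function(tr, cond) {
    d <- tr[tr$condition == cond & !is.na(tr$y), , drop = FALSE]
    m <- (d$phi1 + d$phi2) / 2
    unname(stats::coef(stats::lm(d$y ~ m))[2])
  }
  sc <- vapply(trials_by_subject, slope, 0, cond = "choice")
  sn <- vapply(trials_by_subject, slope, 0, cond = "nochoice")
  test <- paired_permutation_test(sc, sn, n_perm = n_perm, seed = seed)
  list(slopes = data.frame(choice = sc, nochoice = sn),
       difference = mean(sc - sn), test = test)
}
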