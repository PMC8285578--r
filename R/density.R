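# Grid spacing rule for numerical densities: a tenth of the smallest positive
# noise SD, clamped to [0.05, 0.5] evidence units (accuracy vs desk cost).
grid_spacing <- function(sigma, xi) {
  v <- c(sigma, xi)
  v <- v[v > 0]
  if (!length(v)) stop("degenerate density: zero total variance")
  min(max(min(v) / 10, 0.05), 0.5)
}

# Open (full) discrete convolution of two gridded densities sharing spacing
# h; returns values on the summed grid. FFT-backed via stats::convolve.
conv_open <- function(fa, fk, h) {
  out <- stats::convolve(fa, rev(fk), type = "open") * h
  out[out < 0] <- 0   # FFT round-off
  out
}

new_estimation_density <- function(grid, density, truncation_mass = NA_real_,
                                   flagged = FALSE) {
  h <- grid[2] - grid[1]
  s <- sum(density) * h
  if (s <= 0) stop("degenerate density: zero mass on grid")
  structure(list(grid = grid, density = density / s, spacing = h,
                 truncation_mass = truncation_mass, flagged = flagged),
            class = "estimation_density")
}

#' @export
print.estimation_density <- function(x, ...) {
  m <- density_mean(x)
  cat("Estimation density: ", length(x$grid), " grid points, spacing ",
      format(x$spacing), "\n  mean = ", format(m), ", sd = ",
      format(sqrt(density_mean(x, center = m, order = 2))), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.estimation_density <- function(x, ...) {
  data.frame(value = x$grid, density = x$density)
}

#' Moments of a gridded estimation density
#'
#' @param d An `estimation_density`.
#' @param center Optional centring value (for central moments).
#' @param order Moment order.
#' @return The numerical moment (trapezoid-free Riemann sum; the grid is
#'   uniform and the density renormalised on it).
#' @export
density_mean <- function(d, center = 0, order = 1) {
  sum((d$grid - center)^order * d$density) * d$spacing
}

#' No-Choice trial estimation density (closed form)
#'
#' On a No-Choice trial the predicted estimation is a sum of three Gaussian
#' variables (the two weighted noisy interval representations and estimation
#' noise), hence itself Gaussian:
#' `Y ~ N(w1 (phi1 + delta_e) + w2 (phi2 + delta_e),
#'        sigma^2 (w1^2 + w2^2) + xi^2)`.
#' The closed form is evaluated on a uniform grid for interface parity with
#' [choice_density()]; no convolution is involved.
#'
#' @param phi1,phi2 Interval evidence.
#' @param psych A [fit_psychometric()] object (or list with `sigma`,
#'   `delta_e`).
#' @param w1,w2 Interval weights.
#' @param xi Estimation-noise SD.
#' @return An `estimation_density`.
#' @export
nochoice_density <- function(phi1, phi2, psych, w1, w2, xi) {
  sigma <- psych$sigma; de <- psych$delta_e
  v <- sigma^2 * (w1^2 + w2^2) + xi^2
  if (v <= 0) stop("degenerate density: zero total variance")
  mu <- w1 * (phi1 + de) + w2 * (phi2 + de)
  h <- grid_spacing(sigma, xi)
  grid <- seq(mu - 6 * sqrt(v) - h, mu + 6 * sqrt(v) + h, by = h)
  new_estimation_density(grid, stats::dnorm(grid, mu, sqrt(v)))
}

#' Choice trial estimation density (truncation + numerical convolution)
#'
#' On a Choice trial the interval-1 representation is conditioned on the
#' binary choice it produced: the density of `X1 ~ N(phi1 + delta_e,
#' sigma^2)` is set to zero on the half-line whose sign is incongruent with
#' the choice `D`, and renormalised (a proper conditional; the normaliser
#' depends only on fixed quantities so it cannot move the likelihood's
#' argmax). The truncated variable is scaled by `w1` (negative `w1` flips the
#' scaled support; the truncation itself always acts on the evidence axis),
#' then numerically convolved with the combined Gaussian density of the
#' weighted interval-2 representation and the estimation noise,
#' `N(w2 (phi2 + delta_e), w2^2 sigma^2 + xi^2)`.
#'
#' When the choice is virtually impossible under `phi1` (truncation mass
#' below 1e-12) the truncated density is evaluated in log space relative to
#' its maximum, which acts as a numerical floor; the result is flagged.
#'
#' @inheritParams nochoice_density
#' @param D Binary choice, +1 or -1.
#' @param y_cover Optional values the returned grid must cover (the grid is
#'   auto-extended so likelihood evaluation never falls off it).
#' @param spacing Optional grid-spacing override (default: the package rule,
#'   a tenth of the smallest noise SD clamped to 0.05-0.5).
#' @return An `estimation_density` with `truncation_mass` (the analytic
#'   probability of the choice under `phi1`) and a `flagged` marker.
#' @export
choice_density <- function(phi1, phi2, D, psych, w1, w2, xi, y_cover = NULL,
                           spacing = NULL) {
  stopifnot(D %in% c(-1, 1))
  sigma <- psych$sigma; de <- psych$delta_e
  mu1 <- phi1 + de
  m2 <- w2 * (phi2 + de)
  s2 <- sqrt(w2^2 * sigma^2 + xi^2)
  h <- if (is.null(spacing)) grid_spacing(sigma, xi) else spacing
  zmass <- stats::pnorm(D * mu1 / sigma)
  flagged <- zmass < 1e-12

  if (w1 == 0) {
    # weight zero: the truncated component is a point mass at 0
    if (s2 == 0) stop("degenerate density: zero total variance")
    grid <- seq(m2 - 6 * s2 - h, m2 + 6 * s2 + h, by = h)
    return(new_estimation_density(grid, stats::dnorm(grid, m2, s2),
                                  zmass, flagged))
  }

  c1 <- w1 * mu1
  L1 <- 6 * abs(w1) * sigma + h
  if (!is.null(y_cover)) {
    span <- L1 + (if (s2 > 0) 6 * s2 else 0)
    need <- max(abs(y_cover - (c1 + m2)), 0) + 3 * h
    L1 <- L1 + max(0, need - span)
  }
  lo <- min(c1 - L1, -2 * h)
  hi <- max(c1 + L1, 2 * h)
  u <- seq(lo, hi, by = h)
  bnd <- NULL
  if (zmass > 1e-10) {
    # interior cells: pointwise truncated density (smooth, so the grid
    # convolution below is spectrally accurate); the one cell straddling the
    # truncation boundary at u = 0 is carried separately as an exact point
    # mass at its conditional mean, avoiding any error from the density jump
    ea <- (u - h / 2) / w1
    eb <- (u + h / 2) / w1
    xlo <- pmin(ea, eb); xhi <- pmax(ea, eb)
    straddle <- xlo < 0 & xhi > 0
    x1 <- u / w1
    fu <- stats::dnorm(x1, mu1, sigma) / abs(w1)
    fu[sign(x1) != D | straddle] <- 0
    ib <- which(straddle)
    if (length(ib)) {
      a <- if (D > 0) 0 else xlo[ib][1]
      b <- if (D > 0) xhi[ib][1] else 0
      pa <- stats::pnorm(a, mu1, sigma); pb <- stats::pnorm(b, mu1, sigma)
      mb <- max(pb - pa, 0)
      if (mb > 0) {
        za <- (a - mu1) / sigma; zb <- (b - mu1) / sigma
        xb <- mu1 + sigma * (stats::dnorm(za) - stats::dnorm(zb)) / (pb - pa)
        # edge of the interior quadrature region (u scale), for the
        # Euler-Maclaurin boundary correction applied after convolution
        ue <- if (xor(D > 0, w1 < 0)) u[ib][1] + h / 2 else u[ib][1] - h / 2
        fe <- stats::dnorm(ue / w1, mu1, sigma) / abs(w1)
        dfe <- fe * (-(ue / w1 - mu1) / sigma^2) / w1
        bnd <- c(mass = mb, u = w1 * xb, ue = ue, fe = fe, dfe = dfe,
                 dir = if (xor(D > 0, w1 < 0)) 1 else -1)
      }
    }
  } else {
    # choice virtually impossible under phi1: exact masses underflow, fall
    # back to a pointwise log-space evaluation relative to the maximum
    x1 <- u / w1
    lf <- stats::dnorm(x1, mu1, sigma, log = TRUE) - log(abs(w1))
    lf[sign(x1) != D] <- -Inf
    mx <- max(lf)
    if (!is.finite(mx)) stop("truncated density has no support on the grid")
    fu <- exp(lf - mx)
  }
  tot <- sum(fu) * h + if (is.null(bnd)) 0 else bnd[["mass"]]
  fu <- fu / tot
  mb <- 0
  if (!is.null(bnd)) {
    mb <- bnd[["mass"]] / tot
    bnd[["fe"]] <- bnd[["fe"]] / tot
    bnd[["dfe"]] <- bnd[["dfe"]] / tot
  }

  if (s2 == 0) {
    if (mb > 0) {
      ib <- which.min(abs(u - bnd[["u"]]))
      fu[ib] <- fu[ib] + mb / h
    }
    return(new_estimation_density(u + m2, fu, zmass, flagged))
  }
  v <- seq(-6 * s2 - h, 6 * s2 + h, by = h)
  fk <- stats::dnorm(v, 0, s2)
  conv <- conv_open(fu, fk, h)
  grid <- (u[1] + v[1] + m2) + h * (seq_along(conv) - 1L)
  if (mb > 0) {
    # Euler-Maclaurin boundary term of the midpoint quadrature at the cut
    # edge of the interior region, then the boundary cell's exact mass
    tl <- grid - (bnd[["ue"]] + m2)
    phi_t <- stats::dnorm(tl, 0, s2)
    gprime <- bnd[["dfe"]] * phi_t + bnd[["fe"]] * tl / s2^2 * phi_t
    conv <- pmax(conv - bnd[["dir"]] * h^2 / 24 * gprime, 0)
    conv <- conv + mb * stats::dnorm(grid, bnd[["u"]] + m2, s2)
  }
  new_estimation_density(grid, conv, zmass, flagged)
}

# Evaluate an estimation density at observations. Interpolation is cubic in
# log density (linear interpolation of the density itself is visibly biased
# in the exponential tails), floored so logs stay finite.
density_at <- function(d, y) {
  lf <- log(pmax(d$density, 1e-300))
  inside <- y >= d$grid[1] & y <= d$grid[length(d$grid)]
  out <- rep(1e-300, length(y))
  if (any(inside))
    out[inside] <- exp(stats::spline(d$grid, lf, xout = y[inside],
                                     method = "fmm")$y)
  pmax(out, 1e-300)
}

#' Log-likelihood of estimations under a gain model
#'
#' Sums, over trials, the log of the model-predicted estimation density at
#' the observed estimation. No-Choice trials use the closed-form Gaussian
#' density; Choice trials use the truncated-convolution density, computed
#' once per unique `(phi1, phi2, D)` cell and interpolated at that cell's
#' observations (the cell cache is what makes desk-scale fitting cheap: 23
#' direction combinations x 2 choices in the perceptual task versus 2,070
#' trials).
#'
#' @param trials Preprocessed trial data frame (estimation trials only). For
#'   `model = "selective"` a `consistency` column must be present and
#'   consistency-undefined trials absent.
#' @param psych A `psychfit` (or list with `sigma`, `delta_e`).
#' @param params Named list/vector of weights and noise SDs: for
#'   `model = "global"`, `w1c, w2c, xi_c, w1nc, w2nc, xi_nc` (only the
#'   entries needed for the conditions present are required); for
#'   `model = "selective"`, `w1cc, w2cc, xi_cc, w1ic, w2ic, xi_ic` plus the
#'   No-Choice entries if No-Choice trials are included.
#' @param model Model tag.
#' @return Total log-likelihood (scalar).
#' @export
model_loglik <- function(trials, psych, params,
                         model = c("global", "selective")) {
  model <- match.arg(model)
  params <- as.list(params)
  est <- trials[!trials$feedback_terminated & !is.na(trials$y), , drop = FALSE]
  de <- psych$delta_e
  ll <- 0
  nc <- est[est$condition == "nochoice", , drop = FALSE]
  if (nrow(nc)) {
    v <- psych$sigma^2 * (params$w1nc^2 + params$w2nc^2) + params$xi_nc^2
    mu <- params$w1nc * (nc$phi1 + de) + params$w2nc * (nc$phi2 + de)
    ll <- ll + sum(stats::dnorm(nc$y, mu, sqrt(v), log = TRUE))
  }
  ch <- est[est$condition == "choice", , drop = FALSE]
  if (nrow(ch)) {
    if (model == "global") {
      ll <- ll + choice_cells_loglik(make_choice_cells(ch), psych,
                                     params$w1c, params$w2c, params$xi_c)
    } else {
      if (!"consistency" %in% names(ch))
        stop("selective model requires consistency labels; see label_consistency()")
      if (any(ch$consistency == "undefined"))
        stop("consistency-undefined trials must be removed before a selective fit")
      cc <- ch[ch$consistency == "consistent", , drop = FALSE]
      ic <- ch[ch$consistency == "inconsistent", , drop = FALSE]
      if (nrow(cc))
        ll <- ll + choice_cells_loglik(make_choice_cells(cc), psych,
                                       params$w1cc, params$w2cc, params$xi_cc)
      if (nrow(ic))
        ll <- ll + choice_cells_loglik(make_choice_cells(ic), psych,
                                       params$w1ic, params$w2ic, params$xi_ic)
    }
  }
  ll
}

# Group choice trials into unique (phi1, phi2, D) cells, each carrying its
# observed estimations.
make_choice_cells <- function(trials) {
  key <- paste(trials$phi1, trials$phi2, trials$D)
  lapply(split(seq_len(nrow(trials)), key), function(idx) {
    list(phi1 = trials$phi1[idx[1]], phi2 = trials$phi2[idx[1]],
         D = trials$D[idx[1]], y = trials$y[idx])
  })
}

choice_cells_loglik <- function(cells, psych, w1, w2, xi) {
  # the interval-2 mean w2 * (phi2 + delta_e) enters the Choice density only
  # as a location shift, so one truncated convolution per (phi1, D) group
  # serves every phi2 cell: evaluate it at the shifted observations
  de <- psych$delta_e
  key <- vapply(cells, function(cl) paste(cl$phi1, cl$D), "")
  tot <- 0
  for (grp in split(cells, key)) {
    ys <- unlist(lapply(grp, function(cl) cl$y - w2 * (cl$phi2 + de)))
    d <- choice_density(grp[[1]]$phi1, -de, grp[[1]]$D, psych, w1, w2, xi,
                        y_cover = range(ys))
    tot <- tot + sum(log(density_at(d, ys)))
  }
  tot
}
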