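## Trajectory-level migration statistics: step directions, direction
## autocorrelation, persistence time (exponential fit), directionality
## ratio, polarity-axis vs movement angles, reorientation curves and
## the alignment index.

as_xy <- function(track) {
  if (is.data.frame(track)) cbind(track$x, track$y) else as.matrix(track)
}

track_dt <- function(track, dt = NULL) {
  if (!is.null(dt)) return(dt)
  if (!is.null(attr(track, "dt"))) return(attr(track, "dt"))
  if (is.data.frame(track) && "time" %in% names(track) && nrow(track) > 1)
    return(stats::median(diff(track$time)))
  1
}

#' Directions of consecutive steps of a track
#'
#' `theta(t) = atan2(dy, dx)` of the displacement from position t to
#' t+1.  Zero-displacement steps yield `NA` rather than an arbitrary
#' angle, so stationary frames cannot fake alignment.
#'
#' @param track data.frame with `x`, `y` (or an n x 2 matrix).
#' @return numeric vector of angles in radians, length `n - 1`.
#' @export
step_directions <- function(track) {
  xy <- as_xy(track)
  assert_that(nrow(xy) >= 2, "need at least two positions")
  d <- diff(xy)
  theta <- atan2(d[, 2], d[, 1])
  theta[d[, 1] == 0 & d[, 2] == 0] <- NA_real_
  theta
}

#' Direction autocorrelation of a trajectory
#'
#' `AC(lag) = mean over t of cos(theta(t + lag) - theta(t))`, with
#' missing directions (zero-displacement steps) skipped pairwise.
#' `AC(0) = 1` by construction.
#'
#' @param track data.frame with `x`, `y` and optionally `time`.
#' @param max_lag largest lag in frames; default one third of the
#'   number of steps.
#' @param dt time per frame (default from the track).
#' @return an `autocorr` data.frame with columns `lag` (time units),
#'   `ac`, `n_pairs`; attribute `dt`.
#' @export
direction_autocorrelation <- function(track, max_lag = NULL, dt = NULL) {
  theta <- step_directions(track)
  assert_that(sum(is.finite(theta)) >= 3,
              "need at least three valid step directions")
  dt <- track_dt(track, dt)
  n <- length(theta)
  if (is.null(max_lag)) max_lag <- max(1L, floor(n / 3))
  max_lag <- min(max_lag, n - 1L)
  ac <- numeric(max_lag); np <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    dtheta <- theta[(1 + lag):n] - theta[1:(n - lag)]
    ok <- is.finite(dtheta)
    np[lag] <- sum(ok)
    ac[lag] <- if (np[lag] > 0) mean(cos(dtheta[ok])) else NA_real_
  }
  out <- data.frame(lag = c(0, seq_len(max_lag)) * dt,
                    ac = c(1, ac),
                    n_pairs = c(sum(is.finite(theta)), np))
  attr(out, "dt") <- dt
  class(out) <- c("autocorr", "data.frame")
  out
}

#' Fit the persistence time from a direction-autocorrelation curve
#'
#' Nonlinear least squares of `exp(-lag/tau)` over lags from one frame
#' up to `fit_frac` of the curve's extent.  A curve that never falls
#' below `1/e` in the fitted range cannot resolve its own decay; the
#' fit is then reported at the censoring bound (the track duration)
#' and flagged.
#'
#' @param ac an `autocorr` data.frame (or any with `lag`, `ac`).
#' @param fit_frac fraction of the available lags used (default 1,
#'   i.e. the whole curve, which itself defaults to one third of the
#'   track duration).
#' @param tau_max censoring bound; default the largest lag times 3.
#' @return list with `tau`, `censored` (logical), `converged`,
#'   `fit_range` (c(min, max) lag), `residual` (RMS of fit residuals).
#' @export
fit_persistence_time <- function(ac, fit_frac = 1, tau_max = NULL) {
  lag <- ac$lag; y <- ac$ac
  keep <- lag > 0 & lag <= fit_frac * max(lag) & is.finite(y)
  lag <- lag[keep]; y <- y[keep]
  assert_that(length(lag) >= 5, "need at least 5 lags to fit")
  if (is.null(tau_max)) tau_max <- 3 * max(lag)
  below <- which(y < exp(-1))
  start_tau <- if (length(below)) max(lag[below[1]], lag[1]) else max(lag)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-lag / tau),
                      start = list(tau = start_tau),
                      lower = c(tau = lag[1] / 100),
                      upper = c(tau = tau_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(tau = NA_real_, censored = FALSE, converged = FALSE,
                fit_range = range(lag), residual = NA_real_))
  }
  tau <- unname(stats::coef(fit)["tau"])
  censored <- length(below) == 0 || tau >= 0.999 * tau_max
  if (censored) tau <- tau_max
  list(tau = tau, censored = censored, converged = TRUE,
       fit_range = range(lag),
       residual = sqrt(mean(stats::resid(fit)^2)))
}

#' Directionality ratio of a track
#'
#' Net displacement divided by total path length: 1 for a straight
#' path, 0 for a closed loop.
#'
#' @param track data.frame with `x`, `y`.
#' @return scalar in `[0, 1]`.
#' @export
directionality_ratio <- function(track) {
  xy <- as_xy(track)
  assert_that(nrow(xy) >= 2, "need at least two positions")
  steps <- sqrt(rowSums(diff(xy)^2))
  total <- sum(steps)
  assert_that(total > 0, "zero path length")
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  net / total
}

#' Angles between the nucleus-Golgi axis and the direction of movement
#'
#' Per step, the signed angle (counterclockwise positive) from the
#' displacement vector to the nucleus-to-Golgi vector, in
#' (-180, 180] degrees; plus circular and linear summaries.
#'
#' @param track data.frame with `x`, `y`, `nucleus_x`, `nucleus_y`,
#'   `golgi_x`, `golgi_y`.
#' @return list with `angles_deg` (per step, `NA` where the step or
#'   axis is degenerate), `circ_mean_deg`, `circ_sd_deg`,
#'   `linear_sd_deg` and `r` (mean resultant length).
#' @export
axis_movement_angles <- function(track) {
  need <- c("nucleus_x", "nucleus_y", "golgi_x", "golgi_y")
  assert_that(all(need %in% names(track)),
              "track lacks nucleus/golgi columns")
  motion <- step_directions(track)
  gx <- track$golgi_x - track$nucleus_x
  gy <- track$golgi_y - track$nucleus_y
  axis <- atan2(gy, gx)
  axis[gx == 0 & gy == 0] <- NA_real_
  axis <- axis[-length(axis)]              # axis at the step's start frame
  ang <- wrap_pi(axis - motion)
  deg <- ang * 180 / pi
  r <- mean_resultant_length(ang)
  list(angles_deg = deg,
       circ_mean_deg = circ_mean(ang) * 180 / pi,
       circ_sd_deg = circ_sd(ang) * 180 / pi,
       linear_sd_deg = stats::sd(deg, na.rm = TRUE),
       r = r)
}

#' Reorientation of the nucleus-Golgi axis towards a target
#'
#' The angle between the nucleus-to-Golgi axis and the nucleus-to-
#' target axis per frame, wrapped to `[0, 2*pi)` and then unwrapped to
#' a continuous curve (no 2*pi jumps), reported in degrees.
#' 0 degrees = axis pointing at the target.
#'
#' @param nucleus,golgi,target n x 2 matrices (columns x, y) or
#'   data.frames with `x`, `y`.
#' @param time optional time vector (default frame index, 0-based).
#' @return data.frame with `time` and `angle_deg` (continuous).
#' @export
reorientation_series <- function(nucleus, golgi, target, time = NULL) {
  nuc <- as_xy(nucleus); gol <- as_xy(golgi); tar <- as_xy(target)
  n <- nrow(nuc)
  assert_that(nrow(gol) == n && nrow(tar) == n,
              "nucleus, golgi and target must have equal lengths")
  a_axis <- atan2(gol[, 2] - nuc[, 2], gol[, 1] - nuc[, 1])
  a_targ <- atan2(tar[, 2] - nuc[, 2], tar[, 1] - nuc[, 1])
  ang <- wrap_2pi(a_axis - a_targ)
  # unwrap: remove 2*pi discontinuities between consecutive samples
  d <- diff(ang)
  d <- d - 2 * pi * round(d / (2 * pi))
  unwrapped <- cumsum(c(ang[1], d))
  if (is.null(time)) time <- seq_len(n) - 1
  data.frame(time = time, angle_deg = unwrapped * 180 / pi)
}

#' Cumulative fraction of cells reoriented below a threshold angle
#'
#' Per cell, the first time its |angle| curve reaches the threshold
#' from above marks reorientation; the cumulative count over cells is
#' normalized by the total number of cells (cells that never cross
#' stay in the denominator).
#'
#' @param curves list of data.frames from [reorientation_series()] (or
#'   with columns `time`, `angle_deg`).
#' @param threshold_deg reorientation threshold (default 30 degrees).
#' @return list with `crossing_times` (per cell, `NA` if never),
#'   `curve` (data.frame `time`, `fraction`).
#' @export
cumulative_reorientation <- function(curves, threshold_deg = 30) {
  crossing <- vapply(curves, function(cv) {
    hit <- which(abs(cv$angle_deg) <= threshold_deg)
    if (!length(hit)) NA_real_ else cv$time[hit[1]]
  }, numeric(1))
  n_cells <- length(crossing)
  tt <- sort(unique(crossing[!is.na(crossing)]))
  frac <- vapply(tt, function(t0) sum(crossing <= t0, na.rm = TRUE),
                 numeric(1)) / n_cells
  list(crossing_times = crossing,
       curve = data.frame(time = tt, fraction = frac))
}

#' Alignment index (angular dispersion) of paired angles
#'
#' The mean resultant length
#' `r = sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)` of the per-frame
#' differences between the polarity-axis direction and the direction
#' of movement: 1 = perfect alignment, 0 = uniform dispersion.
#'
#' @param axis_angles,motion_angles paired angles in radians (`NA`s
#'   dropped pairwise); alternatively pass precomputed differences as
#'   `axis_angles` and omit `motion_angles`.
#' @return scalar in `[0, 1]`.
#' @export
alignment_index <- function(axis_angles, motion_angles = NULL) {
  theta <- if (is.null(motion_angles)) axis_angles
           else axis_angles - motion_angles
  mean_resultant_length(theta)
}
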