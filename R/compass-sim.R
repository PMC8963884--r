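## The cell-compass simulation: protrusive events nucleate
## stochastically on a circular contour of markers, biased towards an
## internal polarity axis with probability `p_polarized`, while
## protrusions pull the axis back towards themselves with weight
## `kappa` against its basal random drift.

#' Parameters of the compass simulation
#'
#' @param p_polarized probability in `[0, 1]` that a nucleated event is
#'   placed in front of the polarity axis (otherwise uniformly at
#'   random along the contour).
#' @param kappa weight in `[0, 1]` of the protrusion-derived force in
#'   the polarity-axis update (`1 - kappa` weights the basal drift).
#' @param p_nuc nucleation probability per frame (default 0.25).
#' @param sigma_c placement noise of polarized events, markers
#'   (default 5, i.e. 1/20 of the contour).
#' @param n_markers contour markers (default 100).
#' @param t_tot simulated frames (default 1000).
#' @param dt minutes per frame (default 5).
#' @param axis_gain gain converting the protrusion force (summed
#'   positive speeds, signed by circular direction) into axis motion
#'   in markers/frame; calibrated so a single pinned protrusion
#'   captures the axis within about one event duration at
#'   `kappa = 1` (see [axis_convergence_time()]).
#' @param smooth_window moving-average window (frames) of the basal
#'   axis path; calibrated so the free axis spans a full turn in about
#'   48 frames (4 h).
#' @param template an [event_template_params()].
#' @param seed RNG seed.
#' @return a `compass_params` list.
#' @export
compass_params <- function(p_polarized = 0.5, kappa = 0.5, p_nuc = 0.25,
                           sigma_c = 5, n_markers = 100L, t_tot = 1000L,
                           dt = 5, axis_gain = 0.8, smooth_window = 36L,
                           template = event_template_params(),
                           seed = NULL) {
  assert_that(p_polarized >= 0 && p_polarized <= 1,
              "p_polarized must be in [0, 1]")
  assert_that(kappa >= 0 && kappa <= 1, "kappa must be in [0, 1]")
  assert_that(p_nuc >= 0 && p_nuc <= 1, "p_nuc must be in [0, 1]")
  assert_that(sigma_c >= 0, "sigma_c must be >= 0")
  assert_that(t_tot >= 1, "t_tot must be >= 1")
  structure(list(p_polarized = p_polarized, kappa = kappa, p_nuc = p_nuc,
                 sigma_c = sigma_c, n_markers = as.integer(n_markers),
                 t_tot = as.integer(t_tot), dt = dt,
                 axis_gain = axis_gain,
                 smooth_window = as.integer(smooth_window),
                 template = template, seed = seed),
            class = "compass_params")
}

#' Basal (feedback-free) trajectory of the polarity axis
#'
#' The axis speed is the derivative of a smoothed random function:
#' i.i.d. draws uniform on `(0, 10 * n_markers)` passed through a
#' moving average of `smooth_window` frames.  The window is calibrated
#' so the free axis typically sweeps a full contour turn (360 degrees,
#' `n_markers` markers) in about 48 frames (4 h at 5 min/frame).
#'
#' @param t_tot frames.
#' @param n_markers contour markers.
#' @param smooth_window moving-average window, frames.
#' @param seed RNG seed.
#' @return list with `c_axis` (length `t_tot`, wrapped to
#'   `[0, n_markers)`), `path` (unwrapped), `f_basal` (length
#'   `t_tot`, per-frame derivative; last entry 0).
#' @export
natural_axis_path <- function(t_tot = 1000L, n_markers = 100L,
                              smooth_window = 48L, seed = NULL) {
  with_seed(seed, {
    w <- max(1L, as.integer(smooth_window))
    u <- stats::runif(t_tot + w, 0, 10 * n_markers)
    sm <- stats::filter(u, rep(1 / w, w), sides = 1)
    path <- as.numeric(sm[w:(w + t_tot - 1L)])
    f_basal <- c(diff(path), 0)
    list(c_axis = path %% n_markers, path = path, f_basal = f_basal)
  })
}

# protrusion force on the axis: positive speeds signed by the shortest
# circular offset from the axis to each marker
protrusion_force <- function(v, c_axis, n) {
  pos <- pmax(v, 0)
  off <- circ_offset(seq_len(n) - 1L, c_axis, n)
  sum(pos * sign(off))
}

#' Run the compass simulation
#'
#' Per frame, with probability `p_nuc` a protrusive event nucleates;
#' with probability `p_polarized` its center is drawn from
#' `Normal(c_axis, sigma_c)` (rounded, circular), otherwise uniformly.
#' The event template is added to the morphodynamic map (events
#' superpose).  The axis then moves by
#' `kappa * axis_gain * F_prot + (1 - kappa) * F_basal`, where
#' `F_prot` sums positive edge speeds signed by their circular
#' direction from the axis and `F_basal` is the basal drift.  The
#' centroid steps by the marker-velocity mean
#' `(1/n) * sum_i v_i (cos theta_i, sin theta_i)` with
#' `theta_i = 2 pi i / n`.
#'
#' @param params a [compass_params()].
#' @return a `compass_sim` list: `map` (a `morphomap`,
#'   `n_markers x t_tot`), `c_axis` (length `t_tot`, in
#'   `[0, n_markers)`), `trajectory` (data.frame `frame`, `time`, `x`,
#'   `y`, `t_tot + 1` rows), `events` (data.frame `frame`, `center`,
#'   `polarized`), `params`.
#' @export
simulate_compass <- function(params = compass_params()) {
  p <- params
  n <- p$n_markers; t_tot <- p$t_tot
  tmpl <- single_event_template(p$template, n)
  t_len <- ncol(tmpl)
  with_seed(p$seed, {
    nat <- natural_axis_path(t_tot, n, p$smooth_window, seed = NULL)
    map <- matrix(0, n, t_tot + t_len)
    c_axis <- numeric(t_tot)
    c_axis[1] <- stats::runif(1, 0, n)
    dx <- numeric(t_tot); dy <- numeric(t_tot)
    theta_i <- 2 * pi * (seq_len(n) - 1L) / n
    cth <- cos(theta_i); sth <- sin(theta_i)
    ev_frame <- integer(0); ev_center <- integer(0); ev_pol <- logical(0)
    for (t in seq_len(t_tot)) {
      if (stats::runif(1) < p$p_nuc) {
        pol <- stats::runif(1) < p$p_polarized
        center <- if (pol) {
          as.integer(round(stats::rnorm(1, c_axis[t], p$sigma_c))) %% n
        } else {
          sample.int(n, 1L) - 1L
        }
        idx <- ((center + 0:(n - 1L)) %% n) + 1L
        cols <- t:(t + t_len - 1L)
        map[idx, cols] <- map[idx, cols] + tmpl
        ev_frame <- c(ev_frame, t); ev_center <- c(ev_center, center)
        ev_pol <- c(ev_pol, pol)
      }
      v <- map[, t]
      dx[t] <- mean(v * cth); dy[t] <- mean(v * sth)
      if (t < t_tot) {
        f_prot <- protrusion_force(v, c_axis[t], n)
        c_axis[t + 1L] <- (c_axis[t] + p$kappa * p$axis_gain * f_prot +
                             (1 - p$kappa) * nat$f_basal[t]) %% n
      }
    }
    traj <- data.frame(frame = 0:t_tot, time = (0:t_tot) * p$dt,
                       x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
    attr(traj, "dt") <- p$dt
    structure(list(map = new_morphomap(map[, seq_len(t_tot), drop = FALSE],
                                       dt = p$dt),
                   c_axis = c_axis, trajectory = traj,
                   events = data.frame(frame = ev_frame,
                                       center = ev_center,
                                       polarized = ev_pol),
                   natural = nat, params = p),
              class = "compass_sim")
  })
}

#' @export
print.compass_sim <- function(x, ...) {
  cat(sprintf(
    "compass_sim: p_polarized = %.2f, kappa = %.2f, %d frames, %d events\n",
    x$params$p_polarized, x$params$kappa, x$params$t_tot,
    nrow(x$events)))
  invisible(x)
}

#' Protrusive unicity index of a morphodynamic map
#'
#' The inverse of the average number of simultaneous protrusions.  A
#' sliding window of `window` frames moves along the map; within each
#' window, markers whose speed exceeds `threshold_frac` of the maximal
#' protrusion speed at any frame of the window are active, and the
#' number of circularly connected runs of active markers counts the
#' distinct protruding fronts.  The index is `1 / Np` with `Np` the
#' mean count over windows containing at least one front.
#'
#' With `threshold_scope = "window"` (default) the reference maximum
#' is each window's own peak protrusion speed, so every window's
#' competing fronts are counted on its own scale; `"map"` uses the
#' whole map's peak instead, which only counts fronts comparable to
#' the single strongest event.
#'
#' @param map matrix or `morphomap` of signed edge speeds.
#' @param window sliding-window length, frames (default 10).
#' @param threshold_frac fraction of the maximal protrusion speed
#'   (default 0.7).
#' @param threshold_scope `"window"` or `"map"` (see above).
#' @return scalar in `(0, 1]`, or `NA` if the map has no positive
#'   speeds.
#' @export
unicity_index <- function(map, window = 10L, threshold_frac = 0.7,
                          threshold_scope = c("window", "map")) {
  threshold_scope <- match.arg(threshold_scope)
  v <- unclass(map)
  assert_that(ncol(v) >= window, "map shorter than the sliding window")
  v[!is.finite(v)] <- -Inf
  vmax <- max(v)
  if (!is.finite(vmax) || vmax <= 0) return(NA_real_)
  n <- nrow(v); nT <- ncol(v)
  nw <- nT - window + 1L
  # per-marker running max over each window
  rm_ <- v[, seq_len(nw), drop = FALSE]
  for (k in seq_len(window - 1L))
    rm_ <- pmax(rm_, v[, (1L + k):(nw + k), drop = FALSE])
  wmax <- apply(rm_, 2, max)                     # window peak speed
  thr <- threshold_frac * if (threshold_scope == "window") wmax
                          else rep(vmax, nw)
  active <- sweep(rm_, 2, thr, ">=") & rm_ > 0
  # circular runs per window: starts where active and predecessor not
  prev <- active[c(n, seq_len(n - 1L)), , drop = FALSE]
  starts <- colSums(active & !prev)
  full <- colSums(active) == n                   # fully active ring
  counts <- ifelse(full, 1L, starts)
  has <- counts > 0 & wmax > 0
  if (!any(has)) return(NA_real_)
  1 / mean(counts[has])
}

#' Alignment index of a compass simulation
#'
#' Mean resultant length of the per-frame difference between the
#' polarity-axis direction (`2 pi c_axis / n_markers`) and the
#' instantaneous direction of motion; frames with zero displacement
#' are skipped.
#'
#' @param sim a `compass_sim`.
#' @return scalar in `[0, 1]`.
#' @export
alignment_from_simulation <- function(sim) {
  n <- sim$params$n_markers
  axis_angle <- 2 * pi * sim$c_axis / n
  motion <- step_directions(sim$trajectory)
  alignment_index(axis_angle - motion)
}

#' Persistence time, unicity and alignment of one simulation
#'
#' The same code paths as for experimental data: the trajectory's
#' direction autocorrelation is fitted with `exp(-lag/tau)` (censored
#' at the run duration), the map's unicity index and the axis-motion
#' alignment are computed.
#'
#' @param sim a `compass_sim`.
#' @param unicity_window,unicity_threshold passed to [unicity_index()].
#' @return list with `tau` (same time units as `dt`), `tau_censored`,
#'   `unicity`, `alignment`.
#' @export
compass_observables <- function(sim, unicity_window = 10L,
                                unicity_threshold = 0.7) {
  p <- sim$params
  duration <- p$t_tot * p$dt
  tau <- NA_real_; censored <- FALSE
  ac <- tryCatch(direction_autocorrelation(sim$trajectory, dt = p$dt),
                 error = function(e) NULL)
  if (!is.null(ac)) {
    fit <- fit_persistence_time(ac, tau_max = duration)
    tau <- fit$tau; censored <- fit$censored
  }
  list(tau = tau, tau_censored = censored,
       unicity = unicity_index(sim$map, unicity_window,
                               unicity_threshold),
       alignment = alignment_from_simulation(sim))
}

#' Frames for the axis to reach a pinned sustained protrusion
#'
#' Calibration aid for `axis_gain`: a sustained Gaussian protrusion
#' (peak speed 1, the template's peak scale) is pinned at a fixed
#' marker, the basal drift is switched off (`kappa = 1`), and the
#' axis starts `offset` markers away.  Returns the first frame at
#' which the axis comes within `tol` markers of the protrusion center.
#'
#' @param params a [compass_params()].
#' @param offset initial axis distance, markers (default `n/2`, the
#'   farthest point).
#' @param tol capture distance, markers (default `sigma_c`).
#' @param max_frames give up after this many frames.
#' @return integer frame count (`Inf` if never captured).
#' @export
axis_convergence_time <- function(params = compass_params(kappa = 1),
                                  offset = NULL, tol = NULL,
                                  max_frames = 200L) {
  n <- params$n_markers
  if (is.null(offset)) offset <- n / 2
  if (is.null(tol)) tol <- max(params$sigma_c, 1)
  center <- 0
  v <- circ_gauss(0:(n - 1L), params$template$sigma_narrow, n)
  c_axis <- offset %% n
  for (t in seq_len(max_frames)) {
    if (abs(circ_offset(center, c_axis, n)) <= tol) return(t - 1L)
    f <- protrusion_force(v, c_axis, n)
    c_axis <- (c_axis + params$axis_gain * f) %% n
  }
  Inf
}

#' Render a simulated map as a contour movie
#'
#' Delegates to [gen_contour_movie()]: the simulated morphodynamic map
#' evolves an initially circular elastic contour (visualization and
#' round-trip checks).
#'
#' @param sim a `compass_sim`.
#' @param radius initial contour radius (px).
#' @param frames which frame transitions to render (default all).
#' @param speed_scale multiplies map speeds before displacement
#'   (px/frame per map unit).
#' @return a `contour_sequence`.
#' @export
render_movie <- function(sim, radius = 50, frames = NULL,
                         speed_scale = 1) {
  v <- unclass(sim$map)
  if (!is.null(frames)) v <- v[, frames, drop = FALSE]
  ang <- 2 * pi * (0:(sim$params$n_markers - 1L)) / sim$params$n_markers
  circle <- cbind(radius * cos(ang), radius * sin(ang))
  gen_contour_movie(v * speed_scale, circle, dt = 1)
}
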