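## Single protrusive event of the compass model: a space-time transfer
## function (edge response to a point-like Cdc42 activity pulse)
## convolved with a "signaling puff", normalized to zero total sum so
## superposed events conserve cell area.
##
## The numeric amplitudes and widths are free parameters of the model,
## constrained by two calibration requirements: the resulting event
## lasts about 10 frames (50 min at 5 min/frame) above 10% of its peak
## speed, and its spatial footprint stays below ~20 of 100 markers.

# circular Gaussian over marker offsets, unnormalized peak 1
circ_gauss <- function(s, sigma, n) {
  d <- abs(s) %% n
  d <- pmin(d, n - d)
  exp(-d^2 / (2 * sigma^2))
}

#' Parameters of the single-event space-time template
#'
#' Four kernel terms (amplitudes `A1..A4`): (i) a wide negative spatial
#' Gaussian for the initial lateral inhibition, (ii) a narrow positive
#' Gaussian for the local protrusion, (iii) a positive Gaussian pair
#' whose centers travel laterally at speed `wave_speed` for the
#' traveling wave, and (iv) a negative Gaussian in time centered on 0
#' for the central long-lasting inhibition; each multiplied by an
#' exponential temporal decay (`tau1..tau4`; `tau4` is the SD of the
#' temporal Gaussian of term iv).  The Cdc42 puff is a spatial
#' Gaussian (`sigma_puff`) times an exponential decay (`tau_puff`).
#'
#' Widths are in markers, times in frames.
#'
#' @param A1,sigma_wide,tau1 lateral-inhibition term.
#' @param A2,sigma_narrow,tau2 protrusion term.
#' @param A3,wave_speed,tau3 traveling-wave term (markers/frame).
#' @param A4,sigma_mid,tau4 central-inhibition term.
#' @param sigma_puff,tau_puff Cdc42 puff extent and duration.
#' @param t_len temporal support of the template, frames.
#' @return an `event_template_params` list.
#' @export
event_template_params <- function(A1 = 0.35, sigma_wide = 30, tau1 = 3.5,
                                  A2 = 1.5, sigma_narrow = 3, tau2 = 4,
                                  A3 = 0.35, wave_speed = 1.5, tau3 = 4,
                                  A4 = 0.2, sigma_mid = 5, tau4 = 6,
                                  sigma_puff = 2, tau_puff = 2,
                                  t_len = 36L) {
  p <- list(A1 = A1, sigma_wide = sigma_wide, tau1 = tau1,
            A2 = A2, sigma_narrow = sigma_narrow, tau2 = tau2,
            A3 = A3, wave_speed = wave_speed, tau3 = tau3,
            A4 = A4, sigma_mid = sigma_mid, tau4 = tau4,
            sigma_puff = sigma_puff, tau_puff = tau_puff,
            t_len = as.integer(t_len))
  widths <- c(p$sigma_wide, p$sigma_narrow, p$sigma_mid, p$sigma_puff)
  decays <- c(p$tau1, p$tau2, p$tau3, p$tau4, p$tau_puff)
  assert_that(all(widths > 0) && all(decays > 0),
              "all widths and decay constants must be positive")
  structure(p, class = "event_template_params")
}

#' Space-time transfer function of the edge response
#'
#' `kernel(s, t)` for circular marker offset `s` and `t >= 0` frames:
#' the sum of the four terms described in [event_template_params()].
#'
#' @param params an [event_template_params()].
#' @param n_markers circular spatial support.
#' @return `n_markers x t_len` matrix; row 1 is offset `s = 0`, rows
#'   wrap circularly.
#' @export
make_transfer_function <- function(params = event_template_params(),
                                   n_markers = 100L) {
  p <- params
  n <- as.integer(n_markers)
  assert_that(max(p$sigma_wide, p$sigma_mid, p$sigma_narrow) <= n / 2,
              "spatial widths must not exceed n_markers/2")
  s <- 0:(n - 1L)                       # circular offsets
  tt <- 0:(p$t_len - 1L)
  g_wide <- circ_gauss(s, p$sigma_wide, n)
  g_narrow <- circ_gauss(s, p$sigma_narrow, n)
  g_mid <- circ_gauss(s, p$sigma_mid, n)
  k <- matrix(0, n, p$t_len)
  for (j in seq_along(tt)) {
    t0 <- tt[j]
    wave <- circ_gauss(s - p$wave_speed * t0, p$sigma_narrow, n) +
            circ_gauss(s + p$wave_speed * t0, p$sigma_narrow, n)
    k[, j] <- -p$A1 * g_wide * exp(-t0 / p$tau1) +
               p$A2 * g_narrow * exp(-t0 / p$tau2) +
               p$A3 * wave * exp(-t0 / p$tau3) +
              -p$A4 * g_mid * exp(-t0^2 / (2 * p$tau4^2))
  }
  k
}

# circular convolution along rows (space) and causal along columns
# (time) of two n x T matrices, truncated to T columns
conv_space_time <- function(a, b) {
  n <- nrow(a); nT <- ncol(a)
  # space: FFT along the circular dimension
  fa <- stats::mvfft(a)
  fb <- stats::mvfft(b)
  out <- matrix(0, n, nT)
  # time: causal sum out[, t] = sum_u space_conv(a[, u], b[, t - u + 1])
  # do it as FFT in space for each time pair; cheaper: full FFT in
  # space then direct causal convolution in time on the transformed
  # columns
  conv_t <- matrix(0 + 0i, n, nT)
  for (t in seq_len(nT)) {
    u <- seq_len(t)
    ft <- fa[, u, drop = FALSE] * fb[, t - u + 1L, drop = FALSE]
    conv_t[, t] <- if (length(u) == 1L) ft[, 1] else rowSums(ft)
  }
  Re(stats::mvfft(conv_t, inverse = TRUE)) / n
}

#' Single protrusive-event template
#'
#' Convolves the transfer function with the Cdc42 puff (circular in
#' space, causal in time), then normalizes: the space-time mean is
#' subtracted so the total sum is exactly zero (constant cell area
#' under superposed events; the compensating retraction is spread
#' uniformly around the contour, i.e. a weak global contraction that
#' carries no net directional motion), and the whole template is
#' scaled to peak speed 1.
#'
#' @inheritParams make_transfer_function
#' @return `n_markers x t_len` matrix summing to 0 with maximum 1.
#' @export
single_event_template <- function(params = event_template_params(),
                                  n_markers = 100L) {
  k <- make_transfer_function(params, n_markers)
  n <- nrow(k)
  s <- 0:(n - 1L)
  tt <- 0:(params$t_len - 1L)
  puff <- outer(circ_gauss(s, params$sigma_puff, n),
                exp(-tt / params$tau_puff))
  ev <- conv_space_time(k, puff)
  ev <- ev - mean(ev)
  ev / max(ev)
}

#' Duration and spatial footprint of an event template
#'
#' Duration: number of frames where the template's maximum |speed|
#' exceeds `frac` of its global maximum.  Footprint: maximum number of
#' markers simultaneously above `frac` of the global maximum of the
#' positive part.
#'
#' @param template matrix from [single_event_template()].
#' @param frac detection fraction (default 0.1).
#' @return list with `duration_frames`, `footprint_markers`.
#' @export
event_footprint <- function(template, frac = 0.1) {
  peak <- max(abs(template))
  col_max <- apply(abs(template), 2, max)
  pos_peak <- max(template)
  width <- max(apply(template > frac * pos_peak, 2, sum))
  list(duration_frames = sum(col_max > frac * peak),
       footprint_markers = width)
}
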