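## Synthetic-data generators: ground truth for every downstream stage.
## Persistent-random-walk tracks with known persistence time, contour
## movies realizing a known morphodynamic map, trafficking stacks whose
## intensity lags a protrusion map by a known delay, and noisy blob
## images for segmentation.  All generators are deterministic under a
## fixed seed.

#' Parameters of a persistent random walk
#'
#' @param speed cell speed (length per unit time).
#' @param tau persistence time: the heading performs a mean-zero
#'   angular random walk with increments `Normal(0, sqrt(2*dt/tau))`,
#'   whose direction autocorrelation is exactly `exp(-lag/tau)`.
#'   `Inf` gives a perfectly straight track.
#' @param dt time per frame.
#' @param n_frames number of positions (>= 2).
#' @param seed integer RNG seed (optional).
#' @return a `prw_params` list.
#' @export
prw_params <- function(speed = 1, tau = 120, dt = 5, n_frames = 200L,
                       seed = NULL) {
  assert_that(is.numeric(tau) && tau > 0, "tau must be positive")
  assert_that(is.numeric(dt) && dt > 0, "dt must be positive")
  assert_that(n_frames >= 2, "n_frames must be >= 2")
  structure(list(speed = speed, tau = tau, dt = dt,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "prw_params")
}

#' Generate a persistent-random-walk trajectory
#'
#' @param params a [prw_params()] object (or arguments forwarded to it).
#' @param ... used instead of `params` for convenience.
#' @return a data.frame with columns `frame` (0-based), `time`, `x`,
#'   `y` and attribute `dt`.
#' @examples
#' tr <- gen_prw_trajectory(prw_params(tau = 120, dt = 5, seed = 1))
#' @export
gen_prw_trajectory <- function(params = prw_params(...), ...) {
  p <- params
  with_seed(p$seed, {
    n <- p$n_frames
    sd_step <- if (is.finite(p$tau)) sqrt(2 * p$dt / p$tau) else 0
    theta <- cumsum(c(stats::runif(1, -pi, pi),
                      stats::rnorm(n - 2L, 0, sd_step)))
    step <- p$speed * p$dt
    x <- c(0, cumsum(step * cos(theta)))
    y <- c(0, cumsum(step * sin(theta)))
    out <- data.frame(frame = 0:(n - 1L), time = (0:(n - 1L)) * p$dt,
                      x = x, y = y)
    attr(out, "dt") <- p$dt
    out
  })
}

# TRUE if no two non-adjacent edges of the closed polygon intersect
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]        # skip edges sharing a vertex
    if (!length(js)) next
    d1x <- p2[i, 1] - p1[i, 1]; d1y <- p2[i, 2] - p1[i, 2]
    o1 <- cross2(d1x, d1y, p1[js, 1] - p1[i, 1], p1[js, 2] - p1[i, 2])
    o2 <- cross2(d1x, d1y, p2[js, 1] - p1[i, 1], p2[js, 2] - p1[i, 2])
    d2x <- p2[js, 1] - p1[js, 1]; d2y <- p2[js, 2] - p1[js, 2]
    o3 <- cross2(d2x, d2y, p1[i, 1] - p1[js, 1], p1[i, 2] - p1[js, 2])
    o4 <- cross2(d2x, d2y, p2[i, 1] - p1[js, 1], p2[i, 2] - p1[js, 2])
    if (any(o1 * o2 < 0 & o3 * o4 < 0)) return(FALSE)
  }
  TRUE
}

#' Realize a contour movie from a morphodynamic map
#'
#' Inverts map quantification: starting from `initial_contour`, each
#' frame's markers are displaced along the current outward normal by
#' the corresponding map column (times `dt`), explicit Euler.  Valid
#' for small per-frame steps (|v| * dt much smaller than the cell
#' radius).  If the evolving contour self-intersects, the movie is
#' truncated at the last simple frame with a warning.
#'
#' @param truth_map matrix (or `morphomap`) with one row per marker and
#'   one column per frame transition; positive = outward.
#' @param initial_contour simple closed polygon (`n x 2`); it is
#'   resampled to `nrow(truth_map)` markers.
#' @param dt time per frame (default the map's `dt` or 1).
#' @return a `contour_sequence`: list with `contours` (list of marker
#'   matrices, length `ncol(truth_map) + 1`), `dt`, and
#'   `truncated_at` (`NA` or the first dropped frame index).
#' @export
gen_contour_movie <- function(truth_map, initial_contour, dt = NULL) {
  vals <- unclass(truth_map)
  if (is.null(dt)) dt <- if (!is.null(attr(truth_map, "dt")))
    attr(truth_map, "dt") else 1
  n <- nrow(vals)
  cur <- unclass(resample_contour(initial_contour, n))
  attributes(cur) <- attributes(cur)["dim"]
  contours <- vector("list", ncol(vals) + 1L)
  contours[[1L]] <- cur
  truncated_at <- NA_integer_
  for (t in seq_len(ncol(vals))) {
    nrm <- outward_normals(cur)
    v <- vals[, t]
    v[!is.finite(v)] <- 0
    nxt <- cur + nrm * (v * dt)
    # an inverted (area sign flip) or self-crossing contour is invalid
    if (polygon_area_signed(nxt) <= 0 || !polygon_is_simple(nxt)) {
      warning(sprintf(
        "contour self-intersects at frame %d; movie truncated", t + 1L))
      truncated_at <- t + 1L
      contours <- contours[seq_len(t)]
      break
    }
    contours[[t + 1L]] <- nxt
    cur <- nxt
  }
  structure(list(contours = contours, dt = dt, truncated_at = truncated_at),
            class = "contour_sequence")
}

#' @export
print.contour_sequence <- function(x, ...) {
  cat(sprintf("contour_sequence: %d frames, %d vertices, dt = %g\n",
              length(x$contours), nrow(x$contours[[1]]), x$dt))
  invisible(x)
}

#' Generate a trafficking image stack lagging a protrusion map
#'
#' Builds a radially organized synthetic cell: a disk of radius
#' `cell_radius` centered in a square image, markers at angles
#' `2*pi*i/n` on its boundary and the Golgi at the center.  The
#' intensity painted along the ray towards marker `i` at frame `t` is
#' `max(protrusion_map[i, t - lag_frames], 0)` plus Gaussian noise
#' (secretion trails protrusion; retractions produce no signal).
#'
#' @param protrusion_map matrix, markers x frames.
#' @param lag_frames integer delay in frames (>= 0).
#' @param noise_sd Gaussian pixel noise SD (>= 0).
#' @param cell_radius,golgi_radius geometry in pixels.
#' @param seed RNG seed for the noise.
#' @return list with `stack` (h x w x T array), `truth_rays`
#'   (markers x T matrix of noiseless ray values), `contour` (marker
#'   polygon), `markers`, `golgi_centroid` (x, y, 0-based pixel
#'   centers), `golgi_mask` (logical matrix), `lag_frames`.
#' @export
gen_trafficking_stack <- function(protrusion_map, lag_frames = 0L,
                                  noise_sd = 0, cell_radius = 40,
                                  golgi_radius = 5, seed = NULL) {
  vals <- unclass(protrusion_map)
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(lag_frames >= 0, "lag_frames must be >= 0")
  lag_frames <- as.integer(round(lag_frames))
  n <- nrow(vals); nT <- ncol(vals)
  side <- as.integer(ceiling(2 * cell_radius + 11))
  cx <- (side - 1) / 2; cy <- (side - 1) / 2

  ang <- 2 * pi * (seq_len(n) - 1L) / n
  contour <- cbind(cx + cell_radius * cos(ang), cy + cell_radius * sin(ang))

  # pixel -> nearest-ray assignment inside the annulus golgi..contour
  px <- matrix(0:(side - 1), side, side, byrow = TRUE)   # x = column
  py <- matrix(0:(side - 1), side, side)                 # y = row
  r2 <- (px - cx)^2 + (py - cy)^2
  inside <- r2 <= cell_radius^2 & r2 > golgi_radius^2
  pa <- wrap_2pi(atan2(py - cy, px - cx))
  ray_id <- (round(pa / (2 * pi) * n) %% n) + 1L

  shifted <- matrix(0, n, nT)
  if (lag_frames < nT)
    shifted[, (lag_frames + 1L):nT] <- pmax(vals, 0)[, 1:(nT - lag_frames),
                                                     drop = FALSE]
  stack <- array(0, dim = c(side, side, nT))
  with_seed(seed, {
    for (t in seq_len(nT)) {
      fr <- matrix(0, side, side)
      fr[inside] <- shifted[ray_id[inside], t]
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(side * side, 0, noise_sd), side, side)
      stack[, , t] <- fr
    }
  })
  list(stack = stack, truth_rays = shifted, contour = contour,
       markers = contour, golgi_centroid = c(x = cx, y = cy),
       golgi_mask = r2 <= golgi_radius^2, lag_frames = lag_frames)
}

#' Generate a noisy image of disk-shaped blobs
#'
#' @param n_blobs number of blobs.
#' @param radii radius (px) per blob, recycled.
#' @param intensities peak intensity per blob, recycled.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param dim image size `c(rows, cols)`.
#' @param centers optional `n x 2` matrix of (x, y) centers (0-based
#'   pixel centers); random well-separated interior positions
#'   otherwise.
#' @return list with `image` (matrix) and `centroids` (`n x 2` matrix
#'   of true centers, columns x, y).
#' @export
gen_blob_image <- function(n_blobs = 1L, radii = 8, intensities = 1,
                           noise_sd = 0, seed = NULL, dim = c(96L, 96L),
                           centers = NULL) {
  radii <- rep_len(radii, n_blobs)
  intensities <- rep_len(intensities, n_blobs)
  h <- dim[1]; w <- dim[2]
  with_seed(seed, {
    if (is.null(centers)) {
      centers <- matrix(NA_real_, n_blobs, 2)
      for (b in seq_len(n_blobs)) {
        repeat {
          cand <- c(stats::runif(1, radii[b] + 2, w - radii[b] - 3),
                    stats::runif(1, radii[b] + 2, h - radii[b] - 3))
          if (b == 1L) { centers[b, ] <- cand; break }
          prev <- centers[seq_len(b - 1L), , drop = FALSE]
          sep <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
          # keep blobs far enough apart that morphological closing
          # cannot bridge them
          if (all(sep > radii[b] + radii[seq_len(b - 1L)] + 12)) {
            centers[b, ] <- cand; break
          }
        }
      }
    } else {
      centers <- matrix(centers, ncol = 2)
    }
    px <- matrix(0:(w - 1), h, w, byrow = TRUE)
    py <- matrix(0:(h - 1), h, w)
    img <- matrix(0, h, w)
    for (b in seq_len(n_blobs)) {
      disk <- (px - centers[b, 1])^2 + (py - centers[b, 2])^2 <= radii[b]^2
      img[disk] <- pmax(img[disk], intensities[b])
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    list(image = img, centroids = centers)
  })
}
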