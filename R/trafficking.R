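## Trafficking maps: mean fluorescence intensity along rays from the
## Golgi centroid to each contour marker, and their cross-correlation
## with morphodynamic maps to extract the protrusion-to-secretion time
## lag.

# bilinear interpolation of image values at (x, y) points
# (0-based pixel centers, x = column, y = row)
interp_image <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  v00 <- image[cbind(i0, j0)];     v01 <- image[cbind(i0, j0 + 1)]
  v10 <- image[cbind(i0 + 1, j0)]; v11 <- image[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Build a trafficking map from an image stack
#'
#' For each frame and each contour marker, intensity is sampled by
#' bilinear interpolation at `ceiling(ray length)` evenly spaced points
#' along the segment from the Golgi centroid to the marker; samples
#' falling inside the Golgi mask are excluded (the Golgi's own bright
#' signal would otherwise dominate every ray), and the value is the
#' mean of the remaining samples.  A ray fully inside the mask yields
#' `NA`.
#'
#' @param stack h x w x T numeric array (or list of matrices).
#' @param golgi_centroid c(x, y) or T x 2 matrix (0-based pixel
#'   centers).
#' @param markers n x 2 marker matrix, or a list of per-frame marker
#'   matrices (e.g. from a `morphomap`'s `markers` attribute).
#' @param golgi_mask logical matrix, or list of per-frame masks, or
#'   `NULL` for no exclusion.
#' @param dt time per frame.
#' @return a `morphomap`-classed matrix (n markers x T) of mean ray
#'   intensities with attribute `dt`.
#' @export
build_trafficking_map <- function(stack, golgi_centroid, markers,
                                  golgi_mask = NULL, dt = 1) {
  if (is.list(stack)) stack <- array(unlist(stack),
                                     c(dim(stack[[1]]), length(stack)))
  nT <- dim(stack)[3]
  per_frame_markers <- is.list(markers)
  n <- if (per_frame_markers) nrow(markers[[1]]) else nrow(markers)
  gc <- if (is.matrix(golgi_centroid)) golgi_centroid
        else matrix(golgi_centroid, nT, 2, byrow = TRUE)
  vals <- matrix(NA_real_, n, nT)
  for (t in seq_len(nT)) {
    img <- stack[, , t]
    mk <- if (per_frame_markers) markers[[t]] else markers
    if (is.null(mk)) next
    msk <- if (is.null(golgi_mask)) NULL
           else if (is.list(golgi_mask)) golgi_mask[[t]] else golgi_mask
    for (i in seq_len(n)) {
      len <- sqrt((mk[i, 1] - gc[t, 1])^2 + (mk[i, 2] - gc[t, 2])^2)
      ns <- max(2L, ceiling(len))
      f <- seq(0, 1, length.out = ns)
      sx <- gc[t, 1] + f * (mk[i, 1] - gc[t, 1])
      sy <- gc[t, 2] + f * (mk[i, 2] - gc[t, 2])
      if (!is.null(msk)) {
        ins <- msk[cbind(pmin(pmax(round(sy), 0), nrow(msk) - 1) + 1,
                         pmin(pmax(round(sx), 0), ncol(msk) - 1) + 1)]
        sx <- sx[!ins]; sy <- sy[!ins]
      }
      if (!length(sx)) next
      vals[i, t] <- mean(interp_image(img, sx, sy))
    }
  }
  new_morphomap(vals, dt = dt)
}

#' Normalize an image stack to the first frame's intensity statistics
#'
#' Rescales every frame linearly so its mean and standard deviation
#' match frame 1, removing global intensity drift (photobleaching)
#' before map building.  Because the downstream lag estimate is
#' invariant to affine intensity changes, any residual difference from
#' other drift-correction schemes does not propagate.
#'
#' @param stack h x w x T numeric array.
#' @return normalized array of the same shape.
#' @export
normalize_stack <- function(stack) {
  nT <- dim(stack)[3]
  assert_that(!is.na(nT) && nT >= 2, "need at least two frames")
  m0 <- mean(stack[, , 1]); s0 <- stats::sd(as.vector(stack[, , 1]))
  out <- stack
  for (t in 2:nT) {
    mt <- mean(stack[, , t]); st <- stats::sd(as.vector(stack[, , t]))
    out[, , t] <- if (st > 0) (stack[, , t] - mt) / st * s0 + m0
                  else stack[, , t] - mt + m0
  }
  out
}

#' Cross-correlate a morphodynamic map with a trafficking map
#'
#' Per marker row, the mean-subtracted, variance-normalized
#' cross-covariance of the two time series is computed for lags
#' `-max_lag .. +max_lag` and averaged over rows.  A positive peak lag
#' means protrusion precedes trafficking: the coefficient at lag `L`
#' pairs protrusion at time `t` with trafficking at time `t + L`.
#'
#' @param morphomap,trafficking_map matrices of identical shape with
#'   rows registered marker-for-marker.
#' @param max_lag largest lag in frames (default one third of the
#'   duration).
#' @param dt time per frame (default from `morphomap`).
#' @return an `xcorr_result` list: `lag` (time units), `cc` (mean
#'   curve), `per_row` (matrix rows x lags), `peak_lag` (sub-frame,
#'   from [extract_peak_lag()]), `dt`.
#' @export
crosscorrelate_maps <- function(morphomap, trafficking_map, max_lag = NULL,
                                dt = NULL) {
  a <- unclass(morphomap); b <- unclass(trafficking_map)
  assert_that(all(dim(a) == dim(b)), "maps have different shapes")
  if (is.null(dt)) dt <- if (!is.null(attr(morphomap, "dt")))
    attr(morphomap, "dt") else 1
  nT <- ncol(a)
  if (is.null(max_lag)) max_lag <- max(1L, floor(nT / 3))
  max_lag <- min(max_lag, nT - 2L)
  lags <- -max_lag:max_lag
  n <- nrow(a)
  per_row <- matrix(NA_real_, n, length(lags))
  for (i in seq_len(n)) {
    xi <- a[i, ]; yi <- b[i, ]
    ok <- is.finite(xi) & is.finite(yi)
    if (sum(ok) < max(5, max_lag + 2)) next        # drop sparse rows
    if (stats::sd(xi[ok]) == 0 || stats::sd(yi[ok]) == 0) next
    xi <- xi - mean(xi[ok]); yi <- yi - mean(yi[ok])
    xi[!ok] <- NA; yi[!ok] <- NA
    for (k in seq_along(lags)) {
      L <- lags[k]
      if (L >= 0) { u <- xi[1:(nT - L)]; v <- yi[(1 + L):nT] }
      else        { u <- xi[(1 - L):nT]; v <- yi[1:(nT + L)] }
      good <- is.finite(u) & is.finite(v)
      if (sum(good) < 3) next
      norm <- sqrt(mean(u[good]^2) * mean(v[good]^2))
      if (norm == 0) next
      per_row[i, k] <- mean(u[good] * v[good]) / norm
    }
  }
  cc <- colMeans(per_row, na.rm = TRUE)
  res <- structure(list(lag = lags * dt, cc = cc, per_row = per_row,
                        dt = dt), class = "xcorr_result")
  res$peak_lag <- tryCatch(extract_peak_lag(res)$lag,
                           error = function(e) NA_real_)
  res
}

#' Sub-frame peak lag of a cross-correlation curve
#'
#' Fits a quadratic through the maximum of the curve and its two
#' neighbors; its vertex gives the lag at sub-frame resolution.  A
#' maximum at the domain edge is flagged and returned without the
#' quadratic refinement.
#'
#' @param xcorr an `xcorr_result` (or list with `lag`, `cc`).
#' @return list with `lag` (time units of `lag`), `cc_peak`,
#'   `at_edge` (logical).
#' @export
extract_peak_lag <- function(xcorr) {
  lag <- xcorr$lag; cc <- xcorr$cc
  ok <- is.finite(cc)
  assert_that(sum(ok) >= 3, "cross-correlation curve too short")
  k <- which.max(replace(cc, !ok, -Inf))
  if (k == 1L || k == length(cc) || !ok[k - 1] || !ok[k + 1]) {
    return(list(lag = lag[k], cc_peak = cc[k], at_edge = TRUE))
  }
  dl <- lag[2] - lag[1]
  y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 1), -1)
  list(lag = lag[k] + delta * dl,
       cc_peak = y2 - 0.25 * (y1 - y3) * delta,
       at_edge = FALSE)
}
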