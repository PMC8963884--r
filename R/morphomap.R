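## Morphodynamic maps: markers x time arrays of signed cell-edge speeds
## (protrusion positive, retraction negative) built from consecutive
## closed contours.

#' Resample a closed contour into equidistant markers
#'
#' The contour is forced counterclockwise and divided into `n_markers`
#' points equally spaced in arclength.  The first marker is anchored at
#' the arclength position of the vertex whose direction from the
#' contour centroid has the smallest angle from the +x axis (a fixed
#' convention that makes resampling deterministic; frame-to-frame
#' marker pairing removes any residual dependence on it).
#'
#' @param polygon a two-column matrix (x, y) of vertices of a simple
#'   closed polygon (not repeated at the end), at least 3 vertices.
#' @param n_markers number of markers (default 100).
#' @return a `marker_set`: an `n_markers` x 2 matrix of marker
#'   positions with attributes `centroid` and `perimeter`.
#' @export
resample_contour <- function(polygon, n_markers = 100L) {
  polygon <- as.matrix(polygon)
  assert_that(ncol(polygon) == 2 && nrow(polygon) >= 3,
              "polygon must be an n x 2 matrix with >= 3 vertices")
  assert_that(all(is.finite(polygon)), "polygon has non-finite vertices")
  n_markers <- as.integer(n_markers)
  assert_that(n_markers >= 3, "n_markers must be >= 3")
  polygon <- ensure_ccw(polygon)

  edge <- rbind(polygon[-1, , drop = FALSE], polygon[1, , drop = FALSE]) -
    polygon
  seg_len <- sqrt(rowSums(edge^2))
  perim <- sum(seg_len)
  assert_that(perim > 0, "degenerate polygon: zero perimeter")

  centroid <- colMeans(polygon)
  # start at the vertex closest in angle (about the centroid) to +x
  ang <- wrap_2pi(atan2(polygon[, 2] - centroid[2],
                        polygon[, 1] - centroid[1]))
  start <- which.min(ang)
  ord <- c(start:nrow(polygon), seq_len(start - 1L))
  polygon <- polygon[ord, , drop = FALSE]
  seg_len <- seg_len[ord]

  cum <- c(0, cumsum(seg_len))           # arclength at each vertex
  s <- perim * (seq_len(n_markers) - 1L) / n_markers
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg[seg > nrow(polygon)] <- nrow(polygon)
  frac <- (s - cum[seg]) / seg_len[seg]
  frac[!is.finite(frac)] <- 0            # zero-length edges
  nxt <- c(2:nrow(polygon), 1L)
  pts <- polygon[seg, , drop = FALSE] +
    frac * (polygon[nxt[seg], , drop = FALSE] - polygon[seg, , drop = FALSE])
  structure(pts, centroid = centroid, perimeter = perim,
            class = c("marker_set", "matrix", "array"))
}

#' Pair markers of consecutive frames by exhaustive circular-shift search
#'
#' Finds the circular index shift `s*` minimizing the total squared
#' distance `sum_i |m_i(t) - m_(i+s)(t+dt)|^2` over all `n` candidate
#' shifts.  Ties are broken towards the smallest `|s|`, then the
#' smallest signed `s` (shifts reported in (-n/2, n/2]).
#'
#' @param markers_t,markers_t1 `n x 2` marker matrices of the two
#'   frames, same marker count and orientation.
#' @return a list with `shift` (signed integer), `sq_dist` (the
#'   minimized total squared distance), `displacement` (`n x 2` matrix,
#'   paired marker of frame t+dt minus marker of frame t), and
#'   `pairing` (index into `markers_t1` for each row of `markers_t`).
#' @export
match_contours <- function(markers_t, markers_t1) {
  a <- unclass(markers_t); b <- unclass(markers_t1)
  n <- nrow(a)
  assert_that(nrow(b) == n, "marker counts differ between frames")
  idx <- seq_len(n)
  total <- vapply(0:(n - 1L), function(s) {
    j <- ((idx - 1L + s) %% n) + 1L
    sum((a - b[j, , drop = FALSE])^2)
  }, numeric(1))
  signed <- circ_offset(0:(n - 1L), 0L, n)
  # order candidates: by sq dist, then |s|, then s
  ord <- order(total, abs(signed), signed)
  best <- ord[1L]
  s <- as.integer(0:(n - 1L))[best]
  j <- ((idx - 1L + s) %% n) + 1L
  list(shift = as.integer(signed[best]),
       sq_dist = total[best],
       displacement = b[j, , drop = FALSE] - a,
       pairing = j)
}

# outward normals of a counterclockwise marker set, from the local
# tangent smoothed over a (2k+1)-marker window to resist vertex noise
outward_normals <- function(markers, half_window = 2L) {
  n <- nrow(markers)
  k <- min(half_window, (n - 1L) %/% 2L)
  ip <- ((seq_len(n) - 1L + k) %% n) + 1L
  im <- ((seq_len(n) - 1L - k) %% n) + 1L
  tang <- markers[ip, , drop = FALSE] - markers[im, , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  len[len == 0] <- 1
  tang <- tang / len
  # CCW travel keeps the interior on the left; outward = tangent
  # rotated -90 degrees
  cbind(tang[, 2], -tang[, 1])
}

#' Build a morphodynamic map from a contour sequence
#'
#' Each frame's contour is resampled into `n_markers` equidistant
#' markers; consecutive frames are paired by [match_contours()]; the
#' map entry `value[i, t]` is the speed of marker `i` between frames
#' `t` and `t+1`, signed by the projection of its displacement on the
#' outward normal at frame `t` (positive = protrusion, negative =
#' retraction).
#'
#' With `displacement = "contour"` (default) the distance traveled by
#' marker `i` is measured to the nearest point of the next contour in
#' the neighborhood of its paired marker.  This suppresses the
#' tangential marker slip that equidistant-arclength resampling
#' produces wherever the contour grows locally (slip that would
#' otherwise be booked as spurious edge speed around the whole ring).
#' `"marker"` uses the raw paired-marker displacement instead.
#'
#' @param contours a list of polygons (two-column matrices), one per
#'   frame, or a `contour_sequence` from [gen_contour_movie()].
#' @param dt time per frame; speeds are per unit of `dt` (default 1,
#'   i.e. px/frame).
#' @param pixel_scale physical length per pixel (default 1).
#' @param n_markers markers per contour (default 100).
#' @param displacement `"contour"` or `"marker"` (see above).
#' @return a `morphomap`: an `n_markers x (T-1)` matrix with attributes
#'   `dt`, `n_markers`, `markers` (list of per-frame marker sets) and
#'   `centroids` (frame centroids).  Frames whose contour is `NULL` or
#'   degenerate yield a column of `NA`.
#' @export
build_morphomap <- function(contours, dt = 1, pixel_scale = 1,
                            n_markers = 100L,
                            displacement = c("contour", "marker")) {
  displacement <- match.arg(displacement)
  if (inherits(contours, "contour_sequence")) contours <- contours$contours
  nT <- length(contours)
  assert_that(nT >= 2, "need at least two frames")
  assert_that(dt > 0, "dt must be positive")
  marker_sets <- vector("list", nT)
  for (t in seq_len(nT)) {
    marker_sets[[t]] <- tryCatch(
      resample_contour(contours[[t]], n_markers),
      error = function(e) NULL)
  }
  n <- as.integer(n_markers)
  vals <- matrix(NA_real_, n, nT - 1L)
  for (t in seq_len(nT - 1L)) {
    a <- marker_sets[[t]]; b <- marker_sets[[t + 1L]]
    if (is.null(a) || is.null(b)) next
    m <- match_contours(a, b)
    disp <- if (displacement == "contour")
      contour_displacement(unclass(a), unclass(b), m$pairing)
    else m$displacement
    nrm <- outward_normals(a)
    proj <- rowSums(disp * nrm)
    speed <- sqrt(rowSums(disp^2)) * pixel_scale / dt
    vals[, t] <- ifelse(proj >= 0, speed, -speed)
  }
  centroids <- t(vapply(marker_sets, function(ms) {
    if (is.null(ms)) c(NA_real_, NA_real_) else attr(ms, "centroid")
  }, numeric(2)))
  new_morphomap(vals, dt = dt, markers = marker_sets, centroids = centroids)
}

new_morphomap <- function(values, dt = 1, markers = NULL, centroids = NULL,
                          recenter_offsets = NULL) {
  structure(values, dt = dt, n_markers = nrow(values), markers = markers,
            centroids = centroids, recenter_offsets = recenter_offsets,
            class = c("morphomap", "matrix", "array"))
}

#' @export
print.morphomap <- function(x, ...) {
  cat(sprintf("morphomap: %d markers x %d frame transitions (dt = %g)\n",
              nrow(x), ncol(x), attr(x, "dt")))
  cat(sprintf("  speed range [%.3g, %.3g]%s\n",
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)),
              if (!is.null(attr(x, "recenter_offsets"))) ", recentered"
              else ""))
  invisible(x)
}

# displacement from each marker of frame t to its nearest point on the
# frame t+1 polyline, searched over the segments adjacent to the paired
# marker (removes the tangential component of arclength resampling)
contour_displacement <- function(a, b, pairing) {
  n <- nrow(a)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- pairing[i]
    cand <- c(((j - 2L) %% n) + 1L, j, (j %% n) + 1L)
    best <- b[j, ]; bd <- sum((b[j, ] - a[i, ])^2)
    for (k in 1:2) {
      p <- b[cand[k], ]; q <- b[cand[k + 1L], ]
      v <- q - p
      L2 <- sum(v^2)
      f <- if (L2 == 0) 0 else min(max(sum((a[i, ] - p) * v) / L2, 0), 1)
      pt <- p + f * v
      d <- sum((pt - a[i, ])^2)
      if (d < bd) { bd <- d; best <- pt }
    }
    out[i, ] <- best - a[i, ]
  }
  out
}

# circularly shift a vector so that entry `from` moves to entry `to`
circshift <- function(v, by) {
  n <- length(v)
  by <- ((by %% n) + n) %% n
  if (by == 0) return(v)
  c(v[(n - by + 1L):n], v[1:(n - by)])
}

#' Recenter a morphodynamic map on a reference axis
#'
#' Circularly shifts each column so that the marker whose direction
#' from the cell centroid is nearest the per-column reference angle
#' sits at the middle row (`floor(n/2) + 1`).  Typical references are
#' the nucleus-to-Golgi direction or the instantaneous direction of
#' motion.  The shift applied to each column is stored so the
#' operation is exactly invertible.
#'
#' @param map a `morphomap` built by [build_morphomap()] (needs its
#'   per-frame marker sets), or any matrix when `marker_angles` is
#'   given.
#' @param reference_angles one angle (radians) per column; `NA` leaves
#'   that column unshifted (flagged in the stored offsets as `NA`).
#' @param marker_angles optional `n x T-1` matrix (or length-n vector)
#'   of marker direction angles about the centroid; defaults to the
#'   angles of the map's own markers.
#' @return the recentered `morphomap` with attribute
#'   `recenter_offsets` (integer row shift applied per column).
#' @export
recenter_map <- function(map, reference_angles, marker_angles = NULL) {
  vals <- unclass(map)
  n <- nrow(vals); nT <- ncol(vals)
  assert_that(length(reference_angles) == nT,
              "need one reference angle per map column")
  if (is.null(marker_angles)) {
    msets <- attr(map, "markers")
    assert_that(!is.null(msets),
                "map carries no marker sets; supply marker_angles")
    marker_angles <- vapply(seq_len(nT), function(t) {
      ms <- msets[[t]]
      if (is.null(ms)) return(rep(NA_real_, n))
      ctr <- attr(ms, "centroid")
      atan2(ms[, 2] - ctr[2], ms[, 1] - ctr[1])
    }, numeric(n))
  }
  if (is.null(dim(marker_angles)))
    marker_angles <- matrix(marker_angles, n, nT)
  mid <- n %/% 2L + 1L
  offsets <- integer(nT)
  out <- vals
  for (t in seq_len(nT)) {
    ref <- reference_angles[t]
    if (!is.finite(ref) || all(!is.finite(marker_angles[, t]))) {
      offsets[t] <- NA_integer_
      next
    }
    d <- abs(wrap_pi(marker_angles[, t] - ref))
    i_star <- which.min(d)
    off <- mid - i_star              # shift moving i_star to mid
    offsets[t] <- as.integer(off)
    out[, t] <- circshift(vals[, t], off)
  }
  new_morphomap(out, dt = attr(map, "dt"), markers = attr(map, "markers"),
                centroids = attr(map, "centroids"),
                recenter_offsets = offsets)
}

#' Undo a recentering
#'
#' Applies the inverse of the per-column shifts stored by
#' [recenter_map()], restoring the original map exactly.
#' @param map a recentered `morphomap`.
#' @return the un-recentered `morphomap`.
#' @export
undo_recenter <- function(map) {
  offsets <- attr(map, "recenter_offsets")
  assert_that(!is.null(offsets), "map has no stored recentering offsets")
  vals <- unclass(map)
  for (t in seq_len(ncol(vals))) {
    if (is.na(offsets[t])) next
    vals[, t] <- circshift(vals[, t], -offsets[t])
  }
  new_morphomap(vals, dt = attr(map, "dt"), markers = attr(map, "markers"),
                centroids = attr(map, "centroids"))
}

#' Average protrusion-speed profile of recentered maps
#'
#' Per-row mean over time within each cell, then over cells, with the
#' across-cell standard deviation.  All maps must be recentered on the
#' same reference so the middle row corresponds to the reference axis.
#'
#' @param maps a single recentered `morphomap` or a list of them, all
#'   with the same marker count.
#' @return a data.frame with columns `marker`, `mean_speed`, `sd_speed`.
#' @export
mean_protrusion_profile <- function(maps) {
  if (inherits(maps, "morphomap") || is.matrix(maps)) maps <- list(maps)
  assert_that(length(maps) > 0, "empty map collection")
  n <- nrow(maps[[1]])
  assert_that(all(vapply(maps, nrow, integer(1)) == n),
              "maps have differing marker counts")
  per_cell <- vapply(maps, function(m) rowMeans(unclass(m), na.rm = TRUE),
                     numeric(n))
  per_cell <- matrix(per_cell, nrow = n)
  data.frame(marker = seq_len(n),
             mean_speed = rowMeans(per_cell),
             sd_speed = apply(per_cell, 1, stats::sd))
}

#' Write / read a morphodynamic map as CSV plus JSON sidecar
#'
#' Rows are markers, columns are frame transitions; metadata (dt,
#' marker count, recentering offsets) goes to `<path>.json`.
#' @param map a `morphomap`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_morphomap <- function(map, path) {
  utils::write.table(unclass(map), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(dt = attr(map, "dt"), n_markers = nrow(map),
               recenter_offsets = attr(map, "recenter_offsets"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_morphomap
#' @export
read_morphomap <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  sidecar <- paste0(path, ".json")
  dt <- 1; offsets <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$dt)) dt <- meta$dt
    if (!is.null(meta$recenter_offsets) && length(meta$recenter_offsets))
      offsets <- as.integer(meta$recenter_offsets)
  }
  new_morphomap(vals, dt = dt, recenter_offsets = offsets)
}

#' Render a morphodynamic map in protrusion/retraction colors
#'
#' Red for protrusion, blue for retraction, on a symmetric scale.
#' @param x a `morphomap`.
#' @param ... passed to [graphics::image()].
#' @export
plot.morphomap <- function(x, ...) {
  v <- unclass(x)
  lim <- max(abs(v), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("blue3", "white", "red3"))(255)
  graphics::image(x = seq_len(ncol(v)) * attr(x, "dt"),
                  y = seq_len(nrow(v)), z = t(v),
                  zlim = c(-lim, lim), col = pal,
                  xlab = "time", ylab = "contour marker", ...)
  invisible(x)
}
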