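## Threshold-based segmentation of fluorescently labeled structures
## (cell body, nucleus, Golgi) and nearest-neighbor centroid tracking
## with stage-jump correction.
##
## Coordinates are 0-based pixel centers with x = column and y = row of
## the image matrix.

#' Segmentation configuration
#'
#' @param threshold `"otsu"` for an automatic gray-level threshold
#'   (Otsu's criterion on the image rescaled to `[0, 1]`), or a fixed
#'   numeric value on the raw intensity scale.  Structure-specific
#'   thresholds can be set per channel by passing different configs.
#' @param min_object_area smallest object kept, in px^2.
#' @param closing_radius radius (px) of the disk structuring element
#'   used for morphological closing (default 10).
#' @param clear_border drop objects touching the image border.
#' @return a `seg_config` list.
#' @export
seg_config <- function(threshold = "otsu", min_object_area = 50,
                       closing_radius = 10, clear_border = TRUE) {
  assert_that(min_object_area >= 0, "min_object_area must be >= 0")
  assert_that(closing_radius >= 0, "closing_radius must be >= 0")
  structure(list(threshold = threshold,
                 min_object_area = min_object_area,
                 closing_radius = closing_radius,
                 clear_border = isTRUE(clear_border)),
            class = "seg_config")
}

# label matrix -> centroids (k x 2, columns x, y; 0-based pixel centers)
label_centroids <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (!length(ids)) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("x", "y"))))
  out <- t(vapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}

#' Segment bright structures in a grayscale image
#'
#' Fixed pipeline: global threshold, binarize, clear objects touching
#' the border, remove small objects, morphological closing with a disk
#' structuring element, hole filling, then one centroid per connected
#' component.  An image with nothing above threshold yields a
#' "no object" result rather than an error.
#'
#' @param image 2-D numeric matrix (rows = y, columns = x).
#' @param config a [seg_config()].
#' @return list with `mask` (logical matrix), `labels` (integer label
#'   matrix), `centroids` (k x 2 matrix, columns `x`, `y`),
#'   `areas` (px^2 per component) and `found` (logical).
#' @export
segment_object <- function(image, config = seg_config()) {
  image <- as.matrix(image)
  assert_that(length(dim(image)) == 2, "image must be a 2-D matrix")
  rng <- range(image, finite = TRUE)
  if (identical(config$threshold, "otsu")) {
    if (diff(rng) == 0) {
      thr <- Inf                      # flat image: nothing segmentable
    } else {
      norm <- (image - rng[1]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(norm))
      thr <- rng[1] + t01 * diff(rng)
    }
  } else {
    thr <- as.numeric(config$threshold)
  }
  bw <- image > thr

  no_object <- function() list(
    mask = matrix(FALSE, nrow(image), ncol(image)),
    labels = matrix(0L, nrow(image), ncol(image)),
    centroids = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))),
    areas = numeric(0), found = FALSE)
  if (!any(bw)) return(no_object())

  lab <- EBImage::bwlabel(bw)
  if (config$clear_border) {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ],
                           lab[, 1], lab[, ncol(lab)]))
    bw[lab %in% border_ids[border_ids > 0]] <- FALSE
  }
  if (config$min_object_area > 0 && any(bw)) {
    lab <- EBImage::bwlabel(bw)
    sizes <- tabulate(lab[lab > 0])
    bw[lab > 0 & sizes[pmax(lab, 1)] < config$min_object_area] <- FALSE
  }
  if (!any(bw)) return(no_object())
  if (config$closing_radius > 0) {
    size <- 2 * round(config$closing_radius) + 1
    brush <- EBImage::makeBrush(size, shape = "disc")
    bw <- EBImage::closing(bw * 1, brush) > 0.5
  }
  bw <- EBImage::fillHull(bw * 1) > 0.5
  if (!any(bw)) return(no_object())
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  cent <- label_centroids(lab)
  areas <- tabulate(lab[lab > 0])
  list(mask = bw, labels = lab, centroids = cent, areas = areas,
       found = TRUE)
}

#' Track a centroid through frames by nearest-neighbor selection
#'
#' In each frame the candidate centroid closest to the previously
#' selected one is kept (the "search area" rule that disambiguates
#' multiple detected structures).  Frames with no candidate carry the
#' previous position forward and are flagged.
#'
#' @param centroid_list list (one element per frame) of k x 2 candidate
#'   centroid matrices; `NULL` or 0-row entries are gaps.
#' @param initial c(x, y) used to select the frame-1 centroid; defaults
#'   to the first candidate of the first non-empty frame.
#' @return data.frame with columns `frame` (0-based), `x`, `y`,
#'   `gap` (logical).
#' @export
track_centroids <- function(centroid_list, initial = NULL) {
  nT <- length(centroid_list)
  has <- vapply(centroid_list, function(cc) !is.null(cc) && nrow(cc) > 0,
                logical(1))
  assert_that(any(has), "no candidate centroid in any frame")
  if (is.null(initial)) initial <- centroid_list[[which(has)[1]]][1, 1:2]
  prev <- as.numeric(initial)
  x <- y <- numeric(nT); gap <- logical(nT)
  for (t in seq_len(nT)) {
    cc <- centroid_list[[t]]
    if (is.null(cc) || nrow(cc) == 0) {
      x[t] <- prev[1]; y[t] <- prev[2]; gap[t] <- TRUE
      next
    }
    d2 <- (cc[, 1] - prev[1])^2 + (cc[, 2] - prev[2])^2
    sel <- which.min(d2)
    prev <- as.numeric(cc[sel, 1:2])
    x[t] <- prev[1]; y[t] <- prev[2]
  }
  data.frame(frame = 0:(nT - 1L), x = x, y = y, gap = gap)
}

#' Correct stage-movement jumps in a tracked trajectory
#'
#' When the microscope stage follows the cell, the image-coordinate
#' track jumps by the stage displacement; adding back the recorded
#' stage positions (scaled to pixels) recovers the physical path:
#' `corrected(t) = raw(t) + scale * (stage(t) - stage(1))`.
#'
#' @param track data.frame with columns `x`, `y` (image coordinates).
#' @param stage_positions matrix or data.frame with one (x, y) stage
#'   position per frame, in stage units.
#' @param pixel_scale pixels per stage unit.
#' @return the track with `x`, `y` replaced by corrected coordinates.
#' @export
correct_stage_jumps <- function(track, stage_positions, pixel_scale = 1) {
  sp <- as.matrix(stage_positions)
  assert_that(nrow(sp) == nrow(track),
              "stage positions and track have different lengths")
  out <- track
  out$x <- track$x + pixel_scale * (sp[, 1] - sp[1, 1])
  out$y <- track$y + pixel_scale * (sp[, 2] - sp[1, 2])
  out
}

#' Segment and track one structure through an image stack
#'
#' Convenience wrapper: [segment_object()] per frame, then
#' [track_centroids()], optionally followed by
#' [correct_stage_jumps()].
#'
#' @param stack h x w x T numeric array.
#' @param config a [seg_config()].
#' @param initial optional c(x, y) seed point.
#' @param stage_positions,pixel_scale optional stage-jump correction.
#' @return data.frame as [track_centroids()].
#' @export
track_structure <- function(stack, config = seg_config(), initial = NULL,
                            stage_positions = NULL, pixel_scale = 1) {
  cents <- lapply(seq_len(dim(stack)[3]), function(t)
    segment_object(stack[, , t], config)$centroids)
  tr <- track_centroids(cents, initial)
  if (!is.null(stage_positions))
    tr <- correct_stage_jumps(tr, stage_positions, pixel_scale)
  tr
}
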