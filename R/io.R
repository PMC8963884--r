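## Plain-text and TIFF I/O.  Tracks travel as CSV with header
## `frame,time_min,x,y[,nucleus_x,nucleus_y,golgi_x,golgi_y]`; contours
## as long CSV `frame,vertex,x,y`; image stacks as multi-page TIFF.

#' Write / read a track CSV
#'
#' @param track data.frame with columns `frame`, `time` (minutes), `x`,
#'   `y`, optionally `nucleus_x`, `nucleus_y`, `golgi_x`, `golgi_y`.
#' @param path file path.
#' @return `path` (write) or the track data.frame with attribute `dt`
#'   (read).
#' @export
write_track_csv <- function(track, path) {
  out <- track
  names(out)[names(out) == "time"] <- "time_min"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "time_min"] <- "time"
  if (nrow(df) > 1 && "time" %in% names(df))
    attr(df, "dt") <- stats::median(diff(df$time))
  df
}

#' Write / read a contour sequence as long CSV (`frame,vertex,x,y`)
#'
#' @param contours a `contour_sequence` or list of polygons.
#' @param path file path.
#' @param dt time per frame (read; stored nowhere in the CSV).
#' @export
write_contours_csv <- function(contours, path) {
  if (inherits(contours, "contour_sequence")) contours <- contours$contours
  rows <- lapply(seq_along(contours), function(t) {
    cc <- contours[[t]]
    data.frame(frame = t - 1L, vertex = seq_len(nrow(cc)) - 1L,
               x = cc[, 1], y = cc[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path, dt = 1) {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  contours <- lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    sub <- sub[order(sub$vertex), ]
    cbind(sub$x, sub$y)
  })
  structure(list(contours = contours, dt = dt, truncated_at = NA_integer_),
            class = "contour_sequence")
}

#' Write / read a numeric image stack as multi-page TIFF
#'
#' Intensities are stored as 32-bit float so arbitrary scales
#' round-trip exactly.
#'
#' @param stack h x w x T numeric array (or matrix for one page).
#' @param path file path.
#' @export
write_stack_tiff <- function(stack, path) {
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(t) stack[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}
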