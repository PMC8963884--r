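## Angle and circular-statistics helpers shared across modules.
## All angles are radians internally; user-facing summaries are degrees
## where the field reports degrees.

#' Wrap angles to (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return wrapped angles in (-pi, pi].
#' @keywords internal
wrap_pi <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the +pi representative
  out[out == -pi] <- pi
  out
}

#' Wrap angles to [0, 2*pi)
#' @param theta numeric vector of angles in radians.
#' @keywords internal
wrap_2pi <- function(theta) theta %% (2 * pi)

#' Mean resultant length of a set of angles
#'
#' The angular dispersion r = sqrt(mean(sin)^2 + mean(cos)^2): 1 for
#' identical angles, 0 for uniformly dispersed angles.
#'
#' @param theta angles in radians; `NA`s are dropped.
#' @return scalar in `[0, 1]`.
#' @keywords internal
mean_resultant_length <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NA_real_)
  sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
}

#' Circular mean of angles (radians)
#' @keywords internal
circ_mean <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NA_real_)
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' Circular standard deviation, sqrt(-2 log rbar), radians
#' @keywords internal
circ_sd <- function(theta) {
  r <- mean_resultant_length(theta)
  if (is.na(r)) return(NA_real_)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r))
}

#' Signed shortest circular offset between marker indices
#'
#' Offset from `from` to `to` on a circle of `n` positions, in
#' (-n/2, n/2].
#' @keywords internal
circ_offset <- function(to, from, n) {
  d <- (to - from) %% n
  d[d > n / 2] <- d[d > n / 2] - n
  d
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or removes) the caller's `.Random.seed` afterwards so that
#' seeded generators do not perturb the global RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed and integer indices
#'
#' Deterministic, order-sensitive mixing kept below 2^31 so the result
#' is a valid R integer seed.
#' @keywords internal
derive_seed <- function(base, ...) {
  idx <- c(...)
  x <- as.double(base) %% 2147483629
  for (k in idx) {
    x <- (x * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(x)
}

#' Stop unless a condition holds
#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Polygon area (shoelace), signed: positive for counterclockwise
#' @param xy two-column matrix of vertices (closed implicitly).
#' @keywords internal
polygon_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Force a polygon to counterclockwise orientation
#' @keywords internal
ensure_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  else xy
}
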