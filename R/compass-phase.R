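## Phase diagrams of the compass model over (p_polarized, kappa) and
## inverse estimation of the two feedback parameters from measured
## observables (persistence time, protrusive unicity, alignment).

#' Phase diagrams of persistence time, unicity and alignment
#'
#' Runs the compass simulation over a grid of `(p_polarized, kappa)`
#' values with `replicates` seeded realizations per node and records
#' the mean (and SD) of the three observables.  Censored persistence
#' times (trajectories straighter than the run can resolve) enter the
#' mean at the censoring bound `t_tot * dt`, so the superpersistent
#' corner is well defined.
#'
#' @param p_grid,k_grid grid values in `[0, 1]` (default
#'   `seq(0, 1, by = 0.1)`).
#' @param replicates realizations per grid node (default 20).
#' @param base_params a [compass_params()]; its `p_polarized` and
#'   `kappa` are overridden per node.
#' @param seed base seed; node/replicate seeds are derived
#'   deterministically from it.
#' @param verbose print progress.
#' @return a `phase_diagram` list: `p_grid`, `k_grid`, matrices `tau`,
#'   `unicity`, `alignment` (and `*_sd`, `tau_censored_frac`) indexed
#'   `[p, k]`, `replicates`, `params`.
#' @export
phase_diagram <- function(p_grid = seq(0, 1, by = 0.1),
                          k_grid = seq(0, 1, by = 0.1),
                          replicates = 20L,
                          base_params = compass_params(),
                          seed = 1L, verbose = FALSE) {
  assert_that(all(p_grid >= 0 & p_grid <= 1) &&
              all(k_grid >= 0 & k_grid <= 1),
              "grids must lie in [0, 1]")
  assert_that(replicates >= 1, "need at least one replicate")
  np <- length(p_grid); nk <- length(k_grid)
  z <- function() matrix(NA_real_, np, nk)
  tau <- tau_sd <- uni <- uni_sd <- ali <- ali_sd <- cens <- z()
  for (i in seq_len(np)) {
    for (j in seq_len(nk)) {
      tv <- uv <- av <- numeric(replicates); cv <- logical(replicates)
      for (r in seq_len(replicates)) {
        pars <- base_params
        pars$p_polarized <- p_grid[i]
        pars$kappa <- k_grid[j]
        pars$seed <- derive_seed(seed, i, j, r)
        obs <- compass_observables(simulate_compass(pars))
        tv[r] <- obs$tau; uv[r] <- obs$unicity; av[r] <- obs$alignment
        cv[r] <- isTRUE(obs$tau_censored)
      }
      tau[i, j] <- mean(tv, na.rm = TRUE)
      tau_sd[i, j] <- stats::sd(tv, na.rm = TRUE)
      uni[i, j] <- mean(uv, na.rm = TRUE)
      uni_sd[i, j] <- stats::sd(uv, na.rm = TRUE)
      ali[i, j] <- mean(av, na.rm = TRUE)
      ali_sd[i, j] <- stats::sd(av, na.rm = TRUE)
      cens[i, j] <- mean(cv)
    }
    if (verbose)
      message(sprintf("phase_diagram: p_polarized = %.2f done", p_grid[i]))
  }
  structure(list(p_grid = p_grid, k_grid = k_grid,
                 tau = tau, tau_sd = tau_sd,
                 unicity = uni, unicity_sd = uni_sd,
                 alignment = ali, alignment_sd = ali_sd,
                 tau_censored_frac = cens,
                 replicates = as.integer(replicates),
                 params = base_params, seed = seed),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "phase_diagram: %d x %d grid, %d replicates, t_tot = %d frames\n",
    length(x$p_grid), length(x$k_grid), x$replicates, x$params$t_tot))
  invisible(x)
}

# bilinear interpolation of a grid surface at scattered points
bilinear <- function(xg, yg, z, x, y) {
  ix <- pmin(pmax(findInterval(x, xg), 1L), length(xg) - 1L)
  iy <- pmin(pmax(findInterval(y, yg), 1L), length(yg) - 1L)
  fx <- (x - xg[ix]) / (xg[ix + 1L] - xg[ix])
  fy <- (y - yg[iy]) / (yg[iy + 1L] - yg[iy])
  z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    z[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Estimate the feedback parameters from measured observables
#'
#' Inverts the phase diagrams: minimizes
#' `sum_obs ((simulated - measured) / spread_obs)^2` over
#' `(p_polarized, kappa)` on a fine search grid.  The spread of each
#' observable defaults to the SD of its values over the whole diagram
#' (so all observables contribute on comparable scales); pass
#' `spreads` to use measured uncertainties instead.  With `alignment`
#' missing (e.g. a dispersed Golgi), the fit uses the remaining two
#' observables and is flagged.
#'
#' Because the diagram nodes are Monte-Carlo means, the raw surfaces
#' carry sampling noise that can push the argmin around wherever the
#' residual landscape is flat.  With `smooth = "surface"` (default)
#' each observable is first fitted with a degree-3 polynomial response
#' surface in `(p_polarized, kappa)` (the persistence time on a log
#' scale), which filters that noise and makes the estimate stable
#' across diagram seeds; `"none"` interpolates the raw node values
#' bilinearly.  Grids too small for the polynomial fall back to
#' bilinear interpolation.
#'
#' @param diagram a [phase_diagram()].
#' @param tau measured persistence time, same units as the diagram's
#'   `tau` (i.e. `dt` units).
#' @param unicity measured protrusive unicity in `(0, 1]`.
#' @param alignment measured alignment index in `[0, 1]`, or `NULL`.
#' @param spreads optional named vector/list with elements `tau`,
#'   `unicity`, `alignment` overriding the default spreads.
#' @param refine search-grid points per axis (default 101).
#' @param smooth `"surface"` (polynomial response surface, default) or
#'   `"none"` (bilinear interpolation of raw node means).
#' @return list with `p_polarized`, `kappa`, `residual`,
#'   `used_alignment`, `extrapolated` (measured value outside the
#'   simulated range), and `surface` (data.frame of the search grid
#'   with the residual, for contour plots).
#' @export
estimate_parameters <- function(diagram, tau, unicity, alignment = NULL,
                                spreads = NULL, refine = 101L,
                                smooth = c("surface", "none")) {
  smooth <- match.arg(smooth)
  d <- diagram
  meas <- list(tau = tau, unicity = unicity, alignment = alignment)
  surf <- list(tau = d$tau, unicity = d$unicity, alignment = d$alignment)
  use <- c("tau", "unicity", if (!is.null(alignment)) "alignment")
  spread <- lapply(surf, function(z) stats::sd(as.vector(z), na.rm = TRUE))
  if (!is.null(spreads)) {
    for (nm in names(spreads)) spread[[nm]] <- as.numeric(spreads[[nm]])
  }
  extrapolated <- vapply(use, function(nm) {
    rng <- range(surf[[nm]], na.rm = TRUE)
    meas[[nm]] < rng[1] || meas[[nm]] > rng[2]
  }, logical(1))

  pf <- seq(min(d$p_grid), max(d$p_grid), length.out = refine)
  kf <- seq(min(d$k_grid), max(d$k_grid), length.out = refine)
  gp <- rep(pf, times = refine)
  gk <- rep(kf, each = refine)
  deg <- 3L
  can_smooth <- smooth == "surface" &&
    length(d$p_grid) > deg && length(d$k_grid) > deg
  node_df <- expand.grid(p = d$p_grid, k = d$k_grid)
  eval_surface <- function(z, logscale = FALSE) {
    if (!can_smooth)
      return(bilinear(d$p_grid, d$k_grid, z, gp, gk))
    zz <- as.vector(z)
    ok <- is.finite(zz) & (!logscale | zz > 0)
    if (logscale) zz <- log(pmax(zz, .Machine$double.eps))
    fit <- stats::lm(zz[ok] ~ stats::poly(p, deg, raw = TRUE) *
                       stats::poly(k, deg, raw = TRUE),
                     data = node_df[ok, , drop = FALSE])
    out <- stats::predict(fit, data.frame(p = gp, k = gk))
    if (logscale) exp(out) else out
  }
  resid <- rep(0, length(gp))
  for (nm in use) {
    sim <- eval_surface(surf[[nm]], logscale = nm == "tau")
    resid <- resid + ((sim - meas[[nm]]) / spread[[nm]])^2
  }
  best <- which.min(resid)
  list(p_polarized = gp[best], kappa = gk[best],
       residual = resid[best],
       used_alignment = "alignment" %in% use,
       extrapolated = any(extrapolated),
       surface = data.frame(p_polarized = gp, kappa = gk,
                            residual = resid))
}

#' Plot a phase-diagram surface with measured iso-contours
#'
#' @param x a `phase_diagram`.
#' @param which one of `"tau"`, `"unicity"`, `"alignment"`.
#' @param measured optional measured value drawn as a contour line.
#' @param ... passed to [graphics::image()].
#' @export
plot.phase_diagram <- function(x, which = c("tau", "unicity", "alignment"),
                               measured = NULL, ...) {
  which <- match.arg(which)
  z <- x[[which]]
  graphics::image(x$p_grid, x$k_grid, z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "p_polarized", ylab = "kappa", main = which, ...)
  if (!is.null(measured))
    graphics::contour(x$p_grid, x$k_grid, z, levels = measured,
                      add = TRUE, lwd = 2)
  invisible(x)
}
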