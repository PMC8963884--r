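test_that("transfer function terms have the stated structure", {
  # single positive term: separable Gaussian x exponential
  p1 <- event_template_params(A1 = 0, A3 = 0, A4 = 0)
  k1 <- make_transfer_function(p1, 60)
  expect_true(all(k1 >= 0))
  expect_equal(k1[, 2] / k1[, 1], rep(exp(-1 / p1$tau2), 60),
               tolerance = 1e-9)

  # wave term only: two ridges moving at +/- wave_speed
  p3 <- event_template_params(A1 = 0, A2 = 0, A4 = 0, A3 = 1,
                              wave_speed = 2)
  k3 <- make_transfer_function(p3, 100)
  for (t0 in c(5, 10)) {
    ridge <- which(k3[, t0 + 1] > 0.9 * max(k3[, t0 + 1])) - 1
    d <- pmin(abs(ridge - 2 * t0), 100 - abs(ridge - 2 * t0))
    expect_lte(min(d), 1)
  }

  expect_error(make_transfer_function(
    event_template_params(sigma_wide = 80), 100), "widths")
})

test_that("single-event template: zero sum, calibrated duration, structure", {
  tmpl <- single_event_template()
  expect_lt(abs(sum(tmpl)), 1e-9)
  expect_equal(max(tmpl), 1)

  # duration of the event footprint: about 10 frames (50 min)
  fp <- event_footprint(tmpl)
  expect_gte(fp$duration_frames, 8)
  expect_lte(fp$duration_frames, 12)
  expect_lte(fp$footprint_markers, 20)

  # positive core at the nucleation site, negative values elsewhere
  expect_gt(tmpl[1, 2], 0.5)
  expect_lt(min(tmpl), 0)

  # delta puff: template equals the (normalized) kernel
  pd <- event_template_params(sigma_puff = 1e-6, tau_puff = 1e-6)
  kd <- make_transfer_function(pd, 60)
  kd <- kd - mean(kd); kd <- kd / max(kd)
  td <- single_event_template(pd, 60)
  expect_equal(td, kd, tolerance = 1e-6)
})

test_that("natural axis path is seeded and spans a turn in about 4 h", {
  n1 <- natural_axis_path(200, 100, 36, seed = 5)
  n2 <- natural_axis_path(200, 100, 36, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1$c_axis >= 0 & n1$c_axis < 100))

  # median time for the unwrapped path to span 100 markers: 48 +/- 24
  span_time <- sapply(1:60, function(s) {
    p <- natural_axis_path(300, 100, 36, seed = s)$path
    lo <- cummin(p); hi <- cummax(p)
    w <- which(hi - lo >= 100)
    if (length(w)) w[1] else NA
  })
  expect_gte(median(span_time, na.rm = TRUE), 24)
  expect_lte(median(span_time, na.rm = TRUE), 72)
})

test_that("compass simulation: determinism, no-nucleation limit, area", {
  s1 <- simulate_compass(compass_params(seed = 3, t_tot = 200))
  s2 <- simulate_compass(compass_params(seed = 3, t_tot = 200))
  expect_identical(s1$map, s2$map)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$c_axis, s2$c_axis)

  # no nucleation: zero map, stationary cell, axis = natural path
  s0 <- simulate_compass(compass_params(p_nuc = 0, kappa = 0.5,
                                        t_tot = 150, seed = 4))
  expect_equal(max(abs(unclass(s0$map))), 0)
  expect_equal(max(abs(s0$trajectory$x)), 0)
  expect_equal(nrow(s0$events), 0)

  # zero-sum events: map space-time mean near 0 (constant-area proxy;
  # the residual comes from events truncated at the run's end)
  s3 <- simulate_compass(compass_params(seed = 6, t_tot = 600))
  expect_lt(abs(mean(unclass(s3$map))), 0.01)
})

test_that("axis gain captures a pinned protrusion within one event duration", {
  conv <- axis_convergence_time(compass_params(kappa = 1))
  dur <- event_footprint(single_event_template())$duration_frames
  expect_lte(conv, dur)
})

test_that("unicity index counts simultaneous protruding fronts", {
  # one event at a time: 1
  m1 <- matrix(0, 30, 60)
  m1[5:8, 10:14] <- 1; m1[20:23, 30:34] <- 1
  expect_equal(unicity_index(m1), 1)

  # two simultaneous disjoint events in every window: 1/2
  m2 <- matrix(0, 30, 60)
  m2[3:6, ] <- 1; m2[18:21, ] <- 1
  expect_equal(unicity_index(m2), 0.5)

  # circular adjacency joins fronts wrapping the seam
  m3 <- matrix(0, 30, 60)
  m3[c(29, 30, 1, 2), ] <- 1
  expect_equal(unicity_index(m3), 1)

  # all-retraction map is undefined
  expect_true(is.na(unicity_index(matrix(-1, 30, 60))))
})

test_that("alignment observable: perfect lock and uniform dispersion limits", {
  # construct a simulation-shaped object by hand
  n <- 100; tt <- 400
  ang <- cumsum(rnorm(tt, 0, 0.05))
  sim <- list(params = compass_params(t_tot = tt),
              c_axis = (ang / (2 * pi) * n) %% n,
              trajectory = data.frame(x = c(0, cumsum(cos(ang))),
                                      y = c(0, cumsum(sin(ang)))))
  class(sim) <- "compass_sim"
  expect_equal(alignment_from_simulation(sim), 1, tolerance = 1e-9)

  set.seed(10)
  sim$c_axis <- runif(tt, 0, n)
  expect_lt(alignment_from_simulation(sim), 0.15)
})

test_that("feedback strength orders the persistence regimes", {
  obs_at <- function(pp, kk, seeds = 1:3) {
    res <- sapply(seeds, function(s) {
      sim <- simulate_compass(compass_params(p_polarized = pp, kappa = kk,
                                             t_tot = 600,
                                             seed = 5000 + s))
      o <- compass_observables(sim)
      c(o$tau, o$unicity, o$alignment)
    })
    rowMeans(res)
  }
  lo <- obs_at(0, 0)
  mid <- obs_at(0.5, 0.8)
  hi <- obs_at(0.8, 1)
  # persistence time ranks the three regimes; the uncoupled cell is
  # non-persistent (< 1 h)
  expect_lt(lo[1], 60)
  expect_lt(lo[1], mid[1])
  expect_lt(mid[1], hi[1])
  # full polarization concentrates protrusions (unicity towards 1)
  uni1 <- obs_at(1, 1, seeds = 1:2)[2]
  expect_gt(uni1, 0.8)
  # alignment grows with coupling
  expect_gt(hi[3], lo[3] + 0.3)
})

test_that("phase diagram and parameter estimation are self-consistent", {
  pd <- phase_diagram(p_grid = c(0.2, 0.8), k_grid = c(0.2, 0.8),
                      replicates = 2,
                      base_params = compass_params(t_tot = 300),
                      seed = 77)
  expect_equal(dim(pd$tau), c(2, 2))
  expect_true(all(is.finite(pd$tau)))

  # measured = simulated values at a node: that node is returned
  est <- estimate_parameters(pd, tau = pd$tau[2, 2],
                             unicity = pd$unicity[2, 2],
                             alignment = pd$alignment[2, 2])
  expect_equal(est$p_polarized, 0.8, tolerance = 1e-6)
  expect_equal(est$kappa, 0.8, tolerance = 1e-6)
  expect_false(est$extrapolated)

  # out-of-range measurement flags extrapolation at the boundary
  est2 <- estimate_parameters(pd, tau = 10 * max(pd$tau),
                              unicity = 0.99, alignment = 0.99)
  expect_true(est2$extrapolated)

  # two-observable fit when alignment is unavailable
  est3 <- estimate_parameters(pd, tau = pd$tau[2, 2],
                              unicity = pd$unicity[2, 2])
  expect_false(est3$used_alignment)

  # deterministic reproduction under the same seed
  pd2 <- phase_diagram(p_grid = c(0.2, 0.8), k_grid = c(0.2, 0.8),
                       replicates = 2,
                       base_params = compass_params(t_tot = 300),
                       seed = 77)
  expect_identical(pd$tau, pd2$tau)
})

test_that("simulated maps render to contour movies consistent with motion", {
  sim <- simulate_compass(compass_params(p_polarized = 1, kappa = 1,
                                         t_tot = 120, seed = 21))
  mv <- render_movie(sim, radius = 80, frames = 1:50)
  expect_gte(length(mv$contours), 45)
  # centroid drift of the movie correlates with the simulated trajectory
  cent <- t(vapply(mv$contours, colMeans, numeric(2)))
  nfr <- nrow(cent)
  d_mv <- cent[nfr, ] - cent[1, ]
  d_tr <- c(sim$trajectory$x[nfr] - sim$trajectory$x[1],
            sim$trajectory$y[nfr] - sim$trajectory$y[1])
  cosang <- sum(d_mv * d_tr) / sqrt(sum(d_mv^2) * sum(d_tr^2))
  expect_gt(cosang, 0.8)

  # round-trip: rebuilt morphomap correlates with the simulated map
  rebuilt <- build_morphomap(mv, n_markers = 100)
  v1 <- as.vector(unclass(sim$map)[, 1:ncol(rebuilt)])
  v2 <- as.vector(unclass(rebuilt))
  ok <- is.finite(v1) & is.finite(v2)
  expect_gt(cor(v1[ok], v2[ok]), 0.9)
})
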