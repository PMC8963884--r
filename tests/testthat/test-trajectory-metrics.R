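test_that("step directions follow atan2 with missing zero steps", {
  expect_equal(step_directions(straight_track()), rep(0, 19))

  square <- data.frame(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  expect_equal(step_directions(square) * 180 / pi, c(0, 90, 180, -90))

  still <- data.frame(x = c(0, 1, 1, 2), y = c(0, 0, 0, 0))
  th <- step_directions(still)
  expect_true(is.na(th[2]))
  expect_equal(th[c(1, 3)], c(0, 0))
})

test_that("direction autocorrelation: straight, zig-zag, PRW", {
  ac1 <- direction_autocorrelation(straight_track(60))
  expect_equal(ac1$ac, rep(1, nrow(ac1)))
  expect_equal(ac1$ac[1], 1)

  zig <- data.frame(x = rep(c(0, 1), 20)[1:40],
                    y = 0, time = (0:39))
  acz <- direction_autocorrelation(zig, max_lag = 8, dt = 1)
  expect_equal(acz$ac, (-1)^(0:8))

  tr <- gen_prw_trajectory(prw_params(tau = 100, dt = 5, n_frames = 2000,
                                      seed = 12))
  acp <- direction_autocorrelation(tr, max_lag = 40)
  expect_equal(acp$ac, exp(-acp$lag / 100), tolerance = 0.12)
})

test_that("persistence-time fit is exact on noiseless curves and censors", {
  lags <- seq(0, 600, by = 5)
  ac <- data.frame(lag = lags, ac = exp(-lags / 120))
  fit <- fit_persistence_time(ac)
  expect_equal(fit$tau, 120, tolerance = 1e-6)
  expect_false(fit$censored)

  flat <- data.frame(lag = lags, ac = rep(1, length(lags)))
  fit2 <- fit_persistence_time(flat, tau_max = 1800)
  expect_true(fit2$censored)
  expect_equal(fit2$tau, 1800)
})

test_that("persistence time is recovered across tau values (PRW ensembles)", {
  for (tau in c(60, 150)) {
    taus <- sapply(1:25, function(s) {
      tr <- gen_prw_trajectory(prw_params(tau = tau, dt = 5,
                                          n_frames = 200,
                                          seed = 1000 + s))
      fit_persistence_time(direction_autocorrelation(tr))$tau
    })
    expect_lt(abs(median(taus) - tau) / tau, 0.25)
  }
})

test_that("directionality ratio: straight, right angle, loop", {
  expect_equal(directionality_ratio(straight_track()), 1)
  right <- data.frame(x = c(0, 3, 3), y = c(0, 0, 4))
  expect_equal(directionality_ratio(right), 5 / 7)
  loop <- data.frame(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  expect_equal(directionality_ratio(loop), 0)
})

test_that("axis-movement angles use a counterclockwise sign convention", {
  n <- 10
  base <- data.frame(x = 0:(n - 1), y = 0,
                     nucleus_x = 0:(n - 1), nucleus_y = 0)
  ahead <- transform(base, golgi_x = nucleus_x + 1, golgi_y = 0)
  expect_equal(axis_movement_angles(ahead)$circ_mean_deg, 0)

  left <- transform(base, golgi_x = nucleus_x, golgi_y = 1)
  expect_equal(axis_movement_angles(left)$circ_mean_deg, 90)
  expect_equal(axis_movement_angles(left)$circ_sd_deg, 0, tolerance = 1e-7)
})

test_that("axis-movement summary recovers an imposed circular distribution", {
  set.seed(8)
  n <- 4000
  ang <- (-10 + rnorm(n, 0, 33)) * pi / 180
  x <- cumsum(cos(0 * ang) * 0 + 1)        # straight +x motion
  tr <- data.frame(x = c(0, x), y = 0)
  tr$nucleus_x <- tr$x; tr$nucleus_y <- 0
  tr$golgi_x <- tr$x + c(cos(ang), 1)
  tr$golgi_y <- c(sin(ang), 0)
  res <- axis_movement_angles(tr[1:n, ])
  expect_equal(res$circ_mean_deg, -10, tolerance = 2)
  expect_equal(res$circ_sd_deg, 33, tolerance = 2)
})

test_that("reorientation curves unwrap without 2*pi jumps", {
  n <- 30
  nuc <- cbind(rep(0, n), rep(0, n))
  target <- cbind(rep(10, n), rep(0, n))
  # axis on target throughout: flat zero curve
  gol <- cbind(rep(2, n), rep(0, n))
  rs <- reorientation_series(nuc, gol, target)
  expect_equal(rs$angle_deg, rep(0, n))

  # steadily rotating axis: monotone to 360 with no jumps
  ang <- seq(0, 2 * pi, length.out = n)
  gol2 <- cbind(2 * cos(ang), 2 * sin(ang))
  rs2 <- reorientation_series(nuc, gol2, target)
  expect_equal(rs2$angle_deg[n] - rs2$angle_deg[1], 360, tolerance = 1e-6)
  expect_lt(max(abs(diff(rs2$angle_deg))), 180)

  # noisy rotation crossing +/-180 repeatedly stays continuous
  set.seed(2)
  noisy <- pi + cumsum(rnorm(200, 0, 0.6))
  gol3 <- cbind(2 * cos(noisy), 2 * sin(noisy))
  rs3 <- reorientation_series(cbind(0, 0)[rep(1, 200), ], gol3,
                              cbind(10, 0)[rep(1, 200), ])
  expect_lt(max(abs(diff(rs3$angle_deg))), 180)
})

test_that("cumulative reorientation matches the crossing-time ECDF", {
  curve_at <- function(t0, n = 50) {
    tt <- 0:(n - 1)
    data.frame(time = tt, angle_deg = ifelse(tt < t0, 120, 10))
  }
  # all cells cross at t = 12: step 0 -> 1
  cr <- cumulative_reorientation(lapply(rep(12, 5), curve_at))
  expect_equal(cr$curve$fraction, 1)
  expect_equal(cr$curve$time, 12)

  # no cell crosses: flat zero (empty curve)
  none <- replicate(4, data.frame(time = 0:9, angle_deg = rep(90, 10)),
                    simplify = FALSE)
  expect_equal(nrow(cumulative_reorientation(none)$curve), 0)

  # staggered crossings incl. one never-crossing cell in the denominator
  curves <- c(lapply(c(5, 10, 20), curve_at),
              list(data.frame(time = 0:49, angle_deg = rep(90, 50))))
  cr2 <- cumulative_reorientation(curves)
  expect_equal(cr2$curve$time, c(5, 10, 20))
  expect_equal(cr2$curve$fraction, c(1, 2, 3) / 4)
})

test_that("alignment index matches closed forms and is rotation invariant", {
  expect_equal(alignment_index(rep(0.7, 10)), 1)
  expect_equal(alignment_index(c(0, 90, 180, 270) * pi / 180), 0,
               tolerance = 1e-12)
  expect_equal(alignment_index(c(0, 90) * pi / 180), sqrt(0.5))
  set.seed(1)
  th <- runif(50, -pi, pi)
  expect_equal(alignment_index(th + 1.234), alignment_index(th),
               tolerance = 1e-12)
})
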