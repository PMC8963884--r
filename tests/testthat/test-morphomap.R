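test_that("contour resampling gives equal arclength spacing", {
  # circle: markers at angles 2*pi*i/n, spacing 2*pi*r/n
  mk <- resample_contour(circle_polygon(50, 500), 100)
  ang <- atan2(mk[, 2], mk[, 1])
  expect_equal(ang[1], 0, tolerance = 0.05)
  gaps <- sqrt(rowSums((mk[c(2:100, 1), ] - mk)^2))
  expect_equal(gaps, rep(2 * pi * 50 / 100, 100), tolerance = 1e-3)

  # unit square, n = 4: spacing exactly 1
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  mk4 <- resample_contour(sq, 4)
  g4 <- sqrt(rowSums((mk4[c(2:4, 1), ] - mk4)^2))
  expect_equal(g4, rep(1, 4), tolerance = 1e-12)

  # random polygon: consecutive arclength gaps all equal perimeter/n
  poly <- blob_polygon(seed = 11)
  mkr <- resample_contour(poly, 64)
  per <- attr(mkr, "perimeter")
  gr <- sqrt(rowSums((mkr[c(2:64, 1), ] - mkr)^2))
  # chord lengths approximate arclength gaps on a dense smooth polygon
  expect_equal(gr, rep(per / 64, 64), tolerance = 1e-2)

  expect_error(resample_contour(rbind(c(0, 0), c(0, 0), c(0, 0))),
               "perimeter")
})

test_that("marker matching recovers circular shifts and translations", {
  mk <- unclass(resample_contour(blob_polygon(seed = 2), 50))
  # identical contours
  m0 <- match_contours(mk, mk)
  expect_equal(m0$shift, 0L)
  expect_equal(max(abs(m0$displacement)), 0)

  # rotated marker list, geometry unchanged: s* = -k (mod n)
  for (k in c(3L, 17L, 49L)) {
    rot <- mk[c((k + 1):50, 1:k), ]
    mr <- match_contours(rot, mk)
    expect_equal((mr$shift + 50L) %% 50L, k %% 50L)
    expect_equal(max(abs(mr$displacement)), 0)
  }

  # translated contour: equals an independent brute-force search
  shift_xy <- c(3, -2)
  mk2 <- mk + matrix(shift_xy, 50, 2, byrow = TRUE)
  got <- match_contours(mk, mk2)
  brute <- sapply(0:49, function(s) {
    j <- ((seq_len(50) - 1 + s) %% 50) + 1
    sum((mk - mk2[j, ])^2)
  })
  expect_equal(got$sq_dist, min(brute))
  expect_equal(sqrt(mean(rowSums(got$displacement^2))),
               sqrt(sum(shift_xy^2)), tolerance = 1e-6)

  # invariance to rigid translation of both frames
  off <- matrix(c(100, 55), 50, 2, byrow = TRUE)
  both <- match_contours(mk + off, mk2 + off)
  expect_equal(both$shift, got$shift)
  expect_equal(both$sq_dist, got$sq_dist, tolerance = 1e-6)
})

test_that("morphomap signs protrusion and retraction by the outward normal", {
  grow <- lapply(0:5, function(k) circle_polygon(50 + k, 300))
  m_grow <- build_morphomap(grow, n_markers = 60)
  expect_equal(as.vector(unclass(m_grow)), rep(1, 60 * 5),
               tolerance = 0.02)

  shrink <- lapply(0:5, function(k) circle_polygon(50 - k, 300))
  m_shrink <- build_morphomap(shrink, n_markers = 60)
  expect_equal(as.vector(unclass(m_shrink)), rep(-1, 60 * 5),
               tolerance = 0.02)

  # physical units: pixel_scale and dt rescale speeds
  m_cal <- build_morphomap(grow, dt = 5, pixel_scale = 0.5, n_markers = 60)
  expect_equal(mean(unclass(m_cal)), 0.5 / 5, tolerance = 0.02)

  # reversed time negates and column-reverses the map
  m_rev <- build_morphomap(rev(grow), n_markers = 60)
  expect_equal(unclass(m_rev), -unclass(m_grow)[, 5:1], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("map recentering is an invertible circular permutation", {
  set.seed(4)
  contours <- lapply(0:9, function(k) blob_polygon(50 + k / 2, seed = 21))
  mp <- build_morphomap(contours, n_markers = 40)
  refs <- runif(9, -pi, pi)
  rc <- recenter_map(mp, refs)
  # each column is a permutation of the original multiset
  for (t in 1:9)
    expect_equal(sort(unclass(rc)[, t]), sort(unclass(mp)[, t]))
  # inverse restores exactly
  expect_equal(unclass(undo_recenter(rc)), unclass(mp))

  # reference at the middle marker's own direction: identity column
  msets <- attr(mp, "markers")
  ctr <- attr(msets[[1]], "centroid")
  mid <- 40 %/% 2 + 1
  ref_mid <- atan2(msets[[1]][mid, 2] - ctr[2],
                   msets[[1]][mid, 1] - ctr[1])
  rc2 <- recenter_map(mp, c(ref_mid, refs[-1]))
  expect_equal(attr(rc2, "recenter_offsets")[1], 0L)

  # constant 90 degree rotation of the reference shifts rows by n/4
  rc3 <- recenter_map(mp, rep(ref_mid + pi / 2, 9))
  d <- (attr(rc3, "recenter_offsets")[1] + 10) %% 40
  expect_lte(min(d, 40 - d), 1)

  # missing reference leaves the column unshifted and flagged
  rc4 <- recenter_map(mp, c(NA, refs[-1]))
  expect_true(is.na(attr(rc4, "recenter_offsets")[1]))
  expect_equal(unclass(rc4)[, 1], unclass(mp)[, 1])
})

test_that("mean protrusion profile averages recentered maps by row", {
  z <- matrix(0, 20, 6)
  expect_equal(mean_protrusion_profile(z)$mean_speed, rep(0, 20))

  band <- matrix(0, 20, 6); band[11, ] <- 2   # midline protrusion band
  pr <- mean_protrusion_profile(list(band, band))
  expect_equal(which.max(pr$mean_speed), 11)
  expect_equal(pr$sd_speed, rep(0, 20))
  expect_error(mean_protrusion_profile(list()), "empty")
})
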