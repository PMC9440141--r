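test_that("backbone fits reproduce lines exactly", {
  # collinear horizontal points: all tangent angles zero
  pts <- cbind(seq(0, 10, length.out = 12), rep(2, 12))
  bb <- fit_backbone(pts)
  expect_equal(length(bb$tangent_angles), 100L)
  expect_true(all(abs(bb$tangent_angles) < 1e-9))
  # y = 2x: all angles atan(2)
  pts2 <- cbind(seq(0, 5, length.out = 10), 2 * seq(0, 5, length.out = 10))
  bb2 <- fit_backbone(pts2)
  expect_true(all(abs(bb2$tangent_angles - atan(2)) < 1e-6))
  expect_error(fit_backbone(pts2[1:4, ]), "5 points")
})

test_that("degree <= 4 generators are fitted with vanishing residual", {
  x <- seq(-1, 1, length.out = 25)
  for (cf in list(c(0, 1, 0, 0, 0), c(2, -1, 3, 0, 0),
                  c(0.5, 0, -2, 1, 0.3))) {
    y <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3 + cf[5] * x^4
    bb <- fit_backbone(cbind(x, y))
    expect_lt(bb$residual, 1e-9)
  }
  # chord-length parameterization handles the same line
  bb <- fit_backbone(cbind(x, 2 * x), param = "chord")
  expect_true(all(abs(bb$tangent_angles - atan(2)) < 1e-6))
})

test_that("cross-correlation maps find constructed delays", {
  set.seed(71)
  base <- as.vector(arima.sim(list(ar = 0.8), 80))
  angles <- matrix(base, 1)
  # trace identical to its local angle series: r = 1 at lag 0
  tr <- trace_matrix(matrix(base, 1))
  xc <- activity_curvature_xcorr(tr, angles, max_lag = 10)
  expect_equal(xc$map[1, 1], 1, tolerance = 1e-12)
  expect_equal(xc$lag[1, 1], 0L)
  # delayed trace: peak at the constructed lag with r ~ 1
  delayed <- c(rep(base[1], 3), base[1:77])
  xcd <- activity_curvature_xcorr(trace_matrix(matrix(delayed, 1)), angles)
  expect_equal(xcd$lag[1, 1], 3L)
  expect_gt(abs(xcd$map[1, 1]), 0.95)
  # affine rescaling of either series leaves the map unchanged
  xcs <- activity_curvature_xcorr(trace_matrix(matrix(3 * delayed - 7, 1)),
                                  5 * angles + 2)
  expect_equal(xcs$map, xcd$map, tolerance = 1e-10)
})

test_that("local correlation summary picks the strongest cell", {
  set.seed(72)
  angles <- matrix(rnorm(3 * 60), 3)
  traces <- trace_matrix(rbind(angles[2, ], rnorm(60)))
  lm_ <- local_max_abs(traces, angles, cell_positions = c(2, 3))
  expect_equal(lm_$per_cell[1], 1, tolerance = 1e-12)
  expect_equal(lm_$summary, 1, tolerance = 1e-12)
})

test_that("neurite segmentation follows the five-step contract", {
  # blank image: empty mask
  expect_false(any(segment_neurites(matrix(0, 40, 40))))
  # noiseless phantom: high recall of the true centreline
  ph <- make_neurite_phantom(c(96, 96), n_branches = 3, photon_level = 500,
                             seed = 73)
  mask <- segment_neurites(ph$clean)
  expect_gte(segmentation_recall(mask, ph$skeleton), 0.9)
  # small specks are removed by the size filter
  speck <- matrix(0, 64, 64); speck[10:11, 10:11] <- 100
  expect_false(any(segment_neurites(speck)))
  expect_error(segment_neurites(ph$clean, thresh_window = 24), "odd")
})

test_that("segmentation is idempotent on its own binary output", {
  ph <- make_neurite_phantom(c(96, 96), n_branches = 3, photon_level = 500,
                             seed = 74)
  m1 <- segment_neurites(ph$clean)
  m2 <- segment_neurites(m1 * 1)
  expect_identical(m2, m1)
})
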