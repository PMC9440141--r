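test_that("nucleus scenes hit the photon level exactly and stay in bounds", {
  s <- make_nuclei_scene(c(12, 48, 48), n_cells = 20, photon_level = 1000,
                         seed = 3)
  expect_equal(max(s$clean), 1000)
  expect_equal(min(s$clean), 0)
  expect_equal(nrow(s$nuclei$centers), 20L)
  expect_true(all(s$nuclei$centers >= 1 &
                  s$nuclei$centers <= rep(c(12, 48, 48),
                                          each = 20)))
  # covariances SPD
  for (S in s$nuclei$covariances)
    expect_true(all(eigen(S, TRUE)$values > 0))
})

test_that("a single Gaussian cell peaks at its centre and decays radially", {
  s <- make_nuclei_scene(c(9, 33, 33), n_cells = 1, photon_level = 100,
                         seed = 11)
  ctr <- s$nuclei$centers[1, ]
  pk <- which(unclass(s$clean) == max(s$clean), arr.ind = TRUE)[1, ]
  expect_true(sqrt(sum((pk - ctr)^2)) <= 1)
  # radially monotone along a line through the centre
  zc <- round(ctr[1]); yc <- round(ctr[2])
  prof <- unclass(s$clean)[zc, yc, round(ctr[3]):33]
  expect_true(all(diff(prof) <= 1e-9))
})

test_that("rendered Gaussian mass matches the closed-form integral", {
  # oracle: integral of peak * exp(-q/2) = peak (2 pi)^{3/2} sqrt(det(S))
  S <- diag(c(1.5, 2.5, 2)^2)
  peak <- 0.7
  img <- niddl:::add_gaussian_cell(array(0, c(40, 40, 40)),
                                   c(20.3, 19.6, 20.1), S, peak)
  expected <- peak * (2 * pi)^1.5 * sqrt(det(S))
  expect_lt(abs(sum(img) - expected) / expected, 0.01)
})

test_that("corrupt applies Poisson shot noise plus unit readout noise", {
  z <- array(0, c(10, 100, 100))   # 1e5 voxels
  nz <- corrupt(z, seed = 5)
  expect_gt(mean(nz), -0.02); expect_lt(mean(nz), 0.02)
  v <- stats::var(as.vector(nz))
  expect_gt(v, 0.96); expect_lt(v, 1.04)

  cst <- array(100, c(10, 100, 100))
  nc <- corrupt(cst, seed = 6)
  expect_lt(abs(stats::var(as.vector(nc)) - 101) / 101, 0.05)

  expect_error(corrupt(array(-1, c(2, 2, 2))), "non-negative")
})

test_that("the photon sweep levels are all accepted and expectation is kept", {
  for (pl in c(20, 50, 100, 200, 500, 1000)) {
    s <- make_nuclei_scene(c(4, 24, 24), n_cells = 4, photon_level = pl,
                           seed = pl)
    n <- corrupt(s$clean, seed = pl + 1)
    expect_equal(max(s$clean), pl)
    expect_lt(abs(mean(n - s$clean)), 0.15)  # readout mean 0
  }
})

test_that("photon-level rescaling is affine and order-preserving", {
  s1 <- make_nuclei_scene(c(6, 32, 32), n_cells = 6, photon_level = 100,
                          seed = 9)
  s2 <- make_nuclei_scene(c(6, 32, 32), n_cells = 6, photon_level = 1000,
                          seed = 9)
  expect_equal(which.max(unclass(s1$clean)), which.max(unclass(s2$clean)))
  expect_equal(unclass(s2$clean), unclass(s1$clean) * 10, tolerance = 1e-12)
})

test_that("seeds make scenes, traces and noise reproducible", {
  a <- make_nuclei_scene(c(4, 24, 24), n_cells = 5, seed = 17)
  b <- make_nuclei_scene(c(4, 24, 24), n_cells = 5, seed = 17)
  expect_identical(unclass(a$clean), unclass(b$clean))
  expect_identical(corrupt(a$clean, seed = 3), corrupt(b$clean, seed = 3))
  expect_identical(make_transient_traces(4, 50, seed = 2)$values,
                   make_transient_traces(4, 50, seed = 2)$values)
})

test_that("transient traces follow baseline + exponential-decay pulses", {
  # amplitude 0: constant baseline
  t0 <- make_transient_traces(3, 40, seed = 1, amplitude = 0, baseline = 0.5)
  expect_true(all(t0$values == 0.5))
  # single transient: value at t0 + tau is baseline + A/e
  tr <- make_transient_traces(1, 100, seed = 1, baseline = 0.2,
                              amplitude = 1, tau = 10,
                              onsets = list(20))
  expect_equal(tr$values[1, 20], 1.2)
  expect_equal(tr$values[1, 30], 0.2 + exp(-1), tolerance = 1e-12)
  expect_true(all(tr$values >= 0))
  # default video length is 100 frames
  expect_equal(ncol(make_transient_traces(2, seed = 1)$values), 100L)
})

test_that("semi-synthetic videos modulate peaks by the assigned traces", {
  # grid of well-separated cells
  centers <- as.matrix(expand.grid(z = 5, y = c(12, 36), x = c(12, 36)))
  covs <- replicate(4, diag(c(1.5, 2, 2)^2), simplify = FALSE)
  nuc <- nucleus_set(centers, covs, rep(1, 4))
  tr <- make_transient_traces(4, 30, seed = 8, baseline = 0.3,
                              amplitude = 1, rate = 0.08)
  v <- make_semisynthetic_video(c(9, 48, 48), nuc, tr, photon_level = 500,
                                seed = 4)
  expect_equal(dim(v$clean), c(30, 9, 48, 48))
  expect_equal(max(v$clean), 500)
  # single-pixel traces from the clean video track the assigned traces
  tracks <- cell_tracks(centers, T_len = 30)
  got <- extract_single_pixel(v$clean, tracks)
  r <- trace_pearson(got, trace_matrix(tr$values))
  expect_true(all(r > 0.99))

  # zero-amplitude traces give identical frames
  tr0 <- make_transient_traces(4, 5, seed = 1, amplitude = 0)
  v0 <- make_semisynthetic_video(c(9, 48, 48), nuc, tr0, photon_level = 100,
                                 seed = 2)
  for (t in 2:5)
    expect_equal(v0$clean[t, , , ], v0$clean[1, , , ])

  expect_error(make_semisynthetic_video(c(9, 48, 48), nuc,
                                        make_transient_traces(3, 5, seed = 1),
                                        seed = 1),
               "cells")
})

test_that("neurite phantoms expose their true centreline", {
  # zero curves: blank image
  p0 <- make_neurite_phantom(c(32, 32), n_branches = 0, trunk = FALSE,
                             seed = 1)
  expect_true(all(p0$clean == 0))
  expect_false(any(p0$skeleton))

  # straight horizontal tube at a configured row
  path <- cbind(rep(16, 2), c(4, 60))
  p1 <- make_neurite_phantom(c(32, 64), paths = list(path), seed = 2,
                             photon_level = 100, tube_sigma = 1)
  rows <- which(apply(p1$skeleton, 1, any))
  expect_equal(rows, 16L)

  # cross-section integral per unit length matches the Gaussian profile:
  # colsum / peak = sqrt(2 pi sigma^2) for unit-amplitude Gaussian section
  mid_cols <- 20:45
  ratio <- colSums(p1$clean)[mid_cols] / max(p1$clean)
  expect_true(all(abs(ratio - sqrt(2 * pi)) / sqrt(2 * pi) < 0.02))
})
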