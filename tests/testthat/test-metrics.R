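test_that("metric identities hold on identical images", {
  a <- array(runif(200) * 50, c(2, 10, 10))
  expect_equal(rmse(a, a), 0)
  expect_equal(psnr(a, a), 100)
  expect_equal(ssim(a, a), 1)
})

test_that("rmse reproduces the hand-evaluated 1x2 example", {
  # after min-max normalization both stay (0,1) and (1,0)
  expect_equal(rmse(matrix(c(0, 1), 1), matrix(c(1, 0), 1)), 1)
})

test_that("normalization maps ranges to [0,1] and flags constants", {
  expect_equal(normalize_image(array(0:10)), array((0:10) / 10))
  x <- matrix(seq(0, 1, length.out = 10), 2)
  expect_equal(normalize_image(x), x)         # idempotent on [0,1] range
  expect_message(z <- normalize_image(matrix(5, 3, 3)), "constant")
  expect_true(all(z == 0))
})

test_that("psnr decreases strictly as rmse grows", {
  a <- matrix(seq(0, 1, length.out = 64), 8)
  r_prev <- Inf
  for (noise in c(0.01, 0.05, 0.2)) {
    set.seed(1)
    b <- a + rnorm(64, sd = noise)
    p <- psnr(a, b)
    expect_lt(p, r_prev)
    r_prev <- p
  }
})

test_that("ssim is negative for a checkerboard against its inverse", {
  ck <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_lt(ssim(ck, 1 - ck), 0)
})

test_that("metrics are invariant to affine intensity transforms", {
  set.seed(2)
  a <- matrix(runif(256), 16); b <- matrix(runif(256), 16)
  expect_equal(rmse(5 * a + 3, b), rmse(a, b))
  expect_equal(ssim(a, 0.25 * b - 2), ssim(a, b), tolerance = 1e-12)
  expect_equal(psnr(2 * a, 2 * b), psnr(a, b))
})

test_that("metric_report bundles all three metrics with the rule applied", {
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  rep_ <- metric_report(a, b)
  expect_equal(rep_$rmse, rmse(a, b))
  expect_match(rep_$normalization, "min-max")
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("SNR estimation tracks the constructed noise floor", {
  # sparse bright cells on unit-variance readout noise: with sigma = 1 the
  # estimate should approach mean(foreground) / 1
  s <- make_nuclei_scene(c(8, 64, 64), n_cells = 3, photon_level = 100,
                         seed = 41)
  set.seed(42)
  img <- unclass(s$clean) + array(rnorm(8 * 64 * 64), c(8, 64, 64))
  mask <- unclass(s$clean) > 0.5
  snr <- estimate_snr(img, mask)
  expect_lt(abs(snr - mean(img[mask])) / mean(img[mask]), 0.25)
  expect_error(estimate_snr(array(0, c(2, 4, 4))), "constant")
})

test_that("SNR scales linearly under pure additive Gaussian noise", {
  set.seed(7)
  signal <- array(0, c(1, 64, 64))
  signal[1, 20:40, 20:40] <- 50
  noise <- array(rnorm(64 * 64), c(1, 64, 64))
  mask <- signal > 0
  s1 <- estimate_snr(signal + noise, mask)
  s3 <- estimate_snr(3 * signal + noise, mask)
  expect_lt(abs(s3 / s1 - 3) / 3, 0.1)
})

test_that("measured SNR rises monotonically across the photon sweep", {
  snrs <- vapply(c(20, 50, 100, 200, 500, 1000), function(pl) {
    s <- make_nuclei_scene(c(4, 32, 32), n_cells = 5, photon_level = pl,
                           seed = 77)
    estimate_snr(unclass(corrupt(s$clean, seed = 78)))
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})
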