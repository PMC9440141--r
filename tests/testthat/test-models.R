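test_that("layer parameter accounting matches the closed-form formula", {
  # cout*cin*k^2 + cout
  expect_equal(count_parameters(niddl:::single_conv_model(1, 4, 3)), 40)
  expect_equal(count_parameters(niddl:::single_conv_model(1, 1, 1)), 2)
  expect_equal(count_parameters(niddl:::single_conv_model(32, 32, 3)), 9248)
})

test_that("fixed-channel networks reproduce the printed model sizes", {
  expect_equal(model_size_mb(build_model(arch_spec("unet_fixed"))), 3.77)
  expect_equal(model_size_mb(build_model(arch_spec("hourglass_wres"))), 3.66)
})

test_that("parameter count is a pure function of the spec", {
  a <- count_parameters(build_model(arch_spec("unet_fixed"), seed = 1))
  b <- count_parameters(build_model(arch_spec("unet_fixed"), seed = 999))
  expect_identical(a, b)
})

test_that("doubling-channel variants are far larger than fixed ones", {
  fixed <- count_parameters(build_model(arch_spec("unet_fixed")))
  doubling <- count_parameters(build_model(arch_spec("unet")))
  expect_gt(doubling / fixed, 5)
  hg_fixed <- count_parameters(build_model(arch_spec("hourglass_wres")))
  hg_doub <- count_parameters(build_model(arch_spec("hourglass_wores")))
  expect_gt(hg_doub / hg_fixed, 5)
})

test_that("spec validation rejects unsupported settings", {
  expect_error(arch_spec("unet_fixed", kernel = 4), "kernel")
  expect_error(arch_spec("unet_fixed", blocks = c(1, 1)), "length")
  expect_error(arch_spec("nonsense"), "arg")
})

test_that("forward output preserves spatial shape across modes", {
  # 2d
  m <- build_model(tiny_arch(), seed = 1)
  r <- niddl:::exec_batch(m, list(matrix(runif(32 * 32), 1)),
                          dims = c(1L, 32L, 32L), want_pred = TRUE)
  expect_equal(dim(r$preds[[1]]), c(1L, 1024L))
  # 2p5d: 2*context_d + 1 input channels, one output plane
  sp <- arch_spec("unet_fixed", levels = 2, channels = 8,
                  blocks = c(1, 1, 1), mode = "2p5d", context_d = 1)
  m2 <- build_model(sp, seed = 2)
  r2 <- niddl:::exec_batch(m2, list(matrix(runif(3 * 256), 3)),
                           dims = c(1L, 16L, 16L), want_pred = TRUE)
  expect_equal(dim(r2$preds[[1]]), c(1L, 256L))
  # 3d: depth in = depth out
  sp3 <- arch_spec("unet_fixed", levels = 2, channels = 8,
                   blocks = c(1, 1, 1), mode = "3d", context_d = 2)
  m3 <- build_model(sp3, seed = 3)
  r3 <- niddl:::exec_batch(m3, list(matrix(runif(2 * 256), 1)),
                           dims = c(2L, 16L, 16L), want_pred = TRUE)
  expect_equal(dim(r3$preds[[1]]), c(1L, 512L))
})

test_that("zero input maps to zero output through fresh models", {
  for (fam in c("unet_fixed", "hourglass_wres", "unet", "hourglass_wores")) {
    m <- build_model(tiny_arch(fam), seed = 4)
    r <- niddl:::exec_batch(m, list(matrix(0, 1, 1024)),
                            dims = c(1L, 32L, 32L), want_pred = TRUE)
    expect_true(all(r$preds[[1]] == 0))
  }
})

test_that("non-multiple plane sizes are padded and cropped transparently", {
  m <- build_model(tiny_arch(), seed = 5)  # levels 2 -> multiple of 4
  x <- array(runif(1 * 21 * 18) * 100, c(1, 21, 18))
  out <- denoise_stack(m, x)
  expect_equal(dim(out), dim(x))
  expect_true(all(is.finite(out)))
  # exact-multiple inputs take the unpadded path and agree with themselves
  x2 <- array(runif(1 * 20 * 20) * 100, c(1, 20, 20))
  expect_equal(dim(denoise_stack(m, x2)), dim(x2))
})

test_that("kernel size 5 builds and runs", {
  sp <- arch_spec("unet_fixed", kernel = 5, levels = 2, channels = 4,
                  blocks = c(1, 1, 1))
  m <- build_model(sp, seed = 6)
  # single 5x5 conv layer formula check via the model total: every conv in
  # this small net uses k = 5 except the 1x1 fusion convs
  r <- niddl:::exec_batch(m, list(matrix(runif(256), 1)),
                          dims = c(1L, 16L, 16L), want_pred = TRUE)
  expect_equal(dim(r$preds[[1]]), c(1L, 256L))
})
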