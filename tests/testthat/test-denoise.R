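test_that("an identity network returns the input through the
           normalization round-trip", {
  m <- identity_model()
  x <- array(runif(4 * 20 * 24) * 500, c(4, 20, 24))
  out <- denoise_stack(m, x)
  expect_equal(unclass(out), x, tolerance = 1e-5)
  # tiling path must blend back to the identity as well
  big <- array(runif(1 * 100 * 90) * 100, c(1, 100, 90))
  out2 <- denoise_stack(m, big, tile = 48L, overlap = 8L)
  expect_equal(unclass(out2), big, tolerance = 1e-5)
})

test_that("2d-mode denoising treats planes independently", {
  m <- build_model(tiny_arch(), seed = 3)
  x <- array(runif(5 * 16 * 16) * 100, c(5, 16, 16))
  out <- denoise_stack(m, x)
  perm <- c(3, 1, 5, 2, 4)
  out_perm <- denoise_stack(m, x[perm, , ])
  expect_equal(out_perm, out[perm, , ], tolerance = 1e-6)
})

test_that("video denoising is frame-independent and order-equivariant", {
  m <- build_model(tiny_arch(), seed = 4)
  v <- video_stack(array(runif(4 * 2 * 16 * 16) * 50, c(4, 2, 16, 16)))
  out <- denoise_video(m, v)
  # identical frames give identical outputs
  vsame <- video_stack(array(rep(v[1, , , ], 4), c(2, 16, 16, 4)))
  vsame <- video_stack(aperm(unclass(vsame), c(4, 1, 2, 3)))
  osame <- denoise_video(m, vsame)
  for (t in 2:4) expect_equal(osame[t, , , ], osame[1, , , ])
  # reordering commutes
  perm <- c(2, 4, 1, 3)
  out_perm <- denoise_video(m, video_stack(unclass(v)[perm, , , ]))
  expect_equal(unclass(out_perm), unclass(out)[perm, , , ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("max-projection denoising matches the documented contract", {
  m <- identity_model()
  v <- video_stack(array(runif(3 * 4 * 16 * 16) * 100, c(3, 4, 16, 16)))
  mp <- denoise_maxproj(m, v)
  expect_equal(dim(mp), c(3L, 16L, 16L))
  # projection of a nonnegative stack dominates every plane
  for (t in 1:3) {
    proj <- max_project(array(v[t, , , ], c(4, 16, 16)))
    expect_equal(mp[t, , ], proj, tolerance = 1e-5)
    for (z in 1:4) expect_true(all(proj >= v[t, z, , ] - 1e-9))
  }
  # depth-1 video: identical to denoise_video then squeeze
  v1 <- video_stack(unclass(v)[, 1, , , drop = FALSE])
  expect_equal(denoise_maxproj(m, v1)[1, , ],
               denoise_video(m, v1)[1, 1, , ], tolerance = 1e-6)
  # mode guard
  sp3 <- arch_spec("unet_fixed", levels = 1, channels = 4, blocks = c(1, 1),
                   mode = "3d", context_d = 1)
  expect_error(denoise_maxproj(build_model(sp3), v), "2d")
})

test_that("2p5d and 3d dispatch produce full-depth outputs", {
  sp25 <- arch_spec("unet_fixed", levels = 1, channels = 4,
                    blocks = c(1, 1), mode = "2p5d", context_d = 1)
  m25 <- build_model(sp25, seed = 1)
  x <- array(runif(4 * 16 * 16) * 10, c(4, 16, 16))
  expect_equal(dim(denoise_stack(m25, x)), dim(x))
  sp3 <- arch_spec("unet_fixed", levels = 1, channels = 4,
                   blocks = c(1, 1), mode = "3d", context_d = 2)
  m3 <- build_model(sp3, seed = 2)
  expect_equal(dim(denoise_stack(m3, x)), dim(x))
  expect_error(denoise_stack(m3, x[1, , , drop = FALSE]), "planes")
})

test_that("median filter honours its contract", {
  cst <- matrix(7, 12, 12)
  expect_equal(median_baseline(cst, 3), cst)
  imp <- matrix(0, 12, 12); imp[6, 6] <- 100
  expect_true(all(median_baseline(imp, 3) == 0))
  expect_error(median_baseline(imp, 4), "odd")
})

test_that("gaussian filter preserves the mean under reflective boundaries", {
  set.seed(9)
  img <- matrix(runif(40 * 30) * 100, 40, 30)
  for (s in c(1, 3, 5)) {
    sm <- gaussian_baseline(img, s)
    expect_lt(abs(mean(sm) - mean(img)) / mean(img), 0.001)
  }
  expect_error(gaussian_baseline(img, 0), "positive")
})

test_that("best_baseline picks the sweep parameter minimizing RMSE", {
  s <- make_nuclei_scene(c(1, 32, 32), n_cells = 4, photon_level = 100,
                         seed = 31)
  noisy <- unclass(corrupt(s$clean, seed = 32))
  clean <- unclass(s$clean)
  bb <- best_baseline(noisy, clean, "median")
  expect_true(bb$param %in% c(3, 5, 7))
  for (w in c(3, 5, 7))
    expect_lte(bb$rmse, rmse(median_baseline(noisy, w), clean))
  bg <- best_baseline(noisy, clean, "gaussian")
  expect_true(bg$param %in% c(1, 3, 5))
})
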