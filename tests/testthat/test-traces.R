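test_that("GMM segmentation recovers a single bright nucleus", {
  s <- make_nuclei_scene(c(8, 24, 24), n_cells = 1, photon_level = 1000,
                         seed = 61)
  seg <- segment_nuclei_gmm(s$clean, seed = 1)
  expect_equal(seg$k, 1L)
  expect_lt(sqrt(sum((seg$centers[1, ] - s$nuclei$centers[1, ])^2)), 1)
  expect_error(segment_nuclei_gmm(array(0, c(2, 8, 8))), "blank")
})

test_that("GMM segmentation resolves a dense synthetic scene", {
  s <- make_nuclei_scene(c(12, 64, 64), n_cells = 25, photon_level = 1000,
                         seed = 62, min_sep = 5)
  seg <- segment_nuclei_gmm(s$clean, seed = 2)
  matched <- match_centers(seg$centers, s$nuclei$centers, tol = 2)
  expect_gte(matched, round(0.9 * 25))
})

test_that("nearest-neighbour tracking keeps identities under jitter", {
  set.seed(63)
  base <- as.matrix(expand.grid(z = c(4, 12), y = c(8, 24, 40),
                                x = c(8, 24, 40)))[1:10, ]
  frames <- lapply(1:50, function(t) base + matrix(rnorm(30, 0, 0.5), 10))
  tk <- track_nearest(frames, gate = 5)
  expect_true(all(tk$valid))
  # every track stays within a voxel-scale ball of its true cell
  for (i in 1:10)
    expect_lt(max(abs(tk$coords[i, , 2] - base[i, 2])), 4)
  # static centres give constant tracks
  tks <- track_nearest(rep(list(base), 5), gate = 5)
  for (t in 2:5) expect_equal(tks$coords[, t, ], tks$coords[, 1, ])
})

test_that("displacements beyond the gate are flagged, not linked", {
  a <- matrix(c(1, 5, 5, 1, 30, 30), 2, 3, byrow = TRUE)
  b <- matrix(c(1, 18, 17, 1, 17, 18), 2, 3, byrow = TRUE)  # > gate away
  tk <- track_nearest(list(a, b), gate = 5)
  expect_false(any(tk$valid[, 2]))
  expect_equal(tk$coords[, 2, ], a)  # carried forward, never cross-linked
})

test_that("trace extraction is exact and linear", {
  v <- array(runif(5 * 4 * 12 * 12) * 10, c(5, 4, 12, 12))
  centers <- matrix(c(2, 6, 6, 3, 9, 4), 2, 3, byrow = TRUE)
  tk <- cell_tracks(centers, T_len = 5)
  tr <- extract_single_pixel(video_stack(v), tk)
  expect_equal(tr$values[1, 3], v[3, 2, 6, 6])
  # roi (1,1,1) is the single-pixel path
  tr_roi1 <- extract_roi(video_stack(v), tk, c(1, 1, 1))
  expect_identical(tr$values, tr_roi1$values)
  # constant video gives constant traces; roi mean of a constant region
  vc <- video_stack(array(3, c(4, 2, 8, 8)))
  tkc <- cell_tracks(matrix(c(1, 4, 4), 1), T_len = 4)
  expect_true(all(extract_roi(vc, tkc, c(1, 3, 3))$values == 3))
  # linearity in the video for fixed tracks
  v2 <- array(runif(length(v)) * 5, dim(v))
  sum_tr <- extract_single_pixel(video_stack(v + v2), tk)
  expect_equal(sum_tr$values,
               tr$values + extract_single_pixel(video_stack(v2), tk)$values)
  # out-of-bounds centres are flagged missing
  tko <- cell_tracks(matrix(c(1, 40, 4), 1), T_len = 4)
  expect_message(tr_oob <- extract_single_pixel(vc, tko), "out-of-bounds")
  expect_true(all(is.na(tr_oob$values)))
})

test_that("trace MAE and Pearson match brute-force evaluation", {
  expect_equal(trace_mae(trace_matrix(matrix(c(1, 2, 3), 1)),
                         trace_matrix(matrix(c(0, 2, 4), 1))),
               2 / 3)
  tm <- trace_matrix(matrix(runif(20), 4))
  expect_true(all(trace_mae(tm, tm) == 0))
  expect_equal(trace_pearson(tm, tm), rep(1, 4))
  # independent brute-force loop oracle on 100 random matrices
  set.seed(64)
  for (rep in 1:100) {
    n <- sample(2:6, 1); T_len <- sample(3:12, 1)
    a <- matrix(rnorm(n * T_len), n); b <- matrix(rnorm(n * T_len), n)
    mae_ref <- numeric(n); r_ref <- numeric(n)
    for (i in 1:n) {
      acc <- 0
      for (t in 1:T_len) acc <- acc + abs(a[i, t] - b[i, t])
      mae_ref[i] <- acc / T_len
      r_ref[i] <- stats::cor(a[i, ], b[i, ])
    }
    expect_lt(max(abs(trace_mae(trace_matrix(a), trace_matrix(b)) -
                        mae_ref)), 1e-12)
    expect_lt(max(abs(trace_pearson(trace_matrix(a), trace_matrix(b)) -
                        r_ref)), 1e-12)
  }
  # zero-variance ground truth: correlation missing, MAE well-defined
  cst <- trace_matrix(matrix(1, 1, 5))
  var_ <- trace_matrix(matrix(rnorm(5), 1))
  expect_true(is.na(trace_pearson(var_, cst)))
  expect_true(is.finite(trace_mae(var_, cst)))
})

test_that("pairwise correlation and PCA obey their structure", {
  set.seed(65)
  v <- matrix(rnorm(5 * 30), 5)
  cm <- pairwise_corr(trace_matrix(v))
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  # rank-1 traces: first component explains everything
  base <- sin(seq_len(40) / 3)
  v1 <- outer(c(1, 2, -1, 0.5), base)
  p <- pca_traces(trace_matrix(v1), k = 3)
  expect_gt(p$explained[1], 0.999)
  expect_equal(dim(p$trajectory), c(40L, 3L))
})
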