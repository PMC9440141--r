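# The batched C++ executor and the layer-by-layer R reference engine are
# independent routes through the same graphs; they must agree exactly.

test_that("executor and reference engine agree on forward passes", {
  set.seed(81)
  for (fam in c("unet_fixed", "hourglass_wres", "unet", "hourglass_wores")) {
    m <- build_model(arch_spec(fam, levels = 2, channels = 4,
                               blocks = c(1, 2, 1)), seed = 82)
    x <- matrix(runif(24 * 24), 1)
    dims <- c(1L, 24L, 24L)
    ref <- niddl:::net_forward(m, x, dims)$out
    exe <- niddl:::exec_batch(m, list(x), dims = dims,
                              want_pred = TRUE)$preds[[1]]
    expect_equal(exe, ref, tolerance = 1e-6)
  }
})

test_that("executor gradients match the reference backward pass", {
  set.seed(83)
  m <- build_model(arch_spec("unet_fixed", levels = 2, channels = 4,
                             blocks = c(1, 1, 1)), seed = 84)
  x <- matrix(runif(256), 1); y <- matrix(runif(256), 1)
  dims <- c(1L, 16L, 16L)
  tape <- niddl:::net_forward(m, x, dims, keep = TRUE)
  gref <- niddl:::net_backward(m, tape,
                               niddl:::loss_grad("l1", tape$out, y))
  gexe <- niddl:::exec_batch(m, list(x), list(y), dims, loss = "l1",
                             want_grads = TRUE)$grads
  for (nm in names(gref)) {
    scale <- max(1e-8, max(abs(gref[[nm]])))
    expect_lt(max(abs(gref[[nm]] - gexe[[nm]])) / scale, 1e-4)
  }
})

test_that("convolution kernels satisfy exact adjoint identities", {
  set.seed(85)
  C <- 3L; Co <- 4L; dims <- c(1L, 6L, 8L); N <- prod(dims)
  kdim <- c(1L, 3L, 3L)
  x <- matrix(rnorm(C * N), C); w <- matrix(rnorm(Co * C * 9), Co)
  dy <- matrix(rnorm(Co * N), Co)
  g <- niddl:::nn_conv_bwd(x, w, dy, dims, kdim)
  V <- matrix(rnorm(C * N), C)
  lhs <- sum(g$dx * V)
  rhs <- sum(dy * niddl:::nn_conv_fwd(V, w, rep(0, Co), dims, kdim))
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-5)
  Wv <- matrix(rnorm(Co * C * 9), Co)
  lhs <- sum(g$dw * Wv)
  rhs <- sum(dy * niddl:::nn_conv_fwd(x, Wv, rep(0, Co), dims, kdim))
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-5)
})

test_that("batched losses average per-sample losses", {
  m <- build_model(tiny_arch(), seed = 86)
  xs <- lapply(1:3, function(i) matrix(runif(256), 1))
  ys <- lapply(1:3, function(i) matrix(runif(256), 1))
  dims <- c(1L, 16L, 16L)
  r <- niddl:::exec_batch(m, xs, ys, dims, loss = "l2", want_grads = FALSE,
                          want_pred = TRUE)
  per <- vapply(1:3, function(i) loss_l2(r$preds[[i]], ys[[i]]), numeric(1))
  expect_equal(r$loss, mean(per), tolerance = 1e-6)
})
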