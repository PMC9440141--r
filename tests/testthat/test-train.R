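make_stack_pairs <- function(n, nz = 6, hw = 16, seed0 = 50, photon = 200) {
  lapply(seq_len(n), function(i) {
    s <- make_nuclei_scene(c(nz, hw, hw), n_cells = 4,
                           photon_level = photon, seed = seed0 + i)
    list(clean = unclass(s$clean),
         noisy = unclass(corrupt(s$clean, seed = seed0 + 900 + i)))
  })
}

test_that("sampling modes yield the expected sample counts and shapes", {
  pairs <- paired_dataset(make_stack_pairs(1, nz = 30), val_frac = 0)
  s2d <- make_training_samples(pairs, "2d")
  expect_equal(nrow(s2d$index), 30L)
  s25 <- make_training_samples(pairs, "2p5d", context_d = 1)
  expect_equal(nrow(s25$index), 28L)       # edge planes skipped
  smp <- s25$fetch(1)
  expect_equal(nrow(smp$x), 3L)            # 2d+1 input channels
  expect_equal(nrow(smp$y), 1L)
  s3d <- make_training_samples(pairs, "3d", context_d = 2)
  expect_equal(nrow(s3d$index), 15L)       # non-overlapping 2-plane chunks
  smp3 <- s3d$fetch(1)
  expect_equal(smp3$dims[1], 2L)
  expect_equal(ncol(smp3$x), ncol(smp3$y)) # input depth = output depth
})

test_that("insufficient stack depth raises a sampling error naming the stack", {
  pairs <- paired_dataset(make_stack_pairs(1, nz = 2), val_frac = 0)
  expect_error(make_training_samples(pairs, "2p5d", context_d = 1), "planes")
})

test_that("losses evaluate hand-checked examples and identities", {
  a <- array(runif(24), c(2, 3, 4))
  expect_equal(loss_l1(a, a), 0)
  expect_equal(loss_l2(a, a), 0)
  expect_equal(loss_l1(c(0, 2), c(1, 1)), 1)
  expect_equal(loss_l2(c(0, 2), c(1, 1)), 1)
  expect_error(loss_l1(1:4, 1:5), "shape")
  # L2 of the difference equals population variance + squared mean
  set.seed(1)
  p <- rnorm(50); t <- rnorm(50)
  d <- p - t
  expect_equal(loss_l2(p, t), mean((d - mean(d))^2) + mean(d)^2,
               tolerance = 1e-12)
})

test_that("a zero-epoch run returns the model unchanged", {
  pairs <- paired_dataset(make_stack_pairs(2), val_frac = 0)
  m <- build_model(tiny_arch(), seed = 1)
  fit <- train_model(m, pairs, train_config(epochs = 0))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$record), 0L)
})

test_that("a single pair can be overfitted far below the initial loss", {
  pairs <- paired_dataset(make_stack_pairs(1, nz = 1, hw = 32),
                          val_frac = 0)
  m <- build_model(tiny_arch(), seed = 2)
  cfg <- train_config(loss = "l1", epochs = 1, epoch_size = 500,
                      batch_size = 1, seed = 3)
  smp <- make_training_samples(pairs, "2d")$fetch(1)
  initial <- niddl:::step_sample(m, smp, "l1", with_grad = FALSE)$loss
  fit <- train_model(m, pairs, cfg)
  final <- niddl:::step_sample(fit$model, smp, "l1",
                               with_grad = FALSE)$loss
  expect_lt(final, 0.1 * initial)
})

test_that("training is bytewise reproducible for equal seeds", {
  pairs <- paired_dataset(make_stack_pairs(3), val_frac = 0.34, seed = 1)
  cfg <- train_config(epochs = 1, epoch_size = 8, batch_size = 2, seed = 11)
  f1 <- train_model(build_model(tiny_arch(), seed = 7), pairs, cfg)
  f2 <- train_model(build_model(tiny_arch(), seed = 7), pairs, cfg)
  expect_identical(serialize(f1$model$params, NULL),
                   serialize(f2$model$params, NULL))
  expect_identical(f1$record$train_loss, f2$record$train_loss)
})

test_that("the selected checkpoint is at least as good as the initial model", {
  pairs <- paired_dataset(make_stack_pairs(4), val_frac = 0.25, seed = 2)
  m0 <- build_model(tiny_arch(), seed = 5)
  val <- make_training_samples(pairs, "2d", subset = "val")
  rmse0 <- niddl:::val_rmse_of(m0, val)
  fit <- train_model(m0, pairs,
                     train_config(epochs = 2, epoch_size = 16,
                                  batch_size = 4, seed = 6))
  rmse1 <- niddl:::val_rmse_of(fit$model, val)
  expect_lte(rmse1, rmse0)
})

test_that("both losses beat the noisy baseline on held-out pairs", {
  # strongly photon-limited regime (peak 50 photons), where denoising has
  # clear headroom for either loss
  pairs0 <- make_stack_pairs(20, nz = 1, hw = 32, photon = 50)
  ds <- paired_dataset(pairs0, val_frac = 0, test_frac = 0.2, seed = 3)
  test_ids <- which(ds$split == "test")
  for (loss in c("l1", "l2")) {
    fit <- train_model(build_model(tiny_arch(), seed = 8), ds,
                       train_config(loss = loss, epochs = 1,
                                    epoch_size = 4800, batch_size = 4,
                                    seed = 9))
    deltas <- vapply(test_ids, function(i) {
      p <- ds$pairs[[i]]
      rmse(p$noisy, p$clean) -
        rmse(unclass(denoise_stack(fit$model, p$noisy)), p$clean)
    }, numeric(1))
    expect_gt(median(deltas), 0)
  }
})

test_that("the training-size sweep is deterministic per (size, seed)", {
  pairs <- paired_dataset(make_stack_pairs(6, nz = 1, hw = 16),
                          val_frac = 0, test_frac = 0.34, seed = 4)
  cfg <- train_config(epochs = 1, epoch_size = 4, batch_size = 2, seed = 0)
  out <- training_size_sweep(pairs, sizes = c(2, 2), spec = tiny_arch(),
                             config = cfg, repeats = 1, seed = 21)
  expect_equal(out$rmse[1], out$rmse[2])
  expect_error(training_size_sweep(pairs, sizes = 10, spec = tiny_arch(),
                                   config = cfg, repeats = 1),
               "exceeds")
})

test_that("NaN parameters abort training with a batch diagnostic", {
  pairs <- paired_dataset(make_stack_pairs(2), val_frac = 0)
  m <- build_model(tiny_arch(), seed = 1)
  # poison the head convolution: no ReLU follows it, so the NaN reaches
  # the loss
  wnames <- grep("\\.w$", names(m$params), value = TRUE)
  m$params[[utils::tail(wnames, 1)]][] <- NaN
  expect_error(train_model(m, pairs,
                           train_config(epochs = 1, epoch_size = 2,
                                        batch_size = 1)),
               "non-finite loss at step")
})
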