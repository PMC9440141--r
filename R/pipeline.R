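## ---------------------------------------------------------------------------
## End-to-end drivers: synthetic photon-sweep benchmark and semi-synthetic
## trace recovery. Desk-scale defaults (64x64 planes / 128x128x16 videos)
## keep runs tractable on one CPU; paper_scale restores the printed sizes.

#' Synthetic denoising benchmark across photon levels
#'
#' For each photon count: generates clean/noisy nucleus-scene pairs, trains
#' a network on the training pairs, and evaluates the trained model and the
#' classical filter sweeps on held-out pairs with the normalized
#' RMSE/PSNR/SSIM metrics.
#'
#' @param photon_levels photon counts to sweep (full sweep:
#'   20, 50, 100, 200, 500, 1000).
#' @param n_train,n_test training/held-out pairs per level.
#' @param shape scene shape (z, y, x).
#' @param n_cells nuclei per scene.
#' @param arch an \code{\link{arch_spec}}.
#' @param loss,epochs,epoch_size,batch_size,lr training schedule.
#' @param seed master seed.
#' @param paper_scale use the full-scale protocol (128 x 128 x 30 scenes,
#'   60 cells, photon sweep 20..1000).
#' @param dry_run return the execution plan without computing.
#' @param model optional pre-trained model reused for every level (skips
#'   training).
#' @return list with \code{config}, \code{results} (one row per held-out
#'   pair x method), and \code{summary} (median metrics per level x method,
#'   with the best filter parameters marked).
#' @export
run_synthetic_benchmark <- function(photon_levels = c(100, 200),
                                    n_train = 40L, n_test = 10L,
                                    shape = c(1L, 64L, 64L), n_cells = 8L,
                                    arch = arch_spec("unet_fixed"),
                                    loss = "l1", epochs = 2L,
                                    epoch_size = 100L, batch_size = 8L,
                                    lr = 1e-3, seed = 0L,
                                    paper_scale = FALSE, dry_run = FALSE,
                                    model = NULL) {
  if (paper_scale) {
    photon_levels <- c(20, 50, 100, 200, 500, 1000)
    shape <- c(30L, 128L, 128L); n_cells <- 60L
    n_train <- 200L; n_test <- 50L
  }
  config <- list(photon_levels = photon_levels, n_train = n_train,
                 n_test = n_test, shape = shape, n_cells = n_cells,
                 arch = arch, loss = loss, epochs = epochs,
                 epoch_size = epoch_size, batch_size = batch_size, lr = lr,
                 seed = seed)
  if (dry_run) {
    plan <- c(
      sprintf("generate %d train + %d test scene pairs of %s at levels %s",
              n_train, n_test, paste(shape, collapse = "x"),
              paste(photon_levels, collapse = ", ")),
      sprintf("train %s (%s loss) for %d epochs x %d samples, batch %d",
              arch$family, loss, epochs, epoch_size, batch_size),
      "evaluate model + median (3/5/7) + gaussian (1/3/5) on held-out pairs",
      "summarise median RMSE/PSNR/SSIM per photon level and method")
    return(list(config = config, plan = plan))
  }
  results <- list()
  for (li in seq_along(photon_levels)) {
    pl <- photon_levels[li]
    lseed <- seed + 7919L * li
    mkpair <- function(i) {
      s <- make_nuclei_scene(shape, n_cells = n_cells, photon_level = pl,
                             seed = lseed + i)
      list(clean = unclass(s$clean),
           noisy = unclass(corrupt(s$clean, seed = lseed + 500000L + i)))
    }
    train_pairs <- lapply(seq_len(n_train), mkpair)
    test_pairs <- lapply(n_train + seq_len(n_test), mkpair)
    mdl <- model
    if (is.null(mdl)) {
      fit <- niddl(train_pairs, arch = arch, loss = loss, epochs = epochs,
                   epoch_size = epoch_size, batch_size = batch_size,
                   lr = lr, seed = lseed)
      mdl <- fit$model
    }
    for (ti in seq_along(test_pairs)) {
      tp <- test_pairs[[ti]]
      evals <- list(noisy = tp$noisy,
                    niddl = unclass(denoise_stack(mdl, tp$noisy)))
      for (w in c(3, 5, 7))
        evals[[paste0("median", w)]] <- median_baseline(tp$noisy, w)
      for (s in c(1, 3, 5))
        evals[[paste0("gaussian", s)]] <- gaussian_baseline(tp$noisy, s)
      for (m in names(evals)) {
        rep_ <- metric_report(evals[[m]], tp$clean)
        results[[length(results) + 1L]] <- data.frame(
          photon_level = pl, method = m, image = ti, rmse = rep_$rmse,
          psnr = rep_$psnr, ssim = rep_$ssim)
      }
    }
  }
  results <- do.call(rbind, results)
  summary <- stats::aggregate(cbind(rmse, psnr, ssim) ~ photon_level + method,
                              data = results, FUN = stats::median)
  summary <- summary[order(summary$photon_level, summary$rmse), ]
  list(config = config, results = results, summary = summary)
}

#' Semi-synthetic trace recovery experiment
#'
#' Builds a semi-synthetic calcium video with known per-cell ground truth,
#' trains a denoiser on independent scene pairs (never on video frames),
#' denoises the video frame by frame, and extracts traces from the noisy,
#' clean and denoised videos with one shared set of ground-truth positions
#' (avoiding segmentation-difference artifacts). Reports per-cell MAE and
#' Pearson correlation against the ground-truth traces, the Frobenius
#' distance between pairwise-correlation matrices, and PCA trajectories.
#'
#' @param shape frame shape (z, y, x).
#' @param n_cells cells in the video.
#' @param T_len frames.
#' @param photon_level video peak photon count.
#' @param n_train_pairs independent scene pairs for training.
#' @param train_shape shape of the training scenes.
#' @param arch,loss,epochs,epoch_size,batch_size,lr training schedule.
#' @param model optional pre-trained model (skips training).
#' @param roi extraction box (z, y, x); \code{c(1, 1, 1)} for single pixel.
#' @param seed master seed.
#' @param dry_run return the plan without computing.
#' @param paper_scale full-scale protocol (512 x 512 x 30, 130 cells,
#'   100 frames).
#' @return list with \code{config}, per-cell \code{mae} and \code{pearson}
#'   (noisy and denoised arms), \code{corr_frobenius} distances, a
#'   \code{pca} comparison, and the extracted \code{traces}.
#' @export
run_trace_recovery <- function(shape = c(16L, 128L, 128L), n_cells = 30L,
                               T_len = 50L, photon_level = 200,
                               n_train_pairs = 40L,
                               train_shape = c(1L, 64L, 64L),
                               arch = arch_spec("unet_fixed"), loss = "l1",
                               epochs = 2L, epoch_size = 100L,
                               batch_size = 8L, lr = 1e-3, model = NULL,
                               roi = c(1L, 1L, 1L), seed = 0L,
                               dry_run = FALSE, paper_scale = FALSE) {
  if (paper_scale) {
    shape <- c(30L, 512L, 512L); n_cells <- 130L; T_len <- 100L
  }
  config <- list(shape = shape, n_cells = n_cells, T_len = T_len,
                 photon_level = photon_level,
                 n_train_pairs = n_train_pairs, train_shape = train_shape,
                 arch = arch, loss = loss, epochs = epochs,
                 epoch_size = epoch_size, batch_size = batch_size, lr = lr,
                 roi = roi, seed = seed)
  if (dry_run) {
    plan <- c(
      sprintf("simulate %d-cell %s video, %d frames, photon level %g",
              n_cells, paste(shape, collapse = "x"), T_len, photon_level),
      sprintf("train %s on %d independent scene pairs (not video frames)",
              arch$family, n_train_pairs),
      "denoise every frame independently",
      "extract traces (shared ground-truth positions) and compare arms")
    return(list(config = config, plan = plan))
  }

  # cell layout and transient traces
  scene <- make_nuclei_scene(shape, n_cells = n_cells,
                             photon_level = photon_level, seed = seed)
  tr <- make_transient_traces(n_cells, T_len = T_len, seed = seed + 1L)
  video <- make_semisynthetic_video(shape, scene$nuclei, tr,
                                    photon_level = photon_level,
                                    seed = seed + 2L)

  mdl <- model
  if (is.null(mdl)) {
    lseed <- seed + 31L
    train_pairs <- lapply(seq_len(n_train_pairs), function(i) {
      s <- make_nuclei_scene(train_shape, n_cells = max(4L, n_cells %/% 4L),
                             photon_level = photon_level, seed = lseed + i)
      list(clean = unclass(s$clean),
           noisy = unclass(corrupt(s$clean, seed = lseed + 500000L + i)))
    })
    fit <- niddl(train_pairs, arch = arch, loss = loss, epochs = epochs,
                 epoch_size = epoch_size, batch_size = batch_size, lr = lr,
                 seed = lseed)
    mdl <- fit$model
  }
  denoised <- denoise_video(mdl, video$noisy)

  tracks <- cell_tracks(video$nuclei$centers, T_len = T_len)
  t_gt <- extract_roi(video$clean, tracks, roi)
  t_noisy <- extract_roi(video$noisy, tracks, roi)
  t_den <- extract_roi(denoised, tracks, roi)

  mae_noisy <- trace_mae(t_noisy, t_gt)
  mae_den <- trace_mae(t_den, t_gt)
  r_noisy <- trace_pearson(t_noisy, t_gt)
  r_den <- trace_pearson(t_den, t_gt)

  cg <- pairwise_corr(t_gt); cn <- pairwise_corr(t_noisy)
  cd <- pairwise_corr(t_den)
  fro <- function(a, b) {
    d <- a - b
    sqrt(sum(d[is.finite(d)]^2))
  }
  list(config = config,
       mae = list(noisy = mae_noisy, denoised = mae_den),
       pearson = list(noisy = r_noisy, denoised = r_den),
       corr_frobenius = list(noisy = fro(cn, cg), denoised = fro(cd, cg)),
       pca = list(gt = pca_traces(t_gt), noisy = pca_traces(t_noisy),
                  denoised = pca_traces(t_den)),
       traces = list(gt = t_gt, noisy = t_noisy, denoised = t_den),
       model = mdl)
}
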