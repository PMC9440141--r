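#' Fit a supervised denoising network
#'
#' The front door of the package: trains a compact encoder--decoder CNN to
#' map low-SNR (noisy) image planes to high-SNR (clean) planes, using small
#' sets of temporally independent image pairs. The fitted object is applied
#' frame-independently to stacks and videos via \code{\link{predict.niddl}}
#' (or \code{\link{denoise_stack}} / \code{\link{denoise_video}}).
#'
#' @param pairs a \code{\link{paired_dataset}}, or a plain list of
#'   \code{list(noisy =, clean =)} stacks (then split with
#'   \code{val_frac}).
#' @param arch an \code{\link{arch_spec}}; its \code{mode}/\code{context_d}
#'   drive the sampling mode.
#' @param loss \code{"l1"} (default; more stable across training runs) or
#'   \code{"l2"}.
#' @param epochs,epoch_size,batch_size,lr training schedule; see
#'   \code{\link{train_config}}.
#' @param seed seed controlling weight initialisation, the data split and
#'   the sampling order.
#' @param val_frac validation fraction when \code{pairs} is a plain list.
#' @param checkpoint optional RDS path for the best model.
#' @param verbose log per-epoch progress.
#' @return an object of class \code{"niddl"} with components \code{model},
#'   \code{record}, \code{arch}, \code{config}, \code{call}.
#' @examples
#' \donttest{
#' scn <- lapply(1:8, function(i) {
#'   s <- make_nuclei_scene(c(1, 64, 64), n_cells = 6, photon_level = 200,
#'                          seed = i)
#'   list(clean = unclass(s$clean),
#'        noisy = unclass(corrupt(s$clean, seed = i + 100)))
#' })
#' fit <- niddl(scn, arch = arch_spec("unet_fixed", levels = 2,
#'                                    blocks = c(1, 1, 1)),
#'              epochs = 1, epoch_size = 8, batch_size = 2, seed = 1)
#' den <- predict(fit, scn[[1]]$noisy)
#' }
#' @export
niddl <- function(pairs, arch = arch_spec("unet_fixed"),
                  loss = c("l1", "l2"), epochs = 100L, epoch_size = 1000L,
                  batch_size = 50L, lr = 1e-3, seed = 0L, val_frac = 0.1,
                  checkpoint = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  cl <- match.call()
  if (!inherits(pairs, "niddl_pairs"))
    pairs <- paired_dataset(pairs, val_frac = val_frac, seed = seed)
  cfg <- train_config(loss = loss, lr = lr, batch_size = batch_size,
                      epoch_size = epoch_size, epochs = epochs,
                      mode = arch$mode, context_d = arch$context_d,
                      seed = seed)
  model <- build_model(arch, seed = seed)
  fit <- train_model(model, pairs, cfg, checkpoint = checkpoint,
                     verbose = verbose)
  structure(list(model = fit$model, record = fit$record, arch = arch,
                 config = cfg, dataset = pairs, call = cl),
            class = "niddl")
}

#' @export
print.niddl <- function(x, ...) {
  cat("niddl denoiser\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  architecture: ", x$arch$family, " (", x$arch$mode, ", ",
      format(count_parameters(x$model), big.mark = ","), " parameters, ",
      sprintf("%.2f", model_size_mb(x$model)), " MB)\n", sep = "")
  if (nrow(x$record) > 0) {
    cat("  epochs: ", nrow(x$record), ", final train ", x$config$loss,
        " loss: ", sprintf("%.5f", utils::tail(x$record$train_loss, 1)),
        "\n", sep = "")
    if (any(is.finite(x$record$val_rmse)))
      cat("  best validation RMSE: ",
          sprintf("%.5f", min(x$record$val_rmse, na.rm = TRUE)),
          " (normalized units)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.niddl <- function(object, ...) {
  out <- list(
    family = object$arch$family,
    mode = object$arch$mode,
    parameters = count_parameters(object$model),
    size_mb = model_size_mb(object$model),
    loss = object$config$loss,
    epochs = nrow(object$record),
    final_train_loss = if (nrow(object$record)) {
      utils::tail(object$record$train_loss, 1)
    } else NA_real_,
    best_val_rmse = if (any(is.finite(object$record$val_rmse))) {
      min(object$record$val_rmse, na.rm = TRUE)
    } else NA_real_,
    pairs = length(object$dataset$pairs))
  class(out) <- "summary.niddl"
  out
}

#' @export
print.summary.niddl <- function(x, ...) {
  cat("Supervised denoising network\n")
  cat(sprintf("  %s / %s, %s parameters (%.2f MB)\n", x$family, x$mode,
              format(x$parameters, big.mark = ","), x$size_mb))
  cat(sprintf("  trained %d epochs on %d image pairs (%s loss)\n",
              x$epochs, x$pairs, x$loss))
  if (is.finite(x$final_train_loss))
    cat(sprintf("  final training loss: %.5f\n", x$final_train_loss))
  if (is.finite(x$best_val_rmse))
    cat(sprintf("  best validation RMSE: %.5f (normalized units)\n",
                x$best_val_rmse))
  invisible(x)
}

#' @export
coef.niddl <- function(object, ...) object$model$params

#' Denoise new data with a fitted network
#'
#' Dispatches on the shape of \code{newdata}: a 2D matrix is treated as a
#' single plane, a 3D array as a stack (z, y, x), a 4D array as a video
#' (t, z, y, x) whose frames are denoised independently.
#'
#' @param object a \code{"niddl"} fit.
#' @param newdata matrix, stack or video.
#' @param ... passed to \code{\link{denoise_stack}} (tiling options).
#' @return denoised data of the same shape.
#' @export
predict.niddl <- function(object, newdata, ...) {
  nd <- length(dim(newdata) %||% 1L)
  if (is.matrix(newdata)) {
    out <- denoise_stack(object$model, array(newdata, c(1L, dim(newdata))),
                         ...)
    return(matrix(out[1, , ], nrow(newdata), ncol(newdata)))
  }
  if (nd == 3L) return(denoise_stack(object$model, newdata, ...))
  if (nd == 4L) return(denoise_video(object$model, newdata, ...))
  stop("newdata must be a 2D plane, 3D stack or 4D video", call. = FALSE)
}

#' @export
plot.niddl <- function(x, ...) {
  r <- x$record
  if (nrow(r) == 0) {
    warning("no training record to plot")
    return(invisible(x))
  }
  graphics::plot(r$epoch, r$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = paste0("training ", x$config$loss,
                                               " loss"),
                 main = paste0(x$arch$family, " training curve"), ...)
  if (any(is.finite(r$val_rmse))) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(r$epoch, r$val_rmse, type = "l", col = "red", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4, col.axis = "red")
    graphics::mtext("validation RMSE", side = 4, line = 2, col = "red")
  }
  invisible(x)
}

#' Residuals of a fitted denoiser
#'
#' Denoises the requested pair's noisy stack and returns the difference to
#' its clean counterpart on the normalized scale used by the metrics.
#'
#' @param object a \code{"niddl"} fit.
#' @param pair index of the pair to evaluate (default: first validation
#'   pair, else first pair).
#' @param ... unused.
#' @return array of normalized residuals (denoised minus clean).
#' @export
residuals.niddl <- function(object, pair = NULL, ...) {
  ds <- object$dataset
  if (is.null(pair)) {
    pair <- which(ds$split == "val")[1]
    if (is.na(pair)) pair <- 1L
  }
  p <- ds$pairs[[pair]]
  den <- denoise_stack(object$model, p$noisy)
  suppress_norm_warn(unclass(den)) - suppress_norm_warn(unclass(p$clean))
}
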