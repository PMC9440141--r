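## ---------------------------------------------------------------------------
## Paired datasets, sampling modes, and supervised training.

#' Build a paired noisy/clean dataset
#'
#' @param pairs list of \code{list(noisy =, clean =)} stacks (3D arrays) of
#'   identical shape within each pair.
#' @param val_frac fraction of pairs held out for validation (whole stacks,
#'   never individual planes, to avoid z-plane leakage).
#' @param test_frac fraction of pairs held out for testing; test pairs are
#'   never visited by training.
#' @param seed seed for the split assignment.
#' @return an object of class \code{"niddl_pairs"} with a \code{split}
#'   factor (\code{train}/\code{val}/\code{test}) per pair.
#' @export
paired_dataset <- function(pairs, val_frac = 0.1, test_frac = 0, seed = 0L) {
  stopifnot(length(pairs) >= 1)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (is.null(p$noisy) || is.null(p$clean))
      stop("pair ", i, " must have $noisy and $clean", call. = FALSE)
    if (!identical(dim(p$noisy), dim(p$clean)))
      stop("pair ", i, ": noisy and clean shapes differ", call. = FALSE)
  }
  n <- length(pairs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  n_test <- floor(test_frac * n)
  n_val <- floor(val_frac * n)
  split <- rep("train", n)
  if (n_test > 0) split[idx[seq_len(n_test)]] <- "test"
  if (n_val > 0) split[idx[n_test + seq_len(n_val)]] <- "val"
  if (!any(split == "train")) stop("empty training split", call. = FALSE)
  structure(list(pairs = pairs, split = split), class = "niddl_pairs")
}

#' @export
print.niddl_pairs <- function(x, ...) {
  cat("niddl paired dataset: ", length(x$pairs), " pairs (",
      sum(x$split == "train"), " train / ", sum(x$split == "val"),
      " val / ", sum(x$split == "test"), " test)\n", sep = "")
  invisible(x)
}

# Min-max normalization to [0, 1], per image/sample; constant inputs map to
# zeros. Returns the mapping so predictions can be taken back to the
# original intensity range.
norm01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) list(x = x * 0, lo = lo, hi = hi)
  else list(x = (x - lo) / (hi - lo), lo = lo, hi = hi)
}

denorm01 <- function(x, nfo) {
  if (nfo$hi == nfo$lo) x + nfo$lo else x * (nfo$hi - nfo$lo) + nfo$lo
}

# Row-vectorize a (y, x) matrix into the engine's spatial order
# n = (d*H + h)*W + w.
vec_plane <- function(m) as.vector(t(m))
unvec_plane <- function(v, H, W) t(matrix(v, W, H))

#' Enumerate training samples for a mode
#'
#' 2d mode yields one sample per z-plane; 2p5d yields interior planes (a
#' \code{(2*context_d+1)}-plane neighbourhood in, the clean centre plane
#' out); 3d yields consecutive non-overlapping chunks of \code{context_d}
#' planes. Every sample is min-max normalized per image at fetch time.
#'
#' @param dataset a \code{"niddl_pairs"}.
#' @param mode \code{"2d"}, \code{"2p5d"} or \code{"3d"}.
#' @param context_d z-context (see \code{\link{arch_spec}}).
#' @param subset which split(s) to draw from.
#' @return an object of class \code{"niddl_samples"}: an index table plus a
#'   \code{fetch(i)} closure returning \code{list(x, y, dims)}.
#' @export
make_training_samples <- function(dataset, mode = "2d", context_d = 1L,
                                  subset = "train") {
  stopifnot(inherits(dataset, "niddl_pairs"))
  mode <- match.arg(mode, c("2d", "2p5d", "3d"))
  keep <- which(dataset$split %in% subset)
  rows <- list()
  for (i in keep) {
    nz <- dim(dataset$pairs[[i]]$noisy)[1]
    zc <- switch(mode,
      "2d" = seq_len(nz),
      "2p5d" = {
        if (nz < 2L * context_d + 1L)
          stop("stack ", i, " has ", nz, " planes; 2p5d with context_d = ",
               context_d, " needs at least ", 2L * context_d + 1L,
               call. = FALSE)
        (context_d + 1L):(nz - context_d)
      },
      "3d" = {
        if (nz < context_d)
          stop("stack ", i, " has ", nz, " planes; 3d needs at least ",
               context_d, call. = FALSE)
        seq(1L, nz - context_d + 1L, by = context_d)
      })
    rows[[length(rows) + 1L]] <- data.frame(pair = i, z = zc)
  }
  index <- do.call(rbind, rows)
  fetch <- function(k, crop = NULL) {
    pair <- dataset$pairs[[index$pair[k]]]
    z <- index$z[k]
    fetch_mode_sample(pair, z, mode, context_d, crop)
  }
  structure(list(index = index, fetch = fetch, mode = mode,
                 context_d = context_d), class = "niddl_samples")
}

fetch_mode_sample <- function(pair, z, mode, context_d, crop = NULL) {
  sub <- function(a, zs) {
    m <- a[zs, , , drop = FALSE]
    if (!is.null(crop)) m <- m[, crop$y, crop$x, drop = FALSE]
    m
  }
  if (mode == "2d") {
    xs <- sub(pair$noisy, z); ys <- sub(pair$clean, z)
  } else if (mode == "2p5d") {
    xs <- sub(pair$noisy, (z - context_d):(z + context_d))
    ys <- sub(pair$clean, z)
  } else {
    zs <- z:min(z + context_d - 1L, dim(pair$noisy)[1])
    xs <- sub(pair$noisy, zs); ys <- sub(pair$clean, zs)
  }
  nx <- norm01(xs); ny <- norm01(ys)
  H <- dim(xs)[2]; W <- dim(xs)[3]
  if (mode == "3d") {
    D <- dim(xs)[1]
    x <- matrix(as.vector(aperm(nx$x, c(3, 2, 1))), nrow = 1)  # w,h,d fast->slow
    y <- matrix(as.vector(aperm(ny$x, c(3, 2, 1))), nrow = 1)
    dims <- c(D, H, W)
  } else {
    x <- t(apply(nx$x, 1, function(p) vec_plane(matrix(p, H, W))))
    if (dim(xs)[1] == 1L) x <- matrix(x, nrow = 1)
    y <- matrix(vec_plane(matrix(ny$x[1, , ], H, W)), nrow = 1)
    dims <- c(1L, H, W)
  }
  list(x = x, y = y, dims = dims, norm_x = nx[-1], norm_y = ny[-1])
}

#' Training configuration
#'
#' Defaults are the package's standard schedule: Adam with learning rate
#' 0.001,
#' batches of 50 samples, 1000 samples per epoch, 100 epochs. For
#' desk-scale experiments reduce \code{epochs}/\code{epoch_size};
#' \code{epochs * epoch_size / batch_size} is the number of optimizer steps.
#'
#' @param loss \code{"l1"} or \code{"l2"}.
#' @param lr Adam learning rate.
#' @param batch_size samples per optimizer step.
#' @param epoch_size training samples drawn per epoch.
#' @param epochs number of epochs.
#' @param mode,context_d sampling mode (must match the model's spec).
#' @param seed RNG seed for sampling order.
#' @param crop_hw planes larger than this on either side are trained on
#'   random square crops of this size.
#' @return an object of class \code{"niddl_train_config"}.
#' @export
train_config <- function(loss = c("l1", "l2"), lr = 1e-3, batch_size = 50L,
                         epoch_size = 1000L, epochs = 100L,
                         mode = c("2d", "2p5d", "3d"), context_d = 1L,
                         seed = 0L, crop_hw = 512L) {
  loss <- match.arg(loss)
  mode <- match.arg(mode)
  structure(list(loss = loss, lr = lr, batch_size = as.integer(batch_size),
                 epoch_size = as.integer(epoch_size),
                 epochs = as.integer(epochs), mode = mode,
                 context_d = as.integer(context_d), seed = as.integer(seed),
                 crop_hw = as.integer(crop_hw)),
            class = "niddl_train_config")
}

# Forward a fetched sample and return prediction + loss (+ gradients).
step_sample <- function(model, smp, loss, with_grad = TRUE, enc = NULL) {
  r <- exec_batch(model, list(smp$x), list(smp$y), smp$dims, loss = loss,
                  want_grads = with_grad, want_pred = TRUE, enc = enc)
  list(loss = r$loss, pred = r$preds[[1]], grads = r$grads)
}

val_rmse_of <- function(model, samples, max_n = 64L, enc = NULL) {
  n <- nrow(samples$index)
  if (n == 0) return(NA_real_)
  if (is.null(enc)) enc <- encode_graph(model)
  ks <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  se <- 0; cnt <- 0
  for (k in ks) {
    smp <- samples$fetch(k)
    r <- exec_batch(model, list(smp$x), dims = smp$dims, want_pred = TRUE,
                    enc = enc)
    se <- se + sum((r$preds[[1]] - smp$y)^2)
    cnt <- cnt + length(smp$y)
  }
  sqrt(se / cnt)
}

#' Train a denoising network
#'
#' Stochastic gradient training with Adam on per-image min-max normalized
#' noisy/clean sample pairs. After every epoch the validation RMSE (in
#' normalized units) is evaluated; the returned model carries the parameters
#' of the best validation epoch (or the final parameters when the dataset
#' has no validation split). Fully reproducible given
#' \code{config$seed}.
#'
#' @param model a \code{"niddl_model"} (untrained or trained).
#' @param dataset a \code{"niddl_pairs"}.
#' @param config a \code{\link{train_config}}; its \code{mode}/
#'   \code{context_d} must match the model spec.
#' @param checkpoint optional path: the best model is saved (RDS) each time
#'   validation RMSE improves.
#' @param verbose log per-epoch progress.
#' @return list with \code{model} (trained) and \code{record} (data frame of
#'   per-epoch training loss, validation RMSE and wall time).
#' @export
train_model <- function(model, dataset, config = train_config(),
                        checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "niddl_model"), inherits(dataset, "niddl_pairs"),
            inherits(config, "niddl_train_config"))
  if (!is.null(model$spec) && model$spec$mode != config$mode)
    stop("model mode ", model$spec$mode, " != config mode ", config$mode,
         call. = FALSE)
  samples <- make_training_samples(dataset, config$mode, config$context_d,
                                   subset = "train")
  val_samples <- if (any(dataset$split == "val"))
    make_training_samples(dataset, config$mode, config$context_d,
                          subset = "val") else NULL
  record <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_rmse = numeric(), seconds = numeric())
  if (config$epochs == 0L)
    return(list(model = model, record = record))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  state <- adam_init(model$params)
  enc <- encode_graph(model)
  n_samp <- nrow(samples$index)
  steps_per_epoch <- max(1L, ceiling(config$epoch_size / config$batch_size))
  best <- list(rmse = Inf, params = model$params)
  step_ix <- 0L
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    epoch_loss <- 0
    for (s in seq_len(steps_per_epoch)) {
      step_ix <- step_ix + 1L
      ks <- sample.int(n_samp, size = min(config$batch_size, n_samp),
                       replace = n_samp < config$batch_size)
      smps <- lapply(ks, function(k) fetch_with_crop(samples, k, dataset,
                                                     config))
      r <- exec_batch(model, lapply(smps, `[[`, "x"),
                      lapply(smps, `[[`, "y"), smps[[1]]$dims,
                      loss = config$loss, want_grads = TRUE, enc = enc)
      if (!is.finite(r$loss))
        stop("non-finite loss at step ", step_ix,
             " (batch of samples ", paste(ks, collapse = ","), ")",
             call. = FALSE)
      upd <- adam_step(model$params, r$grads, state, lr = config$lr)
      model$params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + r$loss
    }
    vr <- if (!is.null(val_samples)) val_rmse_of(model, val_samples,
                                                 enc = enc)
          else NA_real_
    el <- proc.time()[["elapsed"]] - t0
    record <- rbind(record, data.frame(
      epoch = epoch, train_loss = epoch_loss / steps_per_epoch,
      val_rmse = vr, seconds = el))
    if (verbose)
      niddl_log("info", sprintf("epoch %d: loss %.5f, val RMSE %s (%.1fs)",
                                epoch, epoch_loss / steps_per_epoch,
                                ifelse(is.na(vr), "-", sprintf("%.5f", vr)),
                                el))
    if (!is.na(vr) && vr < best$rmse) {
      best <- list(rmse = vr, params = model$params)
      if (!is.null(checkpoint)) {
        model_tmp <- model
        model_tmp$trained <- TRUE
        saveRDS(model_tmp, checkpoint)
      }
    }
  }
  if (!is.null(val_samples) && is.finite(best$rmse))
    model$params <- best$params
  model$trained <- TRUE
  model$provenance$train_seed <- config$seed
  model$provenance$loss <- config$loss
  model$provenance$epochs <- config$epochs
  if (!is.null(checkpoint) && is.null(val_samples)) saveRDS(model, checkpoint)
  list(model = model, record = record)
}

fetch_with_crop <- function(samples, k, dataset, config) {
  pair <- dataset$pairs[[samples$index$pair[k]]]
  H <- dim(pair$noisy)[2]; W <- dim(pair$noisy)[3]
  crop <- NULL
  if (H > config$crop_hw || W > config$crop_hw) {
    ch <- min(H, 256L); cw <- min(W, 256L)
    y0 <- sample.int(H - ch + 1L, 1L); x0 <- sample.int(W - cw + 1L, 1L)
    crop <- list(y = y0:(y0 + ch - 1L), x = x0:(x0 + cw - 1L))
  }
  samples$fetch(k, crop = crop)
}

#' Accuracy versus training-set size
#'
#' Trains \code{repeats} model instances per requested training-set size on
#' random subsets of the training pairs and summarises held-out test RMSE
#' (on normalized images) per size.
#'
#' @param dataset a \code{"niddl_pairs"} with a test split.
#' @param sizes integer vector of training-set sizes (in pairs).
#' @param spec an \code{\link{arch_spec}} for the trained instances.
#' @param config a \code{\link{train_config}}.
#' @param repeats instances per size.
#' @param seed base seed; instance r of size s uses a derived sub-seed.
#' @return data frame with one row per (size, repeat): size, repeat, rmse.
#' @export
training_size_sweep <- function(dataset, sizes, spec, config, repeats = 10L,
                                seed = 0L) {
  train_ids <- which(dataset$split == "train")
  if (max(sizes) > length(train_ids))
    stop("requested size ", max(sizes), " exceeds available training pairs (",
         length(train_ids), ")", call. = FALSE)
  test_samples <- make_training_samples(dataset, config$mode,
                                        config$context_d, subset = "test")
  out <- list()
  for (si in seq_along(sizes)) {
    for (r in seq_len(repeats)) {
      sub_seed <- (seed + 1009L * r + sizes[si]) %% .Machine$integer.max
      old <- .Random.seed_save()
      set.seed(sub_seed)
      chosen <- sample(train_ids, sizes[si])
      .Random.seed_restore(old)
      sub <- dataset
      sub$split <- ifelse(seq_along(dataset$split) %in% chosen,
                          "train", "ignore")
      cfg <- config
      cfg$seed <- sub_seed
      model <- build_model(spec, seed = sub_seed)
      fit <- train_model(model, sub, cfg)
      rmse <- val_rmse_of(fit$model, test_samples)
      out[[length(out) + 1L]] <- data.frame(size = sizes[si], rep = r,
                                            rmse = rmse)
    }
  }
  do.call(rbind, out)
}
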