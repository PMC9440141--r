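## ---------------------------------------------------------------------------
## Applying trained models to stacks and videos, plus classical baselines.

# Reflect-pad a (y, x) matrix on the bottom/right so both sides are
# multiples of `mult`; returns the padded matrix and the original size.
pad_to_multiple <- function(m, mult) {
  H <- nrow(m); W <- ncol(m)
  Hp <- ceiling(H / mult) * mult
  Wp <- ceiling(W / mult) * mult
  if (Hp == H && Wp == W) return(list(m = m, H = H, W = W))
  out <- matrix(0, Hp, Wp)
  out[1:H, 1:W] <- m
  if (Hp > H) out[(H + 1):Hp, 1:W] <- m[H - (seq_len(Hp - H) - 1), 1:W]
  if (Wp > W) out[, (W + 1):Wp] <- out[, W - (seq_len(Wp - W) - 1)]
  list(m = out, H = H, W = W)
}

# Run the network on a multi-channel set of (y, x) planes (rows of channels
# after vectorization). Handles padding to the pooling multiple and optional
# tiling of large planes.
infer_planes <- function(model, planes, tile = 256L, overlap = 32L,
                         enc = NULL) {
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  mult <- 2L^(model$spec$levels %||% 0L)
  if (H > tile || W > tile)
    return(infer_tiled(model, planes, tile, overlap))
  pads <- lapply(planes, pad_to_multiple, mult = mult)
  Hp <- nrow(pads[[1]]$m); Wp <- ncol(pads[[1]]$m)
  x <- do.call(rbind, lapply(pads, function(p) vec_plane(p$m)))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  out <- exec_batch(model, list(x), dims = c(1L, Hp, Wp), want_pred = TRUE,
                    enc = enc)$preds[[1]]
  unvec_plane(out[1, ], Hp, Wp)[1:H, 1:W]
}

infer_tiled <- function(model, planes, tile, overlap) {
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  core <- tile - 2L * overlap
  out <- matrix(0, H, W)
  ys <- seq(1L, H, by = core)
  xs <- seq(1L, W, by = core)
  for (y0 in ys) for (x0 in xs) {
    y1 <- min(y0 + core - 1L, H); x1 <- min(x0 + core - 1L, W)
    ya <- max(1L, y0 - overlap); yb <- min(H, y1 + overlap)
    xa <- max(1L, x0 - overlap); xb <- min(W, x1 + overlap)
    sub <- lapply(planes, function(p) p[ya:yb, xa:xb, drop = FALSE])
    res <- infer_planes(model, sub, tile = .Machine$integer.max)
    out[y0:y1, x0:x1] <- res[(y0 - ya + 1):(y1 - ya + 1),
                             (x0 - xa + 1):(x1 - xa + 1)]
  }
  out
}

#' Denoise a 3D stack with a trained model
#'
#' Dispatches on the model's mode: \code{"2d"} denoises every z-plane
#' independently; \code{"2p5d"} feeds each plane with its z-neighbourhood
#' (edge planes replicate their nearest neighbours); \code{"3d"} processes
#' consecutive \code{context_d}-plane chunks. Inputs are min-max normalized
#' with the noisy data's own range and predictions are mapped back to that
#' range, so output intensities live on the input's scale.
#'
#' @param model a trained \code{"niddl_model"} (or the \code{"niddl"} fit
#'   object from \code{\link{niddl}}).
#' @param noisy a \code{"niddl_stack"} or 3D array (z, y, x).
#' @param tile,overlap tiling of planes larger than \code{tile} pixels per
#'   side, with \code{overlap}-pixel margins blended by centre-cropping.
#' @return denoised stack of the same shape.
#' @export
denoise_stack <- function(model, noisy, tile = 256L, overlap = 32L) {
  if (inherits(model, "niddl")) model <- model$model
  stopifnot(inherits(model, "niddl_model"))
  data <- unclass(noisy)
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  nz <- dim(data)[1]; H <- dim(data)[2]; W <- dim(data)[3]
  spec <- model$spec
  mode <- spec$mode %||% "2d"
  out <- array(0, dim(data))
  plane <- function(z) matrix(data[z, , ], H, W)
  enc <- encode_graph(model)
  if (mode == "2d") {
    if (H <= tile && W <= tile) {
      # batch all planes through one executor pass (chunked for memory)
      mult <- 2L^(spec$levels %||% 0L)
      nfos <- lapply(seq_len(nz), function(z) norm01(plane(z)))
      pads <- lapply(nfos, function(nf) pad_to_multiple(nf$x, mult))
      Hp <- nrow(pads[[1]]$m); Wp <- ncol(pads[[1]]$m)
      for (chunk in split(seq_len(nz), ceiling(seq_len(nz) / 8))) {
        X <- lapply(chunk, function(z) matrix(vec_plane(pads[[z]]$m),
                                              nrow = 1))
        preds <- exec_batch(model, X, dims = c(1L, Hp, Wp),
                            want_pred = TRUE, enc = enc)$preds
        for (i in seq_along(chunk)) {
          z <- chunk[i]
          out[z, , ] <- denorm01(unvec_plane(preds[[i]][1, ],
                                             Hp, Wp)[1:H, 1:W], nfos[[z]])
        }
      }
    } else {
      for (z in seq_len(nz)) {
        nfo <- norm01(plane(z))
        out[z, , ] <- denorm01(infer_planes(model, list(nfo$x), tile,
                                            overlap, enc = enc), nfo)
      }
    }
  } else if (mode == "2p5d") {
    d <- spec$context_d
    if (nz < 1L) stop("empty stack", call. = FALSE)
    for (z in seq_len(nz)) {
      zs <- pmin(pmax(z + (-d):d, 1L), nz)  # clamp at the borders
      nbh <- data[zs, , , drop = FALSE]
      nfo <- norm01(nbh)
      planes <- lapply(seq_along(zs), function(i) matrix(nfo$x[i, , ], H, W))
      out[z, , ] <- denorm01(infer_planes(model, planes, tile, overlap,
                                          enc = enc), nfo)
    }
  } else {  # 3d
    d <- spec$context_d
    if (nz < d) stop("stack has ", nz, " planes; 3d mode needs at least ", d,
                     call. = FALSE)
    starts <- seq(1L, nz, by = d)
    for (z0 in starts) {
      zs <- pmin(z0:(z0 + d - 1L), nz)
      chunk <- data[zs, , , drop = FALSE]
      nfo <- norm01(chunk)
      mult <- 2L^spec$levels
      pads <- lapply(seq_len(d), function(i)
        pad_to_multiple(matrix(nfo$x[i, , ], H, W), mult))
      Hp <- nrow(pads[[1]]$m); Wp <- ncol(pads[[1]]$m)
      x <- matrix(as.vector(do.call(c, lapply(pads, function(p)
        vec_plane(p$m)))), nrow = 1)
      res <- exec_batch(model, list(x), dims = c(d, Hp, Wp),
                        want_pred = TRUE, enc = enc)$preds[[1]]
      for (i in seq_len(d)) {
        pl <- unvec_plane(res[1, ((i - 1) * Hp * Wp + 1):(i * Hp * Wp)],
                          Hp, Wp)[1:H, 1:W]
        out[zs[i], , ] <- denorm01(pl, nfo)
      }
    }
  }
  if (inherits(noisy, "niddl_stack")) image_stack(out) else out
}

#' Denoise a video frame-independently
#'
#' Frame t of the output depends only on frame t of the input; temporal
#' reordering therefore commutes with denoising.
#'
#' @param model trained model (or \code{"niddl"} fit).
#' @param video a \code{"niddl_video"} (t, z, y, x).
#' @inheritParams denoise_stack
#' @return denoised \code{"niddl_video"}.
#' @export
denoise_video <- function(model, video, tile = 256L, overlap = 32L) {
  stopifnot(length(dim(video)) == 4L)
  out <- array(0, dim(video))
  for (t in seq_len(dim(video)[1])) {
    r <- tryCatch(
      denoise_stack(model, array(video[t, , , ], dim(video)[2:4]),
                    tile, overlap),
      error = function(e) stop("frame ", t, ": ", conditionMessage(e),
                               call. = FALSE))
    out[t, , , ] <- r
  }
  video_stack(out, attr(video, "dt_s"))
}

#' Maximum projection over z
#' @param stack 3D array (z, y, x).
#' @return (y, x) matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  apply(unclass(stack), c(2, 3), max)
}

#' Denoise per-frame maximum projections of a video
#'
#' For large-depth, low-magnification recordings the model is trained on
#' max-projection pairs and each frame's 3D stack is collapsed to its
#' maximum projection before 2D inference.
#'
#' @param model trained 2D-mode model.
#' @param video a \code{"niddl_video"}.
#' @inheritParams denoise_stack
#' @return 3D array (t, y, x) of denoised projections.
#' @export
denoise_maxproj <- function(model, video, tile = 256L, overlap = 32L) {
  if (inherits(model, "niddl")) model <- model$model
  if ((model$spec$mode %||% "2d") != "2d")
    stop("max-projection denoising needs a 2d-mode model", call. = FALSE)
  nt <- dim(video)[1]
  out <- array(0, c(nt, dim(video)[3], dim(video)[4]))
  for (t in seq_len(nt)) {
    mp <- max_project(array(video[t, , , ], dim(video)[2:4]))
    den <- denoise_stack(model, array(mp, c(1L, dim(mp))), tile, overlap)
    out[t, , ] <- den[1, , ]
  }
  out
}

## ---------------------------------------------------------------------------
## Classical baselines (2D filtering applied per z-plane; reflective
## boundaries).

#' Median-filter baseline
#'
#' @param img 2D matrix or 3D stack (filtered per plane).
#' @param window odd window size: 3, 5 or 7 in the standard sweep.
#' @return filtered image of the same shape.
#' @export
median_baseline <- function(img, window = 3L) {
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  apply_per_plane(img, function(m) img_median2d(m, as.integer(window)))
}

#' Gaussian-filter baseline
#'
#' Separable Gaussian smoothing (kernel radius 3 sigma, normalized, so the
#' image mean is preserved under the reflective boundary rule).
#'
#' @param img 2D matrix or 3D stack.
#' @param sigma standard deviation in pixels: 1, 3 or 5 in the reference
#'   sweep.
#' @return filtered image of the same shape.
#' @export
gaussian_baseline <- function(img, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  k <- gauss_kernel1d(sigma)
  apply_per_plane(img, function(m) img_sepconv2d(m, k))
}

apply_per_plane <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  data <- unclass(img)
  stopifnot(length(dim(data)) == 3L)
  out <- data
  for (z in seq_len(dim(data)[1]))
    out[z, , ] <- f(matrix(data[z, , ], dim(data)[2], dim(data)[3]))
  out
}

#' Pick the best baseline parameter against a reference
#'
#' Runs the median (windows 3/5/7) or Gaussian (sigmas 1/3/5) sweep and
#' returns the filtered image, parameter and RMSE (computed with the
#' package's normalized metric) for the best-performing setting.
#'
#' @param noisy,reference equally shaped images.
#' @param method \code{"median"} or \code{"gaussian"}.
#' @param params sweep values; defaults to the standard sweeps.
#' @return list with \code{denoised}, \code{param}, \code{rmse}.
#' @export
best_baseline <- function(noisy, reference, method = c("median", "gaussian"),
                          params = NULL) {
  method <- match.arg(method)
  if (is.null(params)) params <- if (method == "median") c(3, 5, 7)
                                 else c(1, 3, 5)
  best <- NULL
  for (p in params) {
    den <- if (method == "median") median_baseline(noisy, p)
           else gaussian_baseline(noisy, p)
    r <- rmse(den, reference)
    if (is.null(best) || r < best$rmse)
      best <- list(denoised = den, param = p, rmse = r)
  }
  best
}
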