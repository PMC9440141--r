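## ---------------------------------------------------------------------------
## Image-quality metrics. Because noisy and clean acquisitions have very
## different dynamic ranges, every metric first min-max normalizes both
## images independently to [0, 1]; all comparisons happen on that scale.

#' Min-max normalize an image to [0, 1]
#'
#' Constant images map to all zeros (with a log warning), since no contrast
#' information exists to preserve.
#'
#' @param img numeric array of any shape with finite values.
#' @return array of the same shape with range [0, 1].
#' @export
normalize_image <- function(img) {
  if (any(!is.finite(img))) stop("image must be finite", call. = FALSE)
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    niddl_log("warn", "normalize_image: constant image mapped to zeros")
    return(img * 0)
  }
  (img - lo) / (hi - lo)
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
}

#' Root-mean-square error between normalized images
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\mathrm{mean}((a' - b')^2)}} where \eqn{a', b'}
#' are the two images after independent min-max normalization.
#'
#' @param a,b equally shaped numeric arrays.
#' @return non-negative scalar; 0 iff the normalized images are identical.
#' @export
rmse <- function(a, b) {
  check_same_shape(a, b)
  an <- suppress_norm_warn(a); bn <- suppress_norm_warn(b)
  sqrt(mean((an - bn)^2))
}

suppress_norm_warn <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) x * 0 else (x - lo) / (hi - lo)
}

#' Peak signal-to-noise ratio (dB)
#'
#' \eqn{\mathrm{PSNR} = 20 \log_{10}(1/\mathrm{RMSE})} on normalized images
#' (peak value 1), capped at 100 dB for identical images.
#'
#' @inheritParams rmse
#' @return PSNR in decibels, at most 100.
#' @export
psnr <- function(a, b) {
  r <- rmse(a, b)
  if (r == 0) return(100)
  min(100, 20 * log10(1 / r))
}

#' Structural similarity index
#'
#' Standard windowed SSIM on normalized images: 7x7 Gaussian window
#' (sigma 1.5), constants k1 = 0.01, k2 = 0.03, data range 1. For stacks the
#' per-plane SSIM values are averaged.
#'
#' @inheritParams rmse
#' @return SSIM in [-1, 1]; 1 iff the normalized images are identical.
#' @export
ssim <- function(a, b) {
  check_same_shape(a, b)
  an <- suppress_norm_warn(a); bn <- suppress_norm_warn(b)
  if (is.matrix(an)) return(ssim_plane(an, bn))
  if (length(dim(an)) == 3L) {
    v <- vapply(seq_len(dim(an)[1]), function(z)
      ssim_plane(matrix(an[z, , ], dim(an)[2], dim(an)[3]),
                 matrix(bn[z, , ], dim(bn)[2], dim(bn)[3])), numeric(1))
    return(mean(v))
  }
  ssim_plane(as.matrix(an), as.matrix(bn))
}

ssim_plane <- function(a, b, k1 = 0.01, k2 = 0.03, L = 1,
                       sigma = 1.5, radius = 3L) {
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k <- k / sum(k)
  f <- function(m) img_sepconv2d(m, k)
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  vab <- f(a * b) - mu_a * mu_b
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  s <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Combined metric report
#'
#' @inheritParams rmse
#' @return list with \code{rmse}, \code{psnr}, \code{ssim} and the
#'   normalization rule applied.
#' @export
metric_report <- function(a, b) {
  list(rmse = rmse(a, b), psnr = psnr(a, b), ssim = ssim(a, b),
       normalization = "per-image min-max to [0,1]")
}

# Otsu's threshold on intensity values (256-bin histogram over the range).
otsu_threshold <- function(x) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * 256) + 1L, 1L), 256L),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  lo + k / 256 * (hi - lo)
}

#' Estimate image SNR from foreground and background statistics
#'
#' SNR = mean(foreground) / background noise standard deviation. Without an
#' explicit mask the foreground is thresholded automatically with Otsu's
#' method. The background standard deviation is estimated robustly (scaled
#' median absolute deviation), so that residual dim structure below the
#' threshold does not inflate the noise floor. This estimator is a declared
#' stand-in for "image SNR": the signal level of labeled structures
#' relative to the background noise fluctuation.
#'
#' @param img numeric array.
#' @param mask optional logical array marking the foreground.
#' @return positive scalar SNR estimate.
#' @export
estimate_snr <- function(img, mask = NULL) {
  img <- unclass(img)
  if (is.null(mask)) {
    if (max(img) == min(img))
      stop("cannot estimate SNR of a constant image", call. = FALSE)
    thr <- otsu_threshold(img)
    mask <- img > thr
  }
  if (!any(mask)) stop("empty foreground", call. = FALSE)
  if (all(mask)) stop("empty background", call. = FALSE)
  bg_sd <- stats::mad(img[!mask])
  if (bg_sd == 0) stop("background has zero variance", call. = FALSE)
  mean(img[mask]) / bg_sd
}
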