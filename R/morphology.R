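## ---------------------------------------------------------------------------
## Body-curvature analysis for freely moving recordings and the five-step
## neurite segmentation.

#' Fit a ventral-cord backbone through ordered cell positions
#'
#' Fits degree-4 polynomials x(s), y(s) by least squares against a monotone
#' arc parameter s (the normalized x-rank by default, or normalized
#' cumulative chord length), samples the curve at 100 equally spaced
#' parameter values and returns the tangent angle
#' \eqn{\theta(s) = \mathrm{atan2}(y'(s), x'(s))} at each sample.
#'
#' @param cell_xy n x 2 matrix of (x, y) positions, ordered along the cord;
#'   n >= 5 (a degree-4 fit needs five points).
#' @param n_samples number of backbone samples (100 in the reference
#'   protocol).
#' @param param \code{"xrank"} (default; assumes the cord does not fold back
#'   in x) or \code{"chord"} (cumulative chord length).
#' @return an object of class \code{"niddl_backbone"}: coefficients,
#'   \code{points} (n_samples x 2), \code{tangent_angles} (radians),
#'   \code{s} and per-point fit \code{residual}.
#' @export
fit_backbone <- function(cell_xy, n_samples = 100L,
                         param = c("xrank", "chord")) {
  param <- match.arg(param)
  cell_xy <- as.matrix(cell_xy)
  if (nrow(cell_xy) < 5L)
    stop("backbone fit needs at least 5 points", call. = FALSE)
  x <- cell_xy[, 1]; y <- cell_xy[, 2]
  s <- if (param == "xrank") {
    (rank(x, ties.method = "first") - 1) / (nrow(cell_xy) - 1)
  } else {
    cl <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    if (max(cl) == 0) stop("degenerate points", call. = FALSE)
    cl / max(cl)
  }
  V <- stats::poly(s, degree = 4, raw = TRUE)
  fx <- stats::lm.fit(cbind(1, V), x)
  fy <- stats::lm.fit(cbind(1, V), y)
  ss <- seq(0, 1, length.out = n_samples)
  Vs <- cbind(1, stats::poly(ss, degree = 4, raw = TRUE))
  px <- Vs %*% fx$coefficients
  py <- Vs %*% fy$coefficients
  # derivative design matrix d/ds of (1, s, s^2, s^3, s^4)
  Vd <- cbind(0, 1, 2 * ss, 3 * ss^2, 4 * ss^3)
  dx <- Vd %*% fx$coefficients
  dy <- Vd %*% fy$coefficients
  structure(list(coef_x = fx$coefficients, coef_y = fy$coefficients,
                 s = ss, points = cbind(x = px, y = py),
                 tangent_angles = atan2(dy, dx)[, 1],
                 residual = sqrt(sum(fx$residuals^2) + sum(fy$residuals^2))),
            class = "niddl_backbone")
}

#' @export
print.niddl_backbone <- function(x, ...) {
  cat("niddl backbone: ", length(x$s), " samples, residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Index of the backbone sample nearest to each cell
#' @param backbone a \code{"niddl_backbone"}.
#' @param cell_xy n x 2 matrix of (x, y) cell positions.
#' @return integer vector of sample indices (1..n_samples).
#' @export
nearest_backbone_sample <- function(backbone, cell_xy) {
  cell_xy <- as.matrix(cell_xy)
  apply(cell_xy, 1, function(p)
    which.min((backbone$points[, 1] - p[1])^2 +
              (backbone$points[, 2] - p[2])^2))
}

# Pearson correlation of a with b delayed by `lag` frames:
# cor(a[t], b[t - lag]).
cor_at_lag <- function(a, b, lag) {
  T_len <- length(a)
  if (lag >= 0) {
    ai <- (1 + lag):T_len; bi <- 1:(T_len - lag)
  } else {
    ai <- 1:(T_len + lag); bi <- (1 - lag):T_len
  }
  if (length(ai) < 3) return(NA_real_)
  if (stats::sd(a[ai]) == 0 || stats::sd(b[bi]) == 0) return(NA_real_)
  stats::cor(a[ai], b[bi])
}

#' Cross-correlate activity traces with backbone tangent angles
#'
#' For every cell and backbone position, computes the normalized (Pearson)
#' cross-correlation over lags \code{-max_lag..max_lag} and keeps the value
#' of largest magnitude (sign preserved). Zero-variance series yield NA.
#'
#' @param traces a \code{"niddl_traces"} (n cells x T).
#' @param angles n_positions x T matrix of tangent-angle time series.
#' @param max_lag lag window in frames.
#' @return list with \code{map} (n_cells x n_positions of signed peak
#'   correlations) and \code{lag} (the peak lag per entry).
#' @export
activity_curvature_xcorr <- function(traces, angles, max_lag = 10L) {
  v <- traces$values
  if (ncol(v) != ncol(angles))
    stop("traces and angles must share T", call. = FALSE)
  lags <- (-max_lag):max_lag
  n <- nrow(v); p <- nrow(angles)
  map <- matrix(NA_real_, n, p)
  lag_at <- matrix(NA_integer_, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      cs <- vapply(lags, function(l) cor_at_lag(v[i, ], angles[j, ], l),
                   numeric(1))
      if (all(is.na(cs))) next
      best <- which.max(abs(cs))
      map[i, j] <- cs[best]
      lag_at[i, j] <- lags[best]
    }
  }
  list(map = map, lag = lag_at)
}

#' Peak local activity-curvature correlation
#'
#' Evaluates the cross-correlation of each cell's trace with the tangent
#' angle at the cell's own (nearest) backbone position and summarises the
#' recording by the maximum absolute peak correlation across cells.
#'
#' @inheritParams activity_curvature_xcorr
#' @param cell_positions integer vector of backbone sample indices per cell
#'   (e.g. from \code{\link{nearest_backbone_sample}}).
#' @return list with \code{per_cell} (signed peak correlation at the local
#'   angle) and \code{summary} (max |per_cell|).
#' @export
local_max_abs <- function(traces, angles, cell_positions, max_lag = 10L) {
  v <- traces$values
  lags <- (-max_lag):max_lag
  per_cell <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    j <- cell_positions[i]
    cs <- vapply(lags, function(l) cor_at_lag(v[i, ], angles[j, ], l),
                 numeric(1))
    if (all(is.na(cs))) next
    per_cell[i] <- cs[which.max(abs(cs))]
  }
  list(per_cell = per_cell, summary = max(abs(per_cell), na.rm = TRUE))
}

## ---------------------------------------------------------------------------
## Neurite segmentation: sharpen, adaptive threshold, morphological opening,
## hole filling, size filtering.

#' Segment neurites in a 2D image
#'
#' Five morphological steps, each parameterized: (1) unsharp-mask
#' sharpening; (2) adaptive thresholding against the local mean over a
#' square window; (3) morphological opening (erosion followed by dilation)
#' with a small diamond brush to remove segmented noise; (4) filling of
#' small holes in the mask complement; (5) removal of connected structures
#' below a minimum pixel size.
#'
#' @param img 2D numeric matrix (use \code{\link{max_project}} for stacks).
#' @param sharpen_radius,sharpen_amount unsharp-mask Gaussian radius and
#'   strength.
#' @param thresh_window side of the local-mean window (odd).
#' @param thresh_offset additive offset on the local mean. The default
#'   (\code{NULL}) adapts to the image: 3 times the robust scale (MAD) of
#'   the local residual, so pure noise stays below threshold while
#'   structures well above the noise floor pass.
#' @param open_brush diameter of the opening brush (odd; 1 disables).
#' @param hole_max_area largest hole area (pixels) filled in step 4.
#' @param min_size smallest structure (pixels) kept in step 5.
#' @return logical matrix mask.
#' @export
segment_neurites <- function(img, sharpen_radius = 2, sharpen_amount = 1,
                             thresh_window = 25L, thresh_offset = NULL,
                             open_brush = 3L, hole_max_area = 20L,
                             min_size = 50L) {
  stopifnot(is.matrix(img))
  if (thresh_window %% 2L != 1L) stop("thresh_window must be odd",
                                      call. = FALSE)
  # (1) sharpen
  sm <- img_sepconv2d(img, gauss_kernel1d(sharpen_radius))
  sharp <- img + sharpen_amount * (img - sm)
  # (2) adaptive threshold (strict >, so blank regions stay background;
  # fluorescence is nonnegative, so the local threshold is floored at zero
  # to keep the negative unsharp ring from promoting background pixels)
  box <- rep(1 / thresh_window, thresh_window)
  localmean <- img_sepconv2d(sharp, box)
  if (is.null(thresh_offset))
    thresh_offset <- 3 * stats::mad(sharp - localmean)
  mask <- sharp > pmax(localmean + thresh_offset, 0)
  # (3) morphological opening
  if (open_brush > 1L) {
    brush <- EBImage::makeBrush(as.integer(open_brush), shape = "diamond")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  # (4) fill small holes in the complement
  mask <- fill_small_holes(mask, hole_max_area)
  # (5) remove small structures
  if (min_size > 0L) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    mask <- array(lab %in% keep, dim(mask))
  }
  mask
}

fill_small_holes <- function(mask, max_area) {
  if (max_area <= 0) return(mask)
  comp <- EBImage::bwlabel((!mask) * 1)
  if (max(comp) == 0) return(mask)
  border_labels <- unique(c(comp[1, ], comp[nrow(comp), ],
                            comp[, 1], comp[, ncol(comp)]))
  sizes <- tabulate(comp[comp > 0])
  fill <- setdiff(which(sizes <= max_area), border_labels)
  mask | array(comp %in% fill, dim(mask))
}

#' Recall of a segmentation against a known centreline
#'
#' Fraction of true skeleton pixels lying within \code{tol} pixels of the
#' mask (i.e. covered by the mask dilated by \code{tol}).
#'
#' @param mask logical segmentation mask.
#' @param skeleton logical centreline mask.
#' @param tol coverage tolerance in pixels.
#' @return scalar in [0, 1].
#' @export
segmentation_recall <- function(mask, skeleton, tol = 1L) {
  if (!any(skeleton)) return(NA_real_)
  if (tol > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(tol) + 1L, shape = "box")
    mask <- EBImage::dilate(mask * 1, brush) > 0.5
  }
  sum(mask & skeleton) / sum(skeleton)
}
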