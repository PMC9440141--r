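## ---------------------------------------------------------------------------
## Synthetic whole-brain scenes, semi-synthetic calcium videos and a neurite
## phantom. All coordinates are 1-based voxel indices in (z, y, x) order.

#' Construct a nucleus set
#'
#' Per-cell parameters of the 3D Gaussian intensity profiles that make up a
#' synthetic scene.
#'
#' @param centers n x 3 matrix of (z, y, x) centres in voxels.
#' @param covariances list of n symmetric positive-definite 3x3 matrices
#'   (voxel^2), rows/cols ordered (z, y, x).
#' @param peaks length-n vector of positive relative peak intensities.
#' @return an object of class \code{"niddl_nuclei"}.
#' @export
nucleus_set <- function(centers, covariances, peaks) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3L, length(covariances) == nrow(centers),
            length(peaks) == nrow(centers), all(peaks > 0))
  for (S in covariances) {
    if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, TRUE)$values <= 0))
      stop("covariances must be symmetric positive-definite", call. = FALSE)
  }
  structure(list(centers = centers, covariances = covariances,
                 peaks = as.numeric(peaks)),
            class = "niddl_nuclei")
}

#' @export
print.niddl_nuclei <- function(x, ...) {
  cat("niddl nucleus set: ", nrow(x$centers), " cells\n", sep = "")
  invisible(x)
}

# Sample a random 3D rotation (QR of a Gaussian matrix, sign-corrected).
random_rotation3 <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

# Rejection-sample cell centres uniformly inside the ellipsoid inscribed in
# the stack (a stand-in for the head region), keeping a minimum separation.
sample_centers <- function(shape, n_cells, min_sep, max_tries = 200L) {
  c0 <- (shape + 1) / 2
  radii <- pmax(shape / 2 - 1, 0.5)
  centers <- matrix(NA_real_, n_cells, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n_cells && tries < max_tries * n_cells) {
    tries <- tries + 1L
    u <- stats::rnorm(3)
    pt <- c0 + radii * (u / sqrt(sum(u^2))) * stats::runif(1)^(1 / 3)
    if (placed > 0L) {
      d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - pt)^2)
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- pt
  }
  if (placed < n_cells)
    stop("could not place ", n_cells, " cells with separation ", min_sep,
         "; achieved ", placed, call. = FALSE)
  centers
}

# Add one Gaussian profile (unit peak times `peak`) into `img` in place-ish;
# returns the updated array. Evaluation is restricted to a +/- 4 sigma box.
add_gaussian_cell <- function(img, center, covariance, peak) {
  shape <- dim(img)
  pre <- solve(covariance)
  ext <- 4 * sqrt(diag(covariance))
  lo <- pmax(ceiling(center - ext), 1)
  hi <- pmin(floor(center + ext), shape)
  if (any(lo > hi)) return(img)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  d <- sweep(grid, 2, center)
  q <- rowSums((d %*% pre) * d)
  img[zi, yi, xi] <- img[zi, yi, xi, drop = FALSE] +
    array(peak * exp(-0.5 * q), c(length(zi), length(yi), length(xi)))
  img
}

# Affine rescale to [0, photon_level].
rescale_photon <- function(x, photon_level) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1]) * photon_level
}

#' Generate a synthetic whole-brain scene
#'
#' Simulates densely packed nuclei as a sum of 3D Gaussian intensity
#' profiles: centres are drawn uniformly inside the ellipsoid inscribed in
#' the stack with a minimum separation, sizes are random anisotropic
#' covariances (lateral sigma 1.5--3 voxels, axial 1--2, randomly rotated),
#' and relative peak intensities are uniform in [0.3, 1]. The summed image is
#' affinely rescaled so its minimum is 0 and its maximum equals
#' \code{photon_level} (the peak photon count).
#'
#' @param shape stack shape (z, y, x).
#' @param n_cells number of nuclei.
#' @param photon_level peak photon count of the clean image.
#' @param seed RNG seed.
#' @param min_sep minimum centre separation in voxels.
#' @param sigma_lat,sigma_ax ranges for lateral/axial standard deviations.
#' @param peak_range range of relative peak intensities.
#' @return list with \code{clean} (a \code{"niddl_stack"}) and \code{nuclei}
#'   (a \code{"niddl_nuclei"}).
#' @export
make_nuclei_scene <- function(shape, n_cells = 60L, photon_level = 1000,
                              seed = 0L, min_sep = 3,
                              sigma_lat = c(1.5, 3), sigma_ax = c(1, 2),
                              peak_range = c(0.3, 1)) {
  stopifnot(length(shape) == 3L, all(shape >= 1), photon_level > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- sample_centers(shape, n_cells, min_sep)
  covariances <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    s <- c(stats::runif(1, sigma_ax[1], sigma_ax[2]),
           stats::runif(1, sigma_lat[1], sigma_lat[2]),
           stats::runif(1, sigma_lat[1], sigma_lat[2]))
    rot <- random_rotation3()
    S <- rot %*% diag(s^2) %*% t(rot)
    covariances[[i]] <- (S + t(S)) / 2
  }
  peaks <- stats::runif(n_cells, peak_range[1], peak_range[2])
  nuclei <- nucleus_set(centers, covariances, peaks)
  img <- array(0, shape)
  for (i in seq_len(n_cells))
    img <- add_gaussian_cell(img, centers[i, ], covariances[[i]], peaks[i])
  clean <- rescale_photon(img, photon_level)
  list(clean = image_stack(clean), nuclei = nuclei)
}

#' Describe the camera noise model
#'
#' @param photon_level peak photon count the clean signal is scaled to
#'   (recorded for provenance; the corruption itself reads the pixel values).
#' @param readout_sigma standard deviation of the additive Gaussian readout
#'   noise (default 1, i.e. unit variance).
#' @param readout_mean mean of the readout noise (default 0).
#' @return an object of class \code{"niddl_noise"}.
#' @export
noise_spec <- function(photon_level = NULL, readout_sigma = 1,
                       readout_mean = 0) {
  stopifnot(readout_sigma >= 0)
  structure(list(photon_level = photon_level, readout_sigma = readout_sigma,
                 readout_mean = readout_mean), class = "niddl_noise")
}

#' Corrupt a clean image with shot and readout noise
#'
#' Each voxel independently becomes
#' \eqn{\mathrm{Poisson}(clean) + \mathcal{N}(\mu, \sigma^2)}: photon shot
#' noise whose variance equals the expected photon count, plus Gaussian
#' camera readout noise (default mean 0, variance 1).
#'
#' @param clean non-negative array (stack, video, or plain array).
#' @param noise a \code{\link{noise_spec}}.
#' @param seed RNG seed.
#' @return array of the same shape and class as \code{clean}.
#' @export
corrupt <- function(clean, noise = noise_spec(), seed = 0L) {
  if (any(clean < 0)) stop("clean image must be non-negative", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(clean)
  noisy <- clean
  noisy[] <- stats::rpois(n, lambda = as.vector(clean)) +
    stats::rnorm(n, mean = noise$readout_mean, sd = noise$readout_sigma)
  noisy
}

#' Generate calcium-transient-like traces
#'
#' Each cell's trace is a constant baseline plus a Poisson-count number of
#' transients with instantaneous rise and exponential decay:
#' \eqn{y(t) = b + \sum_k A\, e^{-(t - t_k)/\tau}} for \eqn{t \ge t_k}.
#' This is a generative stand-in for sampled experimental recordings that
#' preserves the temporal structure relevant for recovery tests (sparse
#' onsets, exponential decay at the indicator timescale).
#'
#' @param n_cells number of cells.
#' @param T_len number of timepoints (frames).
#' @param seed RNG seed.
#' @param baseline constant baseline level (relative units).
#' @param amplitude transient amplitude A (relative units).
#' @param rate expected transients per frame (Poisson).
#' @param tau decay constant in frames.
#' @param onsets optional list (length \code{n_cells}) of fixed onset frames,
#'   overriding the random draws; useful for controlled experiments.
#' @return a \code{"niddl_traces"} with values >= 0.
#' @export
make_transient_traces <- function(n_cells, T_len = 100L, seed = 0L,
                                  baseline = 0.2, amplitude = 0.8,
                                  rate = 0.03, tau = 8,
                                  onsets = NULL) {
  stopifnot(T_len >= 1L, baseline >= 0, amplitude >= 0, rate >= 0, tau > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tgrid <- seq_len(T_len)
  v <- matrix(baseline, n_cells, T_len)
  for (i in seq_len(n_cells)) {
    t0s <- if (!is.null(onsets)) onsets[[i]]
           else sample.int(T_len, size = min(stats::rpois(1, rate * T_len),
                                             T_len))
    for (t0 in t0s) {
      on_ <- tgrid >= t0
      v[i, on_] <- v[i, on_] + amplitude * exp(-(tgrid[on_] - t0) / tau)
    }
  }
  trace_matrix(v)
}

#' Read cell positions from a CSV atlas
#'
#' Expects columns \code{cell_id,x,y,z} (atlas convention); coordinates are
#' returned in (z, y, x) voxel order.
#'
#' @param path CSV file.
#' @return matrix n x 3 of (z, y, x) with rownames from \code{cell_id}.
#' @export
read_positions_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "x", "y", "z") %in% names(df)))
  m <- cbind(z = df$z, y = df$y, x = df$x)
  rownames(m) <- df$cell_id
  m
}

#' Generate a semi-synthetic calcium video with known ground truth
#'
#' Renders, for every time point, the Gaussian nucleus scene with cell i's
#' peak intensity modulated by \code{traces$values[i, t]}; all frames are
#' then jointly rescaled (global maximum and minimum across frames) so the
#' video peak equals \code{photon_level}, and the noisy video is produced by
#' \code{\link{corrupt}} applied to every frame. Ground-truth traces are the
#' clean-video intensities at the (rounded) cell centres, i.e. in
#' post-rescale units.
#'
#' @param shape stack shape (z, y, x) of each frame.
#' @param positions a \code{"niddl_nuclei"}, or an n x 3 (z, y, x) centre
#'   matrix (covariances and relative peaks are then drawn as in
#'   \code{\link{make_nuclei_scene}}), or a path to a positions CSV.
#' @param traces a \code{"niddl_traces"} with one row per cell.
#' @param photon_level peak photon count across the whole video.
#' @param seed RNG seed (cell properties if needed, then noise).
#' @param noise a \code{\link{noise_spec}} for the corruption step.
#' @param per_frame rescale each frame separately instead of globally
#'   (sensitivity checks only; the global rule is the documented one).
#' @return list with \code{clean}, \code{noisy} (\code{"niddl_video"}),
#'   \code{traces_gt} (\code{"niddl_traces"}) and \code{nuclei}.
#' @export
make_semisynthetic_video <- function(shape, positions, traces,
                                     photon_level = 200, seed = 0L,
                                     noise = noise_spec(),
                                     per_frame = FALSE) {
  stopifnot(length(shape) == 3L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.character(positions)) positions <- read_positions_csv(positions)
  if (!inherits(positions, "niddl_nuclei")) {
    centers <- as.matrix(positions)
    n <- nrow(centers)
    covariances <- vector("list", n)
    for (i in seq_len(n)) {
      s <- c(stats::runif(1, 1, 2), stats::runif(1, 1.5, 3),
             stats::runif(1, 1.5, 3))
      rot <- random_rotation3()
      S <- rot %*% diag(s^2) %*% t(rot)
      covariances[[i]] <- (S + t(S)) / 2
    }
    positions <- nucleus_set(centers, covariances,
                             stats::runif(n, 0.3, 1))
  }
  n_cells <- nrow(positions$centers)
  if (nrow(traces$values) != n_cells)
    stop("traces has ", nrow(traces$values), " rows but positions has ",
         n_cells, " cells", call. = FALSE)
  T_len <- ncol(traces$values)

  clean <- array(0, c(T_len, shape))
  frame <- array(0, shape)
  for (t in seq_len(T_len)) {
    frame[] <- 0
    for (i in seq_len(n_cells))
      frame <- add_gaussian_cell(frame, positions$centers[i, ],
                                 positions$covariances[[i]],
                                 positions$peaks[i] * traces$values[i, t])
    clean[t, , , ] <- frame
  }
  if (per_frame) {
    for (t in seq_len(T_len))
      clean[t, , , ] <- rescale_photon(clean[t, , , ], photon_level)
  } else {
    clean <- rescale_photon(clean, photon_level)
  }
  noise_seed <- seed + 1L
  noisy <- corrupt(clean, noise, seed = noise_seed)

  idx <- round(positions$centers)
  idx[, 1] <- pmin(pmax(idx[, 1], 1), shape[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1), shape[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1), shape[3])
  gt <- matrix(0, n_cells, T_len)
  for (t in seq_len(T_len))
    gt[, t] <- clean[cbind(t, idx)]
  list(clean = video_stack(clean), noisy = video_stack(noisy),
       traces_gt = trace_matrix(gt, coords = positions$centers),
       nuclei = positions)
}

## ---------------------------------------------------------------------------
## Neurite phantom.

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

# Deposit unit mass per unit arc length along a polyline into an H x W image
# (nearest-pixel) and record the skeleton pixels.
rasterize_path <- function(img, skel, pts, step = 0.25) {
  if (nrow(pts) < 2) return(list(img = img, skel = skel))
  H <- nrow(img); W <- ncol(img)
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    nseg <- max(2L, ceiling(len / step))
    tt <- seq(0, 1, length.out = nseg)
    ys <- round(a[1] + tt * (b[1] - a[1]))
    xs <- round(a[2] + tt * (b[2] - a[2]))
    keep <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    ys <- ys[keep]; xs <- xs[keep]
    if (length(ys) == 0) next
    w <- len / nseg
    for (k in seq_along(ys)) {
      img[ys[k], xs[k]] <- img[ys[k], xs[k]] + w
      skel[ys[k], xs[k]] <- TRUE
    }
  }
  list(img = img, skel = skel)
}

#' Generate a neurite phantom
#'
#' Draws piecewise-smooth branched curves (a trunk crossing the field plus
#' side branches), dilates them to roughly 2-pixel-wide tubes with a Gaussian
#' cross-section of standard deviation \code{tube_sigma}, rescales to
#' \code{photon_level} and corrupts with the standard noise model. The true
#' centreline mask is returned alongside. This is a test fixture for the
#' neurite segmentation pipeline; no generator of this kind exists for real
#' neurite morphologies.
#'
#' @param shape 2D image shape (y, x).
#' @param n_branches number of side branches off the trunk (0 for a blank
#'   image when \code{paths} is not given and \code{trunk = FALSE}).
#' @param photon_level peak photon count.
#' @param seed RNG seed.
#' @param tube_sigma Gaussian cross-section standard deviation in pixels.
#' @param trunk draw the main trunk curve.
#' @param paths optional list of polylines (matrices of (y, x) vertices)
#'   overriding the random topology.
#' @param noise a \code{\link{noise_spec}}.
#' @return list with \code{clean}, \code{noisy} (2D matrices) and
#'   \code{skeleton} (logical matrix).
#' @export
make_neurite_phantom <- function(shape = c(128L, 128L), n_branches = 4L,
                                 photon_level = 200, seed = 0L,
                                 tube_sigma = 1.0, trunk = TRUE,
                                 paths = NULL, noise = noise_spec()) {
  stopifnot(length(shape) == 2L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- shape[1]; W <- shape[2]
  img <- matrix(0, H, W)
  skel <- matrix(FALSE, H, W)
  if (is.null(paths)) {
    paths <- list()
    if (trunk) {
      xs <- seq(4, W - 3, length.out = 40)
      span <- H * 0.25
      y0 <- stats::runif(1, H * 0.35, H * 0.65)
      cf <- stats::rnorm(3) * c(span, span / 2, span / 3)
      s <- seq(-1, 1, length.out = length(xs))
      ys <- y0 + cf[1] * s / 2 + cf[2] * (s^2 - 1 / 3) + cf[3] * (s^3 - s)
      ys <- pmin(pmax(ys, 3), H - 2)
      trunk_pts <- cbind(ys, xs)
      paths[[length(paths) + 1]] <- trunk_pts
      for (b in seq_len(n_branches)) {
        j <- sample(5:(length(xs) - 5), 1)
        ang <- stats::runif(1, pi / 6, 5 * pi / 6) * sample(c(-1, 1), 1)
        blen <- stats::runif(1, H / 6, H / 3)
        tt <- seq(0, 1, length.out = 15)
        curv <- stats::rnorm(1, 0, 0.6)
        a2 <- ang + curv * tt
        by <- trunk_pts[j, 1] + cumsum(c(0, diff(tt * blen)) * sin(a2))
        bx <- trunk_pts[j, 2] + cumsum(c(0, diff(tt * blen)) * cos(a2))
        keep <- by >= 2 & by <= H - 1 & bx >= 2 & bx <= W - 1
        if (sum(keep) >= 2)
          paths[[length(paths) + 1]] <- cbind(by[keep], bx[keep])
      }
    }
  }
  for (p in paths) {
    r <- rasterize_path(img, skel, as.matrix(p))
    img <- r$img; skel <- r$skel
  }
  if (any(img > 0)) {
    img <- img_sepconv2d(img, gauss_kernel1d(tube_sigma))
    img <- rescale_photon(img, photon_level)
  }
  noisy <- corrupt(array(img, c(1, H, W)), noise, seed = seed + 1L)
  list(clean = img, noisy = matrix(noisy[1, , ], H, W), skeleton = skel)
}
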