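## ---------------------------------------------------------------------------
## Nuclei segmentation, tracking, trace extraction and trace statistics.

#' Cell tracks
#'
#' Per-cell, per-time centre coordinates plus validity flags.
#'
#' @param coords n x T x 3 array of (z, y, x), or an n x 3 matrix of static
#'   positions (replicated across \code{T_len} frames).
#' @param valid n x T logical matrix (default all valid).
#' @param T_len number of frames when \code{coords} is static.
#' @param source provenance label.
#' @return an object of class \code{"niddl_tracks"}.
#' @export
cell_tracks <- function(coords, valid = NULL, T_len = NULL,
                        source = c("synthetic_ground_truth",
                                   "gmm_segmentation", "external_csv")) {
  source <- match.arg(source)
  if (is.matrix(coords)) {
    stopifnot(!is.null(T_len))
    coords <- aperm(array(rep(t(coords), T_len),
                          c(3, nrow(coords), T_len)), c(2, 3, 1))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (is.null(valid)) valid <- matrix(TRUE, dim(coords)[1], dim(coords)[2])
  structure(list(coords = coords, valid = valid, source = source),
            class = "niddl_tracks")
}

#' @export
print.niddl_tracks <- function(x, ...) {
  cat("niddl tracks: ", dim(x$coords)[1], " cells x ", dim(x$coords)[2],
      " frames (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Write/read tracks as CSV (\code{cell_id,t,z,y,x,valid})
#' @param tracks a \code{"niddl_tracks"}.
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  n <- dim(tracks$coords)[1]; T_len <- dim(tracks$coords)[2]
  df <- data.frame(cell_id = rep(seq_len(n), times = T_len),
                   t = rep(seq_len(T_len), each = n),
                   z = as.vector(tracks$coords[, , 1]),
                   y = as.vector(tracks$coords[, , 2]),
                   x = as.vector(tracks$coords[, , 3]),
                   valid = as.vector(tracks$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  ids <- sort(unique(df$cell_id)); ts <- sort(unique(df$t))
  coords <- array(NA_real_, c(length(ids), length(ts), 3))
  valid <- matrix(FALSE, length(ids), length(ts))
  i <- match(df$cell_id, ids); t <- match(df$t, ts)
  coords[cbind(i, t, 1)] <- df$z
  coords[cbind(i, t, 2)] <- df$y
  coords[cbind(i, t, 3)] <- df$x
  valid[cbind(i, t)] <- as.logical(df$valid)
  cell_tracks(coords, valid, source = "external_csv")
}

## ---------------------------------------------------------------------------
## Gaussian-mixture nuclei segmentation.

# 3D local maxima (26-neighbourhood) above a threshold, after light
# per-plane Gaussian smoothing.
find_local_maxima <- function(img, threshold, smooth_sigma = 1) {
  sm <- apply_per_plane(unclass(img), function(m)
    img_sepconv2d(m, gauss_kernel1d(smooth_sigma)))
  d <- dim(sm)
  is_max <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    shifted <- array(-Inf, d)
    zi <- seq_len(d[1]); yi <- seq_len(d[2]); xi <- seq_len(d[3])
    zs <- zi + dz; ys <- yi + dy; xs <- xi + dx
    okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okx <- xs >= 1 & xs <= d[3]
    shifted[zi[okz], yi[oky], xi[okx]] <- sm[zs[okz], ys[oky], xs[okx]]
    is_max <- is_max & (sm >= shifted)
  }
  which(is_max & sm > threshold, arr.ind = TRUE)
}

# Weighted EM for a Gaussian mixture over foreground voxel coordinates,
# weights proportional to voxel intensity.
gmm_em <- function(coords, weights, mu0, max_iter = 50L, tol = 1e-4,
                   reg = 0.1) {
  n <- nrow(coords); k <- nrow(mu0)
  mu <- mu0
  sigma <- replicate(k, diag(4, 3), simplify = FALSE)
  pi_k <- rep(1 / k, k)
  wsum <- sum(weights)
  loglik_old <- -Inf
  logdens <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      ch <- chol(sigma[[j]])
      d <- forwardsolve(t(ch), t(coords) - mu[j, ])
      logdens[, j] <- log(pi_k[j]) - sum(log(diag(ch))) -
        0.5 * colSums(d^2) - 1.5 * log(2 * pi)
    }
    m <- apply(logdens, 1, max)
    pr <- exp(logdens - m)
    rs <- rowSums(pr)
    loglik <- sum(weights * (log(rs) + m))
    gam <- pr / rs * weights
    nk <- colSums(gam)
    pi_k <- nk / wsum
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) next
      mu[j, ] <- colSums(coords * gam[, j]) / nk[j]
      d <- sweep(coords, 2, mu[j, ])
      sigma[[j]] <- crossprod(d * gam[, j], d) / nk[j] + diag(reg, 3)
    }
    if (abs(loglik - loglik_old) < tol * abs(loglik)) break
    loglik_old <- loglik
  }
  labels <- max.col(logdens)
  list(mu = mu, sigma = sigma, pi = pi_k, loglik = loglik, labels = labels,
       k = k)
}

#' Segment nuclei with a Gaussian mixture over voxel coordinates
#'
#' Foreground voxels (above an Otsu threshold by default) are clustered by a
#' weighted Gaussian mixture over their (z, y, x) coordinates, each voxel
#' weighted by its intensity. The component count is initialized from the
#' number of intensity peaks (3D local maxima after light smoothing) and
#' refined by the best BIC over counts within +/-20% of that estimate.
#'
#' @param stack a \code{"niddl_stack"} or 3D array.
#' @param threshold foreground intensity threshold; default Otsu.
#' @param k component count override (skips the BIC refinement).
#' @param seed seed for the k-means initialization of component means.
#' @return list with \code{centers} (k x 3 matrix (z, y, x)), \code{labels}
#'   (integer array, 0 = background), \code{k}, \code{bic}.
#' @export
segment_nuclei_gmm <- function(stack, threshold = NULL, k = NULL, seed = 0L) {
  img <- unclass(stack)
  if (max(img) == min(img))
    stop("cannot segment a blank stack", call. = FALSE)
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  fg <- which(img > threshold, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("no foreground voxels above threshold",
                          call. = FALSE)
  w <- img[fg]
  coords <- fg[, c(1, 2, 3), drop = FALSE]
  storage.mode(coords) <- "double"

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  peaks <- find_local_maxima(img, threshold)
  k0 <- max(1L, nrow(peaks))
  ks <- if (!is.null(k)) k
        else sort(unique(pmax(1L, round(k0 * c(0.8, 0.9, 1, 1.1, 1.2)))))
  best <- NULL
  for (kk in ks) {
    mu0 <- if (kk == nrow(peaks)) {
      pk <- peaks[, c(1, 2, 3), drop = FALSE]
      storage.mode(pk) <- "double"
      pk
    } else {
      km <- suppressWarnings(stats::kmeans(coords, centers = min(kk, nrow(coords)),
                                           nstart = 1, iter.max = 30))
      km$centers
    }
    fit <- gmm_em(coords, w, mu0)
    n_par <- fit$k * (3 + 6) + (fit$k - 1)
    bic <- -2 * fit$loglik + n_par * log(nrow(coords))
    if (is.null(best) || bic < best$bic) best <- c(fit, list(bic = bic))
  }
  labels <- array(0L, dim(img))
  labels[fg] <- best$labels
  list(centers = best$mu, labels = labels, k = best$k, bic = best$bic)
}

#' Greedy nearest-neighbour tracking of per-frame centres
#'
#' Links the cells of frame 1 forward through time: at each step every track
#' is matched to the closest unclaimed detection within \code{gate} voxels
#' (globally greedy, closest link first). Tracks without a match keep their
#' last position and are flagged invalid for that frame.
#'
#' @param centers_list list (length T) of n_t x 3 matrices of (z, y, x).
#' @param gate maximum displacement per frame, in voxels.
#' @return a \code{"niddl_tracks"} for the frame-1 cells.
#' @export
track_nearest <- function(centers_list, gate = 5) {
  stopifnot(length(centers_list) >= 1L)
  c1 <- as.matrix(centers_list[[1]])
  n <- nrow(c1); T_len <- length(centers_list)
  coords <- array(NA_real_, c(n, T_len, 3))
  valid <- matrix(FALSE, n, T_len)
  coords[, 1, ] <- c1
  valid[, 1] <- TRUE
  prev <- c1
  for (t in seq_len(T_len)[-1]) {
    det <- as.matrix(centers_list[[t]])
    assigned <- rep(NA_integer_, n)
    if (nrow(det) > 0) {
      dm <- outer(rowSums(prev^2), rep(1, nrow(det))) +
        outer(rep(1, n), rowSums(det^2)) - 2 * prev %*% t(det)
      dm[dm < 0] <- 0
      dm <- sqrt(dm)
      free_tr <- rep(TRUE, n); free_de <- rep(TRUE, nrow(det))
      repeat {
        dmin <- min(dm[free_tr, free_de, drop = FALSE])
        if (!is.finite(dmin) || dmin > gate || !any(free_tr) || !any(free_de))
          break
        w <- which(dm == dmin & outer(free_tr, free_de), arr.ind = TRUE)[1, ]
        assigned[w[1]] <- w[2]
        free_tr[w[1]] <- FALSE; free_de[w[2]] <- FALSE
        if (!any(free_tr) || !any(free_de)) break
      }
    }
    for (i in seq_len(n)) {
      if (!is.na(assigned[i])) {
        coords[i, t, ] <- det[assigned[i], ]
        valid[i, t] <- TRUE
        prev[i, ] <- det[assigned[i], ]
      } else {
        coords[i, t, ] <- prev[i, ]  # carry forward, flagged invalid
        valid[i, t] <- FALSE
      }
    }
  }
  cell_tracks(coords, valid, source = "gmm_segmentation")
}

## ---------------------------------------------------------------------------
## Trace extraction.

#' Extract single-pixel activity traces
#'
#' The trace value of cell i at frame t is the video intensity at the
#' rounded track centre. Out-of-bounds centres yield \code{NA} (logged).
#'
#' @param video a \code{"niddl_video"} (t, z, y, x).
#' @param tracks a \code{"niddl_tracks"} (static matrices accepted via
#'   \code{\link{cell_tracks}}).
#' @return a \code{"niddl_traces"}.
#' @export
extract_single_pixel <- function(video, tracks) {
  extract_roi(video, tracks, roi = c(1, 1, 1))
}

#' Extract ROI-averaged activity traces
#'
#' Means over an odd-sided (z, y, x) box centred at the track coordinate,
#' clipped at the image borders. \code{roi = c(1, 1, 1)} is single-pixel
#' extraction; typical choices are 3 x 5 x 5 (z, y, x) boxes for
#' whole-brain stacks and 1 x 3 x 3 for 2D projections.
#'
#' @inheritParams extract_single_pixel
#' @param roi odd integers (z, y, x).
#' @return a \code{"niddl_traces"}.
#' @export
extract_roi <- function(video, tracks, roi = c(3, 5, 5)) {
  stopifnot(length(dim(video)) == 4L, all(roi %% 2 == 1))
  d <- dim(video)
  n <- dim(tracks$coords)[1]; T_len <- dim(tracks$coords)[2]
  if (T_len != d[1])
    stop("tracks cover ", T_len, " frames but video has ", d[1],
         call. = FALSE)
  r <- (roi - 1) / 2
  v <- matrix(NA_real_, n, T_len)
  n_oob <- 0L
  for (t in seq_len(T_len)) {
    for (i in seq_len(n)) {
      if (!tracks$valid[i, t]) next
      ct <- round(tracks$coords[i, t, ])
      if (any(ct < 1) || any(ct > d[2:4])) { n_oob <- n_oob + 1L; next }
      zi <- max(1, ct[1] - r[1]):min(d[2], ct[1] + r[1])
      yi <- max(1, ct[2] - r[2]):min(d[3], ct[2] + r[2])
      xi <- max(1, ct[3] - r[3]):min(d[4], ct[3] + r[3])
      v[i, t] <- mean(video[t, zi, yi, xi])
    }
  }
  if (n_oob > 0)
    niddl_log("warn", "extract_roi: ", n_oob,
              " out-of-bounds centres flagged missing")
  trace_matrix_allow_na(v)
}

trace_matrix_allow_na <- function(values, cell_ids = NULL, coords = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(values))
  structure(list(values = values, cell_ids = cell_ids, coords = coords),
            class = "niddl_traces")
}

## ---------------------------------------------------------------------------
## Trace accuracy (MAE / Pearson) and population statistics.

align_traces <- function(test, gt) {
  if (!identical(dim(test$values), dim(gt$values)))
    stop("trace matrices are not aligned: ",
         paste(dim(test$values), collapse = "x"), " vs ",
         paste(dim(gt$values), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Per-cell mean absolute error between trace matrices
#'
#' \eqn{\mathrm{MAE}_i = \frac{1}{T}\sum_{t=1}^{T} |y_{test,i,t} -
#' y_{gt,i,t}|}: the trace-level accuracy statistic comparing traces
#' extracted from a noisy or denoised video against the ground-truth video.
#'
#' @param test,gt \code{"niddl_traces"} with matching cells and T.
#' @return numeric vector of per-cell MAE (NA where either trace has
#'   missing samples).
#' @export
trace_mae <- function(test, gt) {
  align_traces(test, gt)
  rowMeans(abs(test$values - gt$values))
}

#' Per-cell Pearson correlation between trace matrices
#'
#' Cells whose ground-truth or test trace has zero variance have an
#' undefined correlation and are reported as \code{NA}.
#'
#' @inheritParams trace_mae
#' @return numeric vector of per-cell correlations in [-1, 1] (or NA).
#' @export
trace_pearson <- function(test, gt) {
  align_traces(test, gt)
  n <- nrow(test$values)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- test$values[i, ]; b <- gt$values[i, ]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
    out[i] <- stats::cor(a[ok], b[ok])
  }
  out
}

#' Pairwise Pearson correlation among cells
#'
#' @param traces a \code{"niddl_traces"} with T >= 3.
#' @return symmetric n x n matrix with unit diagonal (NA rows for
#'   zero-variance traces).
#' @export
pairwise_corr <- function(traces) {
  v <- traces$values
  if (ncol(v) < 3) stop("need T >= 3", call. = FALSE)
  cm <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  diag(cm) <- 1
  cm
}

#' PCA trajectory of population activity
#'
#' Standardizes each cell's trace (zero mean, unit variance; zero-variance
#' traces stay zero) and runs PCA across cells, returning the k-dimensional
#' temporal trajectory and the fraction of variance explained.
#'
#' @param traces a \code{"niddl_traces"}.
#' @param k number of components.
#' @return list with \code{trajectory} (T x k), \code{explained}
#'   (length-k fractions), \code{rotation}.
#' @export
pca_traces <- function(traces, k = 3L) {
  v <- traces$values
  if (ncol(v) < 3) stop("need T >= 3", call. = FALSE)
  vs <- t(apply(v, 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  p <- stats::prcomp(t(vs), center = FALSE, scale. = FALSE)
  k <- min(k, ncol(p$x))
  ev <- p$sdev^2
  list(trajectory = p$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)] / sum(ev),
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}
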