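# Shared fixtures, generated in code at test time.

# Small clean/noisy scene pair: one 64x64 plane of Gaussian nuclei.
make_pair_64 <- function(i, photon = 200, n_cells = 8L, seed0 = 1000L) {
  s <- make_nuclei_scene(c(1L, 64L, 64L), n_cells = n_cells,
                         photon_level = photon, seed = seed0 + i)
  list(clean = unclass(s$clean),
       noisy = unclass(corrupt(s$clean, seed = seed0 + 500000L + i)))
}

# A compact architecture for fast training tests (same code paths as the
# full-size networks, two pooling levels, narrow features).
tiny_arch <- function(family = "unet_fixed", channels = 8L)
  arch_spec(family, levels = 2L, channels = channels, blocks = c(1L, 1L, 1L))

# Identity network: one 1x1 convolution with weight 1, bias 0.
identity_model <- function() {
  m <- niddl:::single_conv_model(1L, 1L, kernel = 1L, seed = 0L)
  m$params[["n2.w"]][] <- 1
  m$params[["n2.b"]][] <- 0
  m$spec <- structure(list(family = "single_conv", kernel = 1L, mode = "2d",
                           context_d = 0L, channels = 1L, levels = 0L,
                           blocks = 0L, fixed_channels = TRUE),
                      class = "niddl_arch")
  m
}

# Greedy one-to-one matching of detected centres to true centres; returns
# the number matched within `tol` voxels.
match_centers <- function(detected, truth, tol = 2) {
  if (nrow(detected) == 0) return(0L)
  d2 <- outer(rowSums(detected^2), rep(1, nrow(truth))) +
    outer(rep(1, nrow(detected)), rowSums(truth^2)) -
    2 * detected %*% t(truth)
  d <- sqrt(pmax(d2, 0))
  matched <- 0L
  repeat {
    m <- min(d)
    if (!is.finite(m) || m > tol) break
    w <- which(d == m, arr.ind = TRUE)[1, ]
    matched <- matched + 1L
    d[w[1], ] <- Inf
    d[, w[2]] <- Inf
  }
  matched
}
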