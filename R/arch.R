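#' Declare a denoising network architecture
#'
#' Describes one of the four encoder--decoder families used for supervised
#' denoising of fluorescence image planes and stacks. All families share a
#' U-shaped layout with \code{levels} rounds of 2x2 max-pooling and 2x
#' upsampling; they differ in how channel depth evolves and how skip paths
#' are merged:
#'
#' \describe{
#'   \item{\code{unet}}{channel depth doubles after every pooling step and
#'     halves after every upsampling step; skip paths concatenate encoder
#'     features into the decoder (classic U-Net).}
#'   \item{\code{unet_fixed}}{same layout as \code{unet} but every feature
#'     map holds \code{channels} channels. The constant width makes the
#'     network far smaller, which in turn allows many more convolutional
#'     blocks per scale (see \code{blocks}).}
#'   \item{\code{hourglass_wores}}{doubling channels; skip paths pass through
#'     a trainable side convolution and are summed (not concatenated) into
#'     the decoder.}
#'   \item{\code{hourglass_wres}}{hourglass with all feature maps fixed at
#'     \code{channels} channels, which permits identity (short-range)
#'     residual connections inside every convolutional block.}
#' }
#'
#' A convolutional block is two \code{kernel} x \code{kernel} convolutions,
#' each followed by ReLU; in \code{hourglass_wres} the block input is added
#' to the result before the final ReLU. \code{blocks} gives the number of
#' blocks at each encoder scale (mirrored in the decoder) plus the bottleneck
#' count. The fixed-channel defaults place most blocks at coarse scales,
#' where convolutions are cheap and the receptive field grows fastest:
#' 2/4/8/10 blocks at scales 0--3. With the default composition the two
#' fixed-channel networks occupy 3.77 MB (\code{unet_fixed}) and 3.66 MB
#' (\code{hourglass_wres}) at 4 bytes per parameter; see
#' \code{\link{model_size_mb}}.
#'
#' @param family architecture family; one of \code{"unet_fixed"},
#'   \code{"hourglass_wres"}, \code{"unet"}, \code{"hourglass_wores"}.
#' @param kernel convolution kernel side, 3 or 5.
#' @param mode denoising mode: \code{"2d"} (plane to plane), \code{"2p5d"}
#'   (a plane plus \code{context_d} neighbours above and below as input
#'   channels, centre plane out) or \code{"3d"} (a chunk of
#'   \code{context_d} planes in and out, 3D convolutions).
#' @param context_d z-context: neighbour planes per side for \code{"2p5d"},
#'   chunk depth for \code{"3d"}; ignored for \code{"2d"}.
#' @param channels width of the first (and, for fixed families, every)
#'   feature map.
#' @param levels number of pooling/upsampling rounds.
#' @param blocks optional integer vector of length \code{levels + 1}:
#'   convolutional blocks per encoder scale, then the bottleneck count.
#'   Defaults to the calibrated composition for \code{levels = 4}
#'   fixed-channel families and to one block per scale otherwise.
#' @return an object of class \code{"niddl_arch"}.
#' @examples
#' spec <- arch_spec("unet_fixed")
#' model <- build_model(spec, seed = 1)
#' model_size_mb(model)
#' @export
arch_spec <- function(family = c("unet_fixed", "hourglass_wres",
                                 "unet", "hourglass_wores"),
                      kernel = 3L,
                      mode = c("2d", "2p5d", "3d"),
                      context_d = 1L,
                      channels = 32L,
                      levels = 4L,
                      blocks = NULL) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (!kernel %in% c(3L, 5L)) stop("kernel must be 3 or 5", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 0L) stop("levels must be >= 0", call. = FALSE)
  context_d <- as.integer(context_d)
  if (mode != "2d" && context_d < 1L)
    stop("context_d must be >= 1 for 2p5d/3d modes", call. = FALSE)
  fixed <- family %in% c("unet_fixed", "hourglass_wres")
  if (is.null(blocks)) {
    if (fixed && levels == 4L) {
      enc <- c(2L, 4L, 8L, 10L)
      mid <- if (family == "unet_fixed") 3L else 1L
    } else {
      enc <- rep(1L, levels)
      mid <- 1L
    }
    blocks <- c(enc, mid)
  }
  blocks <- as.integer(blocks)
  if (length(blocks) != levels + 1L)
    stop("blocks must have length levels + 1", call. = FALSE)
  structure(
    list(family = family, kernel = as.integer(kernel), mode = mode,
         context_d = context_d, channels = as.integer(channels),
         levels = levels, blocks = blocks,
         fixed_channels = fixed),
    class = "niddl_arch")
}

#' @export
print.niddl_arch <- function(x, ...) {
  cat("niddl architecture spec\n")
  cat("  family:   ", x$family,
      if (x$fixed_channels) " (fixed channel depth)" else " (doubling)",
      "\n", sep = "")
  cat("  mode:     ", x$mode,
      if (x$mode != "2d") paste0(" (context_d = ", x$context_d, ")") else "",
      "\n", sep = "")
  cat("  kernel:   ", x$kernel, "x", x$kernel, "\n", sep = "")
  cat("  channels: ", x$channels, ", levels: ", x$levels, "\n", sep = "")
  cat("  blocks:   ", paste(utils::head(x$blocks, -1), collapse = "/"),
      " + bottleneck ", utils::tail(x$blocks, 1), "\n", sep = "")
  invisible(x)
}

arch_in_channels <- function(spec) {
  switch(spec$mode,
         "2d" = 1L,
         "2p5d" = 2L * spec$context_d + 1L,
         "3d" = 1L)
}

arch_out_channels <- function(spec) 1L

arch_kdim <- function(spec, k = spec$kernel) {
  if (spec$mode == "3d") c(3L, k, k) else c(1L, k, k)
}

arch_level_channels <- function(spec, level) {
  if (spec$fixed_channels) spec$channels
  else as.integer(spec$channels * 2^level)
}

## ---------------------------------------------------------------------------
## Graph construction. A model graph is a list of nodes; node i may consume
## the outputs of earlier nodes only. Node types:
##   input                 - placeholder
##   conv  (w, b, kdim)    - same-padding stride-1 convolution
##   convT2 (w, b)         - 2x2 stride-2 transposed convolution (upsampling)
##   relu, pool, up2       - elementwise / in-plane resampling
##   concat (two inputs)   - channel concatenation
##   add    (two inputs)   - elementwise sum

new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

g_add <- function(g, node) {
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

g_conv <- function(g, input, cin, cout, kdim) {
  g_add(g, list(op = "conv", inputs = input, cin = cin, cout = cout,
                kdim = kdim))
}

g_block <- function(g, input, ch, kdim, residual) {
  a <- g_conv(g, input, ch, ch, kdim)
  a <- g_add(g, list(op = "relu", inputs = a))
  b <- g_conv(g, a, ch, ch, kdim)
  if (residual) b <- g_add(g, list(op = "add", inputs = c(b, input)))
  g_add(g, list(op = "relu", inputs = b))
}

build_graph <- function(spec) {
  g <- new_graph()
  kdim <- arch_kdim(spec)
  hourglass <- spec$family %in% c("hourglass_wores", "hourglass_wres")
  residual <- spec$family == "hourglass_wres"
  L <- spec$levels
  ch <- vapply(0:L, function(l) arch_level_channels(spec, l), integer(1))

  x <- g_add(g, list(op = "input"))
  x <- g_conv(g, x, arch_in_channels(spec), ch[1], kdim)   # stem
  x <- g_add(g, list(op = "relu", inputs = x))

  skips <- integer(L)
  if (L > 0) {
    for (l in seq_len(L)) {                                 # scales 0..L-1
      for (b in seq_len(spec$blocks[l])) x <- g_block(g, x, ch[l], kdim, residual)
      skips[l] <- x
      x <- g_add(g, list(op = "pool", inputs = x))
      if (ch[l + 1] != ch[l]) {                             # doubling families
        x <- g_conv(g, x, ch[l], ch[l + 1], kdim)
        x <- g_add(g, list(op = "relu", inputs = x))
      }
    }
  }
  for (b in seq_len(spec$blocks[L + 1L])) x <- g_block(g, x, ch[L + 1], kdim, residual)

  if (L > 0) {
    for (l in rev(seq_len(L))) {
      if (hourglass) {
        x <- g_add(g, list(op = "convT2", inputs = x,
                           cin = ch[l + 1], cout = ch[l]))
        side <- g_conv(g, skips[l], ch[l], ch[l], kdim)
        x <- g_add(g, list(op = "add", inputs = c(x, side)))
        x <- g_add(g, list(op = "relu", inputs = x))
      } else {
        x <- g_add(g, list(op = "up2", inputs = x))
        x <- g_conv(g, x, ch[l + 1], ch[l], kdim)
        x <- g_add(g, list(op = "relu", inputs = x))
        x <- g_add(g, list(op = "concat", inputs = c(skips[l], x)))
        fuse_k <- if (spec$fixed_channels) c(1L, 1L, 1L) else kdim
        x <- g_conv(g, x, 2L * ch[l], ch[l], fuse_k)
        x <- g_add(g, list(op = "relu", inputs = x))
      }
      for (b in seq_len(spec$blocks[l])) x <- g_block(g, x, ch[l], kdim, residual)
    }
  }
  g_conv(g, x, ch[1], arch_out_channels(spec), kdim)        # linear head
  g$nodes
}

#' Build a network from an architecture spec
#'
#' Instantiates the computation graph and initialises all weights with a
#' uniform fan-in scheme (bounds \eqn{\pm\sqrt{6/\mathrm{fan_in}}}); biases
#' start at zero, so a freshly built model maps an all-zero input to an
#' all-zero output. Initialisation is fully determined by \code{seed}.
#'
#' @param spec an \code{\link{arch_spec}}.
#' @param seed integer seed for weight initialisation.
#' @return an object of class \code{"niddl_model"}: the spec, the node list,
#'   and a named list of parameter tensors.
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "niddl_arch"))
  nodes <- build_graph(spec)
  params <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$op == "conv") {
      kk <- prod(nd$kdim)
      fan_in <- nd$cin * kk
      lim <- sqrt(6 / fan_in)
      w <- matrix(stats::runif(nd$cout * nd$cin * kk, -lim, lim),
                  nrow = nd$cout)
      params[[paste0("n", i, ".w")]] <- w
      params[[paste0("n", i, ".b")]] <- numeric(nd$cout)
    } else if (nd$op == "convT2") {
      fan_in <- nd$cin  # each output pixel sees one input pixel per channel
      lim <- sqrt(6 / fan_in)
      w <- matrix(stats::runif(nd$cout * nd$cin * 4L, -lim, lim),
                  nrow = nd$cout)
      params[[paste0("n", i, ".w")]] <- w
      params[[paste0("n", i, ".b")]] <- numeric(nd$cout)
    }
  }
  structure(list(spec = spec, nodes = nodes, params = params,
                 trained = FALSE, provenance = list(init_seed = seed)),
            class = "niddl_model")
}

# Save/restore the global RNG stream so that model construction with an
# explicit seed does not disturb a caller's random sequence.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Minimal one-convolution model; exercises the same parameter bookkeeping as
# full networks (cout*cin*k^2 + cout parameters) on a graph small enough to
# check by hand.
single_conv_model <- function(cin = 1L, cout = 1L, kernel = 3L, seed = 0L) {
  g <- new_graph()
  x <- g_add(g, list(op = "input"))
  g_conv(g, x, as.integer(cin), as.integer(cout),
         c(1L, as.integer(kernel), as.integer(kernel)))
  nodes <- g$nodes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  kk <- kernel * kernel
  lim <- sqrt(6 / (cin * kk))
  params <- list(matrix(stats::runif(cout * cin * kk, -lim, lim), nrow = cout),
                 numeric(cout))
  names(params) <- c("n2.w", "n2.b")
  structure(list(spec = NULL, nodes = nodes, params = params,
                 trained = FALSE, provenance = list(init_seed = seed)),
            class = "niddl_model")
}

#' Count trainable parameters / model size
#'
#' \code{count_parameters} sums the lengths of all weight and bias tensors;
#' \code{model_size_mb} converts the count to megabytes at 4 bytes per
#' parameter (single-precision storage), rounded to 2 decimals. At the
#' default specs, \code{unet_fixed} occupies 3.77 MB and
#' \code{hourglass_wres} 3.66 MB.
#'
#' @param model a \code{"niddl_model"}.
#' @return integer count / numeric megabytes.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "niddl_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' @rdname count_parameters
#' @export
model_size_mb <- function(model) {
  round(4 * count_parameters(model) / 2^20, 2)
}

#' @export
print.niddl_model <- function(x, ...) {
  cat("niddl model (", x$spec$family, ", ", x$spec$mode, ")\n", sep = "")
  cat("  parameters: ", format(count_parameters(x), big.mark = ","),
      " (", sprintf("%.2f", model_size_mb(x)), " MB)\n", sep = "")
  cat("  trained:    ", x$trained, "\n", sep = "")
  invisible(x)
}
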