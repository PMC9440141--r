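#' @useDynLib niddl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Containers.
##
## An image stack is a plain 3D numeric array indexed (z, y, x), 0 z-planes
## never allowed, with a "pixel_size_um" attribute (dz, dy, dx). A video is a
## 4D array indexed (t, z, y, x). On disk both live as unsigned 16-bit
## multi-page TIFF (one page per z-plane); internally values are doubles.

#' Construct an image stack
#'
#' @param data numeric 3D array (z, y, x), or a matrix (promoted to z = 1).
#' @param pixel_size_um voxel size in micrometres, (dz, dy, dx).
#' @return the array with class \code{"niddl_stack"}.
#' @export
image_stack <- function(data, pixel_size_um = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("image data must be finite", call. = FALSE)
  attr(data, "pixel_size_um") <- as.numeric(pixel_size_um)
  class(data) <- c("niddl_stack", class(data))
  data
}

#' Construct a video stack
#'
#' @param frames numeric 4D array (t, z, y, x).
#' @param dt_s frame interval in seconds, or \code{NA} if unknown.
#' @return the array with class \code{"niddl_video"}.
#' @export
video_stack <- function(frames, dt_s = NA_real_) {
  stopifnot(is.array(frames), length(dim(frames)) == 4L)
  attr(frames, "dt_s") <- dt_s
  class(frames) <- c("niddl_video", class(frames))
  frames
}

#' Extract one time point of a video as an image stack
#' @param video a \code{"niddl_video"}.
#' @param t 1-based frame index.
#' @export
video_frame <- function(video, t) {
  image_stack(array(video[t, , , , drop = TRUE], dim(video)[2:4]))
}

## ---------------------------------------------------------------------------
## TIFF stack I/O.

#' Read a 3D stack from a (multi-page) TIFF file
#'
#' Pages become z-planes in order; a single-page file yields a stack with
#' z = 1. Integer sample values are returned verbatim, so a
#' \code{\link{write_stack}}/\code{read_stack} round trip of 16-bit data is
#' bit-exact.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um voxel size metadata attached to the result.
#' @return a \code{"niddl_stack"} array (z, y, x).
#' @export
read_stack <- function(path, pixel_size_um = c(1, 1, 1)) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("not a readable TIFF (", conditionMessage(e),
                           "): ", path, call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), shp))
      stop("TIFF page ", i, " has inconsistent shape", call. = FALSE)
  data <- array(0, c(length(pages), shp))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  image_stack(data, pixel_size_um)
}

#' Write a 3D stack as a multi-page unsigned 16-bit TIFF
#'
#' Values are rounded to integers and clipped to [0, 65535]; any clipping is
#' reported through the package log (see \code{\link{niddl_log}}).
#'
#' @param stack a \code{"niddl_stack"} or 3D array (z, y, x).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  data <- unclass(stack)
  if (any(!is.finite(data))) stop("stack contains non-finite values",
                                  call. = FALSE)
  v <- round(data)
  if (any(v < 0)) {
    niddl_log("warn", "write_stack: negative intensities clipped to 0")
    v[v < 0] <- 0
  }
  if (any(v > 65535)) {
    niddl_log("warn", "write_stack: intensities above 65535 clipped")
    v[v > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(v)[1]),
                  function(z) matrix(v[z, , ] / 65535, dim(v)[2], dim(v)[3]))
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e) stop("cannot write TIFF to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a video from a directory of per-frame TIFFs or a single 4D TIFF
#'
#' A directory is read as one stack per time point, frames ordered by file
#' name (use zero-padded indices). A single file is interpreted as t-major
#' pages: page \code{(t-1)*nz + z}; \code{nz} must then be given.
#'
#' @param path directory of TIFF files, or one TIFF file.
#' @param nz z-planes per frame when \code{path} is a single file.
#' @param dt_s frame interval metadata.
#' @return a \code{"niddl_video"} array (t, z, y, x).
#' @export
read_video <- function(path, nz = NULL, dt_s = NA_real_) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0) stop("no TIFF files in ", path, call. = FALSE)
    first <- read_stack(files[1])
    frames <- array(0, c(length(files), dim(first)))
    frames[1, , , ] <- first
    for (i in seq_along(files)[-1]) {
      s <- read_stack(files[i])
      if (!identical(dim(s), dim(first)))
        stop("frame ", i, " (", basename(files[i]),
             ") has inconsistent shape", call. = FALSE)
      frames[i, , , ] <- s
    }
    return(video_stack(frames, dt_s))
  }
  if (is.null(nz)) stop("nz is required for single-file videos", call. = FALSE)
  s <- read_stack(path)
  np <- dim(s)[1]
  if (np %% nz != 0)
    stop("page count ", np, " is not a multiple of nz = ", nz, call. = FALSE)
  nt <- np %/% nz
  frames <- array(0, c(nt, nz, dim(s)[2], dim(s)[3]))
  for (t in seq_len(nt))
    frames[t, , , ] <- s[((t - 1) * nz + 1):(t * nz), , ]
  video_stack(frames, dt_s)
}

#' Write a video as one TIFF per time point
#'
#' Files are named \code{<prefix>0001.tif, ...} (zero-padded) inside
#' \code{dir}, which is created if needed.
#'
#' @param video a \code{"niddl_video"}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return \code{dir}, invisibly.
#' @export
write_video <- function(video, dir, prefix = "frame") {
  stopifnot(length(dim(video)) == 4L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nt <- dim(video)[1]
  width <- max(4L, nchar(as.character(nt)))
  for (t in seq_len(nt)) {
    f <- file.path(dir, sprintf("%s%0*d.tif", prefix, width, t))
    write_stack(video_frame(video, t), f)
  }
  invisible(dir)
}

## ---------------------------------------------------------------------------
## Traces, tracks, configuration, logging.

#' Construct a trace matrix
#'
#' Holds per-cell activity time series plus the coordinates the values were
#' (or are to be) sampled at.
#'
#' @param values numeric matrix, cells x timepoints; no missing values.
#' @param cell_ids identifiers, defaults to \code{1:n}.
#' @param coords per-cell (z, y, x) coordinates: an n x 3 matrix for static
#'   positions or an n x T x 3 array for moving cells. Optional.
#' @return an object of class \code{"niddl_traces"}.
#' @export
trace_matrix <- function(values, cell_ids = NULL, coords = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("traces need T >= 1", call. = FALSE)
  if (any(!is.finite(values))) stop("traces must not contain missing values",
                                    call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(values))
  structure(list(values = values, cell_ids = cell_ids, coords = coords),
            class = "niddl_traces")
}

#' @export
print.niddl_traces <- function(x, ...) {
  cat("niddl traces: ", nrow(x$values), " cells x ", ncol(x$values),
      " timepoints\n", sep = "")
  invisible(x)
}

#' Read/write traces as CSV (\code{cell_id,t,value})
#' @param traces a \code{"niddl_traces"}.
#' @param path CSV file path.
#' @return \code{write_traces}: \code{path} invisibly; \code{read_traces}:
#'   a \code{"niddl_traces"}.
#' @export
write_traces <- function(traces, path) {
  v <- traces$values
  df <- data.frame(
    cell_id = rep(traces$cell_ids, times = ncol(v)),
    t = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "t", "value") %in% names(df)))
  ids <- unique(df$cell_id)
  ts <- sort(unique(df$t))
  v <- matrix(NA_real_, length(ids), length(ts))
  v[cbind(match(df$cell_id, ids), match(df$t, ts))] <- df$value
  trace_matrix(v, ids)
}

#' Run configuration
#'
#' Bundles the seed, log level and named paths that drive the pipeline
#' functions; identical (seed, config, inputs) reproduce identical outputs
#' for every stochastic operation in the package.
#'
#' @param seed non-negative integer.
#' @param log_level one of \code{"debug"}, \code{"info"}, \code{"warn"},
#'   \code{"error"}.
#' @param paths named list of input/output locations.
#' @return an object of class \code{"niddl_config"}.
#' @export
run_config <- function(seed = 0L, log_level = "info", paths = list()) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer",
                                     call. = FALSE)
  log_level <- match.arg(log_level, c("debug", "info", "warn", "error"))
  structure(list(seed = seed, log_level = log_level, paths = paths),
            class = "niddl_config")
}

#' Read/write a configuration file (YAML)
#' @param config a \code{"niddl_config"} (or plain named list).
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(seed = x$seed %||% 0L, log_level = x$log_level %||% "info",
             paths = x$paths %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Package logging
#'
#' Writes ISO-timestamped messages to the console (and to the file named by
#' \code{options(niddl.log_file=)}, if set). The threshold is controlled by
#' \code{options(niddl.log_level=)}; default \code{"info"}.
#'
#' @param level one of \code{"debug"}, \code{"info"}, \code{"warn"},
#'   \code{"error"}.
#' @param ... message parts, pasted together.
#' @export
niddl_log <- function(level = "info", ...) {
  threshold <- getOption("niddl.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible())
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " [",
                 toupper(level), "] ", paste0(..., collapse = ""))
  message(line)
  f <- getOption("niddl.log_file", NULL)
  if (!is.null(f)) cat(line, "\n", file = f, append = TRUE)
  invisible(line)
}
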