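#' Construct a frame stack
#'
#' A `frame_stack` is the raw input of the ULM pipeline: a time-ordered set of
#' 2D envelope/B-mode-like intensity grids with acquisition metadata. It is
#' stored as a 3D numeric array with dimensions `rows x cols x frames`.
#'
#' Coordinate convention used by every function in this package: positions are
#' 0-based and measured in pixels, `x` is the column index and `y` the row
#' index, origin at the top-left pixel center. Frame indices are 0-based.
#'
#' @param data 3D numeric array (rows, cols, frames) or a list of matrices.
#' @param frame_rate acquisition frame rate in Hz.
#' @param pixel_size pixel pitch in micrometers (metadata only).
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_rate, pixel_size = 1) {
  if (is.list(data)) data <- simplify2array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, is.numeric(frame_rate), frame_rate > 0)
  structure(data,
            frame_rate_hz = as.numeric(frame_rate),
            pixel_size_um = as.numeric(pixel_size),
            class = c("frame_stack", "array"))
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("frame_stack: %d x %d px, %d frames @ %.6g Hz (pixel %.6g um)\n",
              d[1], d[2], d[3], frame_rate(x), attr(x, "pixel_size_um")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `frame_stack`.
#' @export
n_frames <- function(stack) dim(stack)[3]

#' Frame rate of a stack (Hz)
#' @param stack a `frame_stack`.
#' @export
frame_rate <- function(stack) attr(stack, "frame_rate_hz")

#' Extract one frame as a matrix
#' @param stack a `frame_stack`.
#' @param frame 0-based frame index.
#' @export
get_frame <- function(stack, frame) {
  stopifnot(frame >= 0, frame < n_frames(stack))
  stack[, , frame + 1L]
}

#' Temporally subsample a frame stack
#'
#' Emulates acquisition at a reduced frame rate by keeping frames
#' 0, stride, 2*stride, ... and dividing the frame-rate metadata by the
#' stride (e.g. a 440 Hz stack at stride 3 becomes a 146.67 Hz stack).
#'
#' @param stack a `frame_stack`.
#' @param stride positive integer subsampling factor.
#' @return a `frame_stack` with `ceiling(n/stride)` frames.
#' @export
subsample_frame_rate <- function(stack, stride) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  nf <- n_frames(stack)
  if (stride >= nf)
    stop("stride (", stride, ") must be smaller than the number of frames (", nf, ")")
  keep <- seq(1L, nf, by = stride)
  frame_stack(stack[, , keep, drop = FALSE],
              frame_rate = frame_rate(stack) / stride,
              pixel_size = attr(stack, "pixel_size_um"))
}

#' Write a frame stack as multipage 32-bit float TIFF
#'
#' Values are affinely mapped to [0, 1] for storage; the mapping (`vmin`,
#' `vmax`) and the acquisition metadata are stored in a JSON sidecar file
#' `<path>.json` so that [read_stack_tiff()] restores the original
#' intensities to float32 precision.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- range(stack)
  scale <- if (v[2] > v[1]) v[2] - v[1] else 1
  frames <- lapply(seq_len(n_frames(stack)),
                   function(i) (stack[, , i] - v[1]) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(frame_rate_hz = frame_rate(stack),
               pixel_size_um = attr(stack, "pixel_size_um"),
               vmin = v[1], vmax = v[2])
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_stack_tiff()]
#' @param path TIFF path (its `<path>.json` sidecar must exist).
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(frames)
  scale <- if (meta$vmax > meta$vmin) meta$vmax - meta$vmin else 1
  frame_stack(arr * scale + meta$vmin,
              frame_rate = meta$frame_rate_hz,
              pixel_size = meta$pixel_size_um)
}
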