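#' Localization configuration
#'
#' @param gaussian_sigma standard deviation (px) of the Gaussian smoothing
#'   applied before peak detection to enhance SNR; sized to the PSF.
#' @param min_peak_intensity minimum smoothed intensity of a peak; set it at
#'   or above the SVD noise floor.
#' @param min_peak_separation peaks closer than this (px) are merged, keeping
#'   the brighter one.
#' @export
localization_config <- function(gaussian_sigma = 1.0, min_peak_intensity = 0,
                                min_peak_separation = 3) {
  stopifnot(gaussian_sigma >= 0, min_peak_intensity >= 0,
            min_peak_separation >= 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 min_peak_intensity = min_peak_intensity,
                 min_peak_separation = min_peak_separation),
            class = "localization_config")
}

# separable Gaussian convolution with replicate padding (shift-equivariant
# away from borders; no circular wrap-around)
.gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  w <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-w):w)^2 / (2 * sigma^2)); k <- k / sum(k)
  nr <- nrow(mat); nc <- ncol(mat)
  pad_r <- mat[c(rep(1L, w), seq_len(nr), rep(nr, w)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) out <- out + k[j] * pad_r[(j - 1L) + seq_len(nr), , drop = FALSE]
  pad_c <- out[, c(rep(1L, w), seq_len(nc), rep(nc, w)), drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (j in seq_along(k)) out2 <- out2 + k[j] * pad_c[, (j - 1L) + seq_len(nc), drop = FALSE]
  out2
}

#' Detect integer-pixel intensity peaks in one frame
#'
#' Strict local maxima (8-neighborhood) of the Gaussian-smoothed frame with
#' smoothed intensity >= `min_peak_intensity`; peaks closer than
#' `min_peak_separation` are merged greedily by descending intensity,
#' keeping the brighter one.
#'
#' @param frame nonnegative 2D intensity matrix (post-SVD magnitude).
#' @param config a [localization_config()].
#' @return data.frame with 0-based integer columns `x`, `y` and `intensity`
#'   (from the smoothed frame); zero rows when nothing is found.
#' @export
detect_peaks <- function(frame, config) {
  sm <- .gaussian_smooth(frame, config$gaussian_sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3 || nc < 3)
    return(data.frame(x = integer(), y = integer(), intensity = numeric()))
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr >= config$min_peak_intensity
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & ctr > sm[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = integer(), y = integer(), intensity = numeric()))
  pk <- data.frame(x = idx[, 2], y = idx[, 1],      # +1 border offset -1 for 0-based
                   intensity = ctr[idx])
  pk <- pk[order(-pk$intensity), , drop = FALSE]
  if (config$min_peak_separation > 0 && nrow(pk) > 1) {
    keep <- logical(nrow(pk))
    kx <- numeric(0); ky <- numeric(0)
    for (i in seq_len(nrow(pk))) {
      if (!length(kx) ||
          min((kx - pk$x[i])^2 + (ky - pk$y[i])^2) >= config$min_peak_separation^2) {
        keep[i] <- TRUE
        kx <- c(kx, pk$x[i]); ky <- c(ky, pk$y[i])
      }
    }
    pk <- pk[keep, , drop = FALSE]
  }
  rownames(pk) <- NULL
  pk
}

#' Cosine-fit subpixel offset from three samples around a peak
#'
#' Fits `I(u) = A cos(alpha (u - xi))` to the peak sample `I_0` and its two
#' neighbours and returns the peak offset `xi = -beta / alpha`, with
#' `alpha = arccos((I(-1) + I(1)) / (2 I(0)))`. For `beta` the exact inverse
#' is the arctangent form `beta = arctan((I(-1) - I(1)) / (2 I(0) sin
#' alpha))` (default); on a true cosine profile this recovers the offset to
#' machine precision and returns 0 for symmetric neighbours. The arccos form
#' of `beta` is available via `method = "acos"` for comparison.
#'
#' Degenerate geometry (arccos argument outside [-1, 1] beyond a 1e-12
#' tolerance, or `sin(alpha) == 0`) yields offset 0 with the `degenerate`
#' attribute set.
#'
#' @param I_m1,I_0,I_p1 intensities at u = -1, 0, +1; vectorized. Requires a
#'   strict peak with `I_0 > 0` (on post-filter magnitude images all three
#'   are nonnegative).
#' @param method `"atan"` (exact inverse, default) or `"acos"` (as commonly
#'   printed).
#' @return numeric vector of offsets clamped to [-0.5, 0.5], with a logical
#'   attribute `degenerate` marking fallback entries.
#' @export
cosine_subpixel_offset <- function(I_m1, I_0, I_p1, method = c("atan", "acos")) {
  method <- match.arg(method)
  n <- max(length(I_m1), length(I_0), length(I_p1))
  I_m1 <- rep_len(I_m1, n); I_0 <- rep_len(I_0, n); I_p1 <- rep_len(I_p1, n)
  arg <- (I_m1 + I_p1) / (2 * I_0)
  deg <- !(I_0 > pmax(I_m1, I_p1)) | !(I_0 > 0) | abs(arg) > 1 + 1e-12
  arg <- pmin(pmax(arg, -1), 1)
  alpha <- acos(arg)
  sa <- sin(alpha)
  deg <- deg | sa == 0 | alpha == 0
  sa[sa == 0] <- 1
  barg <- (I_m1 - I_p1) / (2 * I_0 * sa)
  beta <- if (method == "atan") atan(barg)
          else acos(pmin(pmax(barg, -1), 1))
  xi <- -beta / alpha
  xi[deg] <- 0
  xi <- pmin(pmax(xi, -0.5), 0.5)
  attr(xi, "degenerate") <- deg
  xi
}

#' Localize bubbles in one frame to subpixel precision
#'
#' Detects integer peaks with [detect_peaks()], then refines each peak
#' independently along x (columns) and y (rows) with
#' [cosine_subpixel_offset()] applied to the three smoothed samples through
#' the peak. Degenerate fits (e.g. peaks on the frame border) fall back to
#' the integer position and are flagged.
#'
#' @param frame nonnegative 2D intensity matrix.
#' @param config a [localization_config()].
#' @param method passed to [cosine_subpixel_offset()].
#' @return data.frame with columns `x`, `y` (0-based subpixel), `brightness`
#'   (smoothed intensity at the integer peak) and `degenerate`.
#' @export
localize_frame <- function(frame, config, method = "atan") {
  sm <- .gaussian_smooth(frame, config$gaussian_sigma)
  pk <- detect_peaks(frame, config)
  if (!nrow(pk))
    return(data.frame(x = numeric(), y = numeric(),
                      brightness = numeric(), degenerate = logical()))
  nr <- nrow(sm); nc <- ncol(sm)
  r <- pk$y + 1L; c <- pk$x + 1L           # 1-based indices
  xi_x <- numeric(nrow(pk)); xi_y <- numeric(nrow(pk))
  deg <- logical(nrow(pk))
  in_x <- c > 1L & c < nc
  in_y <- r > 1L & r < nr
  if (any(in_x)) {
    o <- cosine_subpixel_offset(sm[cbind(r[in_x], c[in_x] - 1L)],
                                sm[cbind(r[in_x], c[in_x])],
                                sm[cbind(r[in_x], c[in_x] + 1L)],
                                method = method)
    xi_x[in_x] <- o
    deg[in_x] <- deg[in_x] | attr(o, "degenerate")
  }
  if (any(in_y)) {
    o <- cosine_subpixel_offset(sm[cbind(r[in_y] - 1L, c[in_y])],
                                sm[cbind(r[in_y], c[in_y])],
                                sm[cbind(r[in_y] + 1L, c[in_y])],
                                method = method)
    xi_y[in_y] <- o
    deg[in_y] <- deg[in_y] | attr(o, "degenerate")
  }
  deg <- deg | !in_x | !in_y
  data.frame(x = pk$x + xi_x, y = pk$y + xi_y,
             brightness = pk$intensity, degenerate = deg)
}

#' Localize bubbles in every frame of a stack
#'
#' @param stack a [frame_stack()] (post clutter filtering).
#' @param config a [localization_config()].
#' @param method passed to [cosine_subpixel_offset()].
#' @return data.frame of detections: `frame` (0-based), `x`, `y`,
#'   `brightness`, `degenerate`.
#' @export
localize_stack <- function(stack, config, method = "atan") {
  out <- vector("list", n_frames(stack))
  for (t in seq_len(n_frames(stack))) {
    d <- localize_frame(stack[, , t], config, method = method)
    if (nrow(d)) d <- cbind(frame = t - 1L, d)
    out[[t]] <- d
  }
  out <- out[vapply(out, nrow, 1L) > 0]
  if (!length(out))
    return(data.frame(frame = integer(), x = numeric(), y = numeric(),
                      brightness = numeric(), degenerate = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a detections table as CSV
#'
#' Columns `frame, x, y, brightness`, floats with 6 decimals.
#' @param detections data.frame from [localize_stack()].
#' @param path CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  d <- detections[, c("frame", "x", "y", "brightness")]
  d$x <- round(d$x, 6); d$y <- round(d$y, 6); d$brightness <- round(d$brightness, 6)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) utils::read.csv(path)
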