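#' SVD clutter-filter configuration
#'
#' Spatiotemporal SVD filtering removes tissue clutter — the slowly varying,
#' spatially coherent part of the signal — by zeroing the leading singular
#' components of the Casorati matrix (pixels x frames), then applying a
#' magnitude noise floor so that only bubble-originated signal above the
#' floor is retained.
#'
#' @param n_tissue_components number of leading singular components removed.
#' @param noise_threshold post-filter magnitude floor (intensity units);
#'   estimate it from a bubble-free control acquisition with
#'   [estimate_noise_threshold()].
#' @param chunk_size frames per SVD block; chunks are filtered independently
#'   to bound memory on long acquisitions.
#' @export
svd_config <- function(n_tissue_components = 2L, noise_threshold = 0,
                       chunk_size = 200L) {
  stopifnot(n_tissue_components >= 0, noise_threshold >= 0, chunk_size >= 2)
  structure(list(n_tissue_components = as.integer(n_tissue_components),
                 noise_threshold = noise_threshold,
                 chunk_size = as.integer(chunk_size)),
            class = "svd_config")
}

#' Reshape a frame stack into its Casorati matrix
#'
#' @param stack a [frame_stack()] or 3D array.
#' @return numeric matrix with one row per pixel and one column per frame.
#' @export
casorati <- function(stack) {
  d <- dim(stack)
  matrix(stack, nrow = d[1] * d[2], ncol = d[3])
}

# residual after removing the k leading singular components of one chunk
.svd_residual <- function(X, k) {
  if (k == 0L) return(X)
  k <- min(k, min(dim(X)) - 1L)
  s <- svd(X, nu = k, nv = k)
  X - s$u %*% (s$d[seq_len(k)] * t(s$v))
}

#' Spatiotemporal SVD clutter filtering with a noise floor
#'
#' For each temporal chunk the Casorati matrix is formed, its
#' `n_tissue_components` leading singular components are zeroed, the chunk is
#' reconstructed and the magnitude (absolute value) taken; pixels below
#' `noise_threshold` are then set to zero. Frame count and shape are
#' preserved; the output is everywhere nonnegative.
#'
#' @param stack a [frame_stack()].
#' @param config an [svd_config()].
#' @return filtered [frame_stack()] of magnitudes.
#' @export
svd_filter <- function(stack, config) {
  stopifnot(inherits(config, "svd_config"))
  if (!all(is.finite(stack))) stop("non-finite values in input stack")
  d <- dim(stack)
  nf <- d[3]
  starts <- seq(1L, nf, by = config$chunk_size)
  # a trailing 1-frame chunk cannot be SVD-filtered; fold it into the previous
  if (length(starts) > 1L && starts[length(starts)] == nf)
    starts <- starts[-length(starts)]
  out <- array(0, d)
  for (s in starts) {
    e <- min(s + config$chunk_size - 1L, nf)
    X <- casorati(stack[, , s:e, drop = FALSE])
    if (ncol(X) < 2L) stop("SVD chunk must contain at least 2 frames")
    R <- abs(.svd_residual(X, config$n_tissue_components))
    if (config$noise_threshold > 0) R[R < config$noise_threshold] <- 0
    out[, , s:e] <- array(R, c(d[1], d[2], e - s + 1L))
  }
  frame_stack(out, frame_rate = frame_rate(stack),
              pixel_size = attr(stack, "pixel_size_um"))
}

#' Estimate the post-SVD noise floor from a bubble-free control stack
#'
#' Applies the same SVD clutter removal (no thresholding) to a control
#' acquisition without contrast agent and returns the given percentile of the
#' residual magnitudes; the default 99th percentile is a floor that
#' suppresses nearly all clutter/noise residue while keeping bubble peaks,
#' which are far brighter.
#'
#' @param control_stack bubble-free [frame_stack()] (caller's responsibility).
#' @param config an [svd_config()]; its `noise_threshold` is ignored.
#' @param percentile fraction in (0, 1]; 1 gives the maximum residual.
#' @return scalar threshold in intensity units.
#' @export
estimate_noise_threshold <- function(control_stack, config, percentile = 0.99) {
  if (length(control_stack) == 0L) stop("empty control stack")
  stopifnot(percentile > 0, percentile <= 1)
  cfg <- svd_config(config$n_tissue_components, 0, config$chunk_size)
  res <- svd_filter(control_stack, cfg)
  as.numeric(stats::quantile(res, probs = percentile, names = FALSE))
}
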