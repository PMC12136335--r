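#' Render super-resolved density and velocity maps from tracks
#'
#' Accumulates accepted trajectories on a grid upsampled by `sr_factor`.
#' Each inter-frame segment is sampled at super-resolution spacing; each
#' sample increments the density of its SR pixel by one and deposits the
#' segment's signed speed (px/frame; sign +1 for motion toward +y, -1 toward
#' -y) into that pixel's sample list. The velocity map is the per-pixel mean
#' of the samples and is undefined (NA) where density is zero. The mapping
#' from a continuous position to an SR pixel is
#' `floor((coord + 0.5) * sr_factor)` (0-based), matching
#' [render_vessel_mask()].
#'
#' @param tracks data.frame (`track_id, frame, x, y`); typically the
#'   VD-accepted output of [filter_tracks()].
#' @param grid_shape (rows, cols) of the original pixel grid.
#' @param sr_factor integer upsampling factor.
#' @param max_frame_gap largest frame gap between consecutive track points
#'   whose segment is deposited. The default 1 accumulates only observed
#'   inter-frame displacements: a segment bridged by coasting has no
#'   measured positions in between, and interpolating across it would
#'   assert a path (and velocity) that was never observed. `Inf` deposits
#'   every segment.
#' @return object of class `ulm_maps`: list with `density` (integer counts),
#'   `velocity` (signed px/frame, NA outside coverage), `samples`
#'   (data.frame of all deposited velocity samples: `idx` a linear 1-based
#'   index into the SR grid, `v` the signed speed used by the velocity map,
#'   `vx`/`vy` the velocity vector used by [nrmse()]), `sr_factor`,
#'   `grid_shape`.
#' @export
render_maps <- function(tracks, grid_shape, sr_factor = 8L,
                        max_frame_gap = 1L) {
  f <- as.integer(sr_factor)
  nr <- grid_shape[1] * f; nc <- grid_shape[2] * f
  idx_all <- integer(0); v_all <- numeric(0)
  vx_all <- numeric(0); vy_all <- numeric(0)
  if (nrow(tracks)) {
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      tr <- tr[order(tr$frame), , drop = FALSE]
      n <- nrow(tr)
      if (n < 2) next
      for (i in seq_len(n - 1L)) {
        dfr <- tr$frame[i + 1L] - tr$frame[i]
        if (dfr > max_frame_gap) next
        vx <- (tr$x[i + 1L] - tr$x[i]) / dfr
        vy <- (tr$y[i + 1L] - tr$y[i]) / dfr
        sp <- sqrt(vx^2 + vy^2)
        sgn <- if (vy > 0) 1 else if (vy < 0) -1 else 1
        seg <- sp * dfr
        ns <- max(1L, ceiling(seg * f))
        tfr <- (seq_len(ns) - 1L) / ns          # include start, exclude end
        xs <- tr$x[i] + tfr * (tr$x[i + 1L] - tr$x[i])
        ys <- tr$y[i] + tfr * (tr$y[i + 1L] - tr$y[i])
        if (i == n - 1L) { xs <- c(xs, tr$x[n]); ys <- c(ys, tr$y[n]) }
        cx <- floor((xs + 0.5) * f); cy <- floor((ys + 0.5) * f)
        ok <- cx >= 0 & cx < nc & cy >= 0 & cy < nr
        if (!any(ok)) next
        idx_all <- c(idx_all, (cy[ok]) + 1L + (cx[ok]) * nr)
        v_all <- c(v_all, rep(sgn * sp, sum(ok)))
        vx_all <- c(vx_all, rep(vx, sum(ok)))
        vy_all <- c(vy_all, rep(vy, sum(ok)))
      }
    }
  }
  density <- matrix(0L, nr, nc)
  velocity <- matrix(NA_real_, nr, nc)
  if (length(idx_all)) {
    tab <- tabulate(idx_all, nbins = nr * nc)
    density <- matrix(tab, nr, nc)
    sums <- rowsum(v_all, idx_all)
    ui <- as.integer(rownames(sums))
    velocity[ui] <- sums[, 1] / tab[ui]
  }
  structure(list(density = density, velocity = velocity,
                 samples = data.frame(idx = idx_all, v = v_all,
                                      vx = vx_all, vy = vy_all),
                 sr_factor = f, grid_shape = grid_shape),
            class = "ulm_maps")
}

#' @export
print.ulm_maps <- function(x, ...) {
  cat(sprintf("ulm_maps: %d x %d SR grid (factor %d), %d samples, %d covered px\n",
              nrow(x$density), ncol(x$density), x$sr_factor,
              nrow(x$samples), sum(x$density > 0)))
  invisible(x)
}

#' Plot ULM maps
#'
#' Density on a dark-to-bright scale; velocity on a diverging palette, warm
#' colors for flow toward +y.
#'
#' @param x an `ulm_maps` object.
#' @param which `"density"` or `"velocity"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ulm_maps <- function(x, which = c("density", "velocity"), ...) {
  which <- match.arg(which)
  if (which == "density") {
    m <- log1p(x$density)
    graphics::image(t(m)[, nrow(m):1], col = grDevices::hcl.colors(64, "Inferno"),
                    axes = FALSE, asp = nrow(m) / ncol(m), ...)
  } else {
    m <- x$velocity
    lim <- max(abs(m), na.rm = TRUE)
    graphics::image(t(m)[, nrow(m):1], zlim = c(-lim, lim),
                    col = grDevices::hcl.colors(64, "Blue-Red 3"),
                    axes = FALSE, asp = nrow(m) / ncol(m), ...)
  }
  invisible(x)
}

#' Contrast-to-noise ratio between vessel and noise regions
#'
#' `CNR = (E_V - E_N) / sigma_N` with `E_V`, `E_N` the mean intensities of
#' the vessel and noise regions and `sigma_N` the standard deviation of the
#' noise region; invariant under positive rescaling of the image.
#'
#' @param image numeric matrix (typically a density map).
#' @param vessel_region,noise_region disjoint non-empty logical masks of the
#'   same dimension as `image`.
#' @export
cnr <- function(image, vessel_region, noise_region) {
  stopifnot(identical(dim(image), dim(vessel_region)),
            identical(dim(image), dim(noise_region)))
  if (!any(vessel_region) || !any(noise_region)) stop("empty region")
  if (any(vessel_region & noise_region)) stop("regions must be disjoint")
  ev <- mean(image[vessel_region])
  en <- mean(image[noise_region])
  sn <- stats::sd(image[noise_region])
  if (sn == 0) stop("noise region has zero standard deviation")
  (ev - en) / sn
}

#' Normalized RMSE of per-pixel velocity estimates
#'
#' For each covered pixel with at least `min_samples` velocity samples and a
#' nonzero mean velocity vector, computes
#' `sqrt(mean(|V_i - V_mean|^2)) / |V_mean|` with `V_i` the per-sample
#' velocity vectors and `V_mean` their mean vector; the image-level value is
#' the unweighted mean over valid pixels (a density-weighted mean is
#' available). Pixels whose mean velocity vanishes are excluded and counted.
#' Scale-invariant: multiplying all samples by c > 0 leaves the result
#' unchanged. Given a plain list of numeric vectors, each is treated as 1D
#' (scalar speed) samples of one pixel.
#'
#' @param x an `ulm_maps` object, or a list of numeric per-pixel sample
#'   vectors.
#' @param min_samples minimum samples per pixel (>= 2).
#' @param weighted weight pixels by their sample count.
#' @return scalar nRMSE with attributes `n_valid` and `n_zero_mean`.
#' @export
nrmse <- function(x, min_samples = 2L, weighted = FALSE) {
  if (inherits(x, "ulm_maps")) {
    s <- x$samples
    agg <- rowsum(cbind(1, s$vx, s$vy, s$vx^2, s$vy^2), s$idx)
    n <- agg[, 1]
    mx <- agg[, 2] / n; my <- agg[, 3] / n
    ss <- pmax(agg[, 4] - n * mx^2, 0) + pmax(agg[, 5] - n * my^2, 0)
    mnorm <- sqrt(mx^2 + my^2)
  } else {
    n <- vapply(x, length, 1L)
    mnorm <- abs(vapply(x, mean, 1))
    ss <- vapply(x, function(v) sum((v - mean(v))^2), 1)
  }
  enough <- n >= min_samples
  zero <- enough & mnorm == 0
  ok <- enough & mnorm != 0
  vals <- sqrt(ss[ok] / n[ok]) / mnorm[ok]
  out <- if (!length(vals)) NA_real_
         else if (weighted) sum(vals * n[ok]) / sum(n[ok])
         else mean(vals)
  attr(out, "n_valid") <- sum(ok)
  attr(out, "n_zero_mean") <- sum(zero)
  out
}

# square (Chebyshev) binary dilation by r pixels via iterated 3x3 OR
.dilate <- function(mask, r) {
  if (r <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  for (k in seq_len(r)) {
    m <- mask
    m[-1, ] <- m[-1, ] | mask[-nr, ]
    m[-nr, ] <- m[-nr, ] | mask[-1, ]
    m2 <- m
    m2[, -1] <- m2[, -1] | m[, -nc]
    m2[, -nc] <- m2[, -nc] | m[, -1]
    mask <- m2
  }
  mask
}

#' Vessel/noise evaluation regions from a ground-truth mask
#'
#' The vessel region is the mask dilated by `dilate_vessel` original pixels
#' (tolerating residual localization or alignment offsets); the noise region
#' is everything outside the mask dilated by `margin` pixels, so that a
#' guard band separates the two.
#'
#' @param vessel_mask logical SR-resolution mask (see [render_vessel_mask()]).
#' @param sr_factor the mask's upsampling factor.
#' @param dilate_vessel,margin dilation radii in original pixels.
#' @return list of disjoint logical masks `vessel` and `noise`.
#' @export
region_masks_from_truth <- function(vessel_mask, sr_factor = 8L,
                                    dilate_vessel = 2, margin = 6) {
  f <- as.integer(sr_factor)
  vessel <- .dilate(vessel_mask, round(dilate_vessel * f))
  noise <- !.dilate(vessel_mask, round(margin * f))
  list(vessel = vessel, noise = noise)
}

#' Mean trace length of a track set (detections per track)
#' @param tracks data.frame from [track_stack()].
#' @export
mean_trace_length <- function(tracks) {
  if (!nrow(tracks)) return(0)
  mean(table(tracks$track_id))
}

#' Mean trace duration of a track set, in seconds
#' @param tracks data.frame from [track_stack()].
#' @param frame_rate acquisition rate (Hz) of the tracked stack.
#' @export
mean_trace_duration <- function(tracks, frame_rate) {
  if (!nrow(tracks)) return(0)
  d <- tapply(tracks$frame, tracks$track_id, function(f) diff(range(f)) + 1)
  mean(d) / frame_rate
}

#' Mean flow speed of a track set, in px/s
#'
#' Per-track mean step speed scaled by the frame rate so that values are
#' comparable across temporal subsampling. Only observed consecutive-frame
#' displacements enter (steps across coasted gaps are chords that
#' underestimate speed on curved paths and are skipped, like in
#' [render_maps()]).
#'
#' @param tracks data.frame from [track_stack()].
#' @param frame_rate acquisition rate (Hz) of the tracked stack.
#' @param max_frame_gap largest frame gap between points of a counted step.
#' @export
mean_flow_speed <- function(tracks, frame_rate, max_frame_gap = 1) {
  if (!nrow(tracks)) return(0)
  sp <- tapply(seq_len(nrow(tracks)), tracks$track_id, function(i) {
    tr <- tracks[i, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(NA_real_)
    df <- diff(tr$frame)
    st <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / df
    st <- st[df <= max_frame_gap]
    if (!length(st)) return(NA_real_)
    mean(st)
  })
  mean(sp, na.rm = TRUE) * frame_rate
}
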