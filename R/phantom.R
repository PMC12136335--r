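#' Specify one vessel of the flow phantom
#'
#' A vessel is a tube of constant radius around a polyline centerline.
#' Bubbles are advected along the centerline (arc-length parameterization,
#' linear interpolation between control points) at constant `flow_speed`,
#' each with a fixed lateral offset drawn inside the lumen; they die on
#' leaving the centerline or the grid.
#'
#' @param centerline numeric n x 2 matrix of (x, y) control points in pixels
#'   (0-based coordinates, x = column, y = row); at least 2 points.
#' @param radius lumen radius in pixels (> 0).
#' @param flow_speed bubble speed in pixels/frame (>= 0).
#' @param direction_sign +1 to traverse the centerline from its first to its
#'   last control point, -1 for the reverse. Order control points toward
#'   increasing y so that +1 means flow toward +y.
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(centerline, radius, flow_speed, direction_sign = 1) {
  centerline <- as.matrix(centerline)
  stopifnot(nrow(centerline) >= 2, ncol(centerline) == 2,
            radius > 0, flow_speed >= 0, direction_sign %in% c(-1, 1))
  structure(list(centerline = centerline, radius = radius,
                 flow_speed = flow_speed, direction_sign = direction_sign),
            class = "vessel_spec")
}

#' Configuration of the synthetic ULM flow phantom
#'
#' The phantom emulates the three additive components of an in-vivo
#' contrast-enhanced acquisition: sparse moving point scatterers (microbubbles
#' convolved with a Gaussian PSF), low-rank slowly varying tissue clutter, and
#' i.i.d. Gaussian noise, with an optional smooth global motion
#' (respiration/heartbeat-like sinusoid) applied to the whole scene.
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 128 x 128 px grid at 440 Hz, PSF sigma 1.2 px, per-bubble
#' brightness drawn uniformly from `brightness_range`, tissue clutter an
#' order of magnitude brighter than single bubbles (rank 2), and mild additive
#' noise.
#'
#' @param grid_shape (rows, cols) in pixels, each >= 32.
#' @param n_frames number of frames (>= 3).
#' @param frame_rate acquisition rate in Hz.
#' @param vessels list of [vessel_spec()] objects (may be empty).
#' @param bubble_rate expected spawns per frame per vessel (Poisson mean).
#' @param psf_sigma Gaussian PSF standard deviation in pixels (> 0).
#' @param brightness_range (min, max) of per-bubble constant peak brightness.
#' @param clutter_amplitude overall clutter intensity scale (>= 0).
#' @param clutter_rank number of separable space-time clutter components.
#' @param noise_sigma standard deviation of additive Gaussian noise (>= 0).
#' @param motion_amplitude (ax, ay) pixels of global sinusoidal motion.
#' @param motion_period period of the motion sinusoid in frames.
#' @param min_spawn_spacing minimum along-vessel headway (px) between
#'   bubbles of the same vessel; spawns closer than this to an existing
#'   bubble are suppressed. Since co-vessel bubbles share one speed, the
#'   headway persists for the bubbles' lifetime, keeping same-vessel bubbles
#'   resolvable (separability is a working assumption of peak-based
#'   localization); bubbles of crossing vessels may still overlap
#'   transiently. The default, four PSF sigmas, is just above the two-sigma
#'   merging limit of peak detection.
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(128L, 128L),
                           n_frames = 200L,
                           frame_rate = 440,
                           vessels = list(),
                           bubble_rate = 0.2,
                           psf_sigma = 1.2,
                           brightness_range = c(5, 10),
                           clutter_amplitude = 20,
                           clutter_rank = 2L,
                           noise_sigma = 0.3,
                           motion_amplitude = c(0, 0),
                           motion_period = 80L,
                           min_spawn_spacing = 4 * psf_sigma,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 32),
            n_frames >= 3, psf_sigma > 0, bubble_rate >= 0,
            clutter_amplitude >= 0, clutter_rank >= 0, noise_sigma >= 0,
            length(motion_amplitude) == 2, all(motion_amplitude >= 0),
            motion_period >= 1, length(brightness_range) == 2,
            brightness_range[1] > 0, brightness_range[2] >= brightness_range[1])
  for (v in vessels) stopifnot(inherits(v, "vessel_spec"))
  structure(list(grid_shape = as.integer(grid_shape),
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 vessels = vessels, bubble_rate = bubble_rate,
                 psf_sigma = psf_sigma, brightness_range = brightness_range,
                 clutter_amplitude = clutter_amplitude,
                 clutter_rank = as.integer(clutter_rank),
                 noise_sigma = noise_sigma,
                 motion_amplitude = as.numeric(motion_amplitude),
                 motion_period = motion_period,
                 min_spawn_spacing = min_spawn_spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# arc-length parameterization of a polyline; returns interpolators
.polyline_param <- function(pts) {
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  list(total = cum[length(cum)], cum = cum, pts = pts, seg = seg, len = len)
}

# position and unit tangent at arc length s (vectorized over s)
.polyline_eval <- function(par, s) {
  s <- pmin(pmax(s, 0), par$total)
  i <- findInterval(s, par$cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(par$seg))
  t_ <- (s - par$cum[i]) / pmax(par$len[i], .Machine$double.eps)
  pos <- par$pts[i, , drop = FALSE] + par$seg[i, , drop = FALSE] * t_
  tan_ <- par$seg[i, , drop = FALSE] / pmax(par$len[i], .Machine$double.eps)
  list(pos = pos, tangent = tan_)
}

#' Shift an image by a subpixel displacement (bilinear, zero padding)
#'
#' Content is moved by (+dx, +dy): a feature at position (x, y) appears at
#' (x + dx, y + dy) in the output. Used both by the phantom's global-motion
#' model and by motion-compensation tests.
#'
#' @param mat 2D numeric matrix.
#' @param dx,dy displacement in pixels (x = columns, y = rows).
#' @export
shift_image <- function(mat, dx, dy) {
  if (dx == 0 && dy == 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  # source coordinates (1-based): out[r, c] = in[r - dy, c - dx]
  sr <- seq_len(nr) - dy
  sc <- seq_len(nc) - dx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0;   fc <- sc - c0
  at <- function(ri, ci) {
    ok_r <- ri >= 1 & ri <= nr
    ok_c <- ci >= 1 & ci <= nc
    m <- matrix(0, nr, nc)
    if (any(ok_r) && any(ok_c))
      m[ok_r, ok_c] <- mat[ri[ok_r], ci[ok_c], drop = FALSE]
    m
  }
  at(r0, c0) * outer(1 - fr, 1 - fc) +
    at(r0 + 1, c0) * outer(fr, 1 - fc) +
    at(r0, c0 + 1) * outer(1 - fr, fc) +
    at(r0 + 1, c0 + 1) * outer(fr, fc)
}

# stamp one Gaussian blob (peak amplitude b at 0-based subpixel (x, y))
.add_blob <- function(img, x, y, b, sigma) {
  w <- ceiling(4 * sigma)
  rc <- round(y) + 1L; cc <- round(x) + 1L
  rr <- max(1L, rc - w):min(nrow(img), rc + w)
  cc_ <- max(1L, cc - w):min(ncol(img), cc + w)
  if (!length(rr) || !length(cc_)) return(img)
  gy <- exp(-((rr - 1L) - y)^2 / (2 * sigma^2))
  gx <- exp(-((cc_ - 1L) - x)^2 / (2 * sigma^2))
  img[rr, cc_] <- img[rr, cc_] + b * outer(gy, gx)
  img
}

#' Generate a synthetic ULM movie with exact ground truth
#'
#' Builds, frame by frame, `clutter + bubbles`, applies the global sinusoidal
#' motion to the whole scene by bilinear shifting, then adds i.i.d. Gaussian
#' noise. Ground truth records the pre-motion bubble tracks, the applied
#' per-frame displacements dx(t) = ax sin(2 pi t / P) (and likewise dy), and a
#' super-resolved vessel mask. With `keep_layers = TRUE` the post-motion
#' clutter, bubble and noise layers are stored separately so downstream
#' filters can be checked by exact energy bookkeeping.
#'
#' @param config a [phantom_config()].
#' @param keep_layers store the additive scene components in the ground truth.
#' @param mask_sr_factor super-resolution factor of the ground-truth vessel
#'   mask.
#' @return list with elements `stack` (a [frame_stack()]) and `truth` (list:
#'   `tracks` data.frame (track_id, frame, x, y, brightness), `displacements`
#'   data.frame (frame, dx, dy), `vessel_mask`, `sr_factor`, and optionally
#'   `layers`).
#' @export
generate_phantom <- function(config, keep_layers = TRUE, mask_sr_factor = 8L) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  nf <- config$n_frames

  # ---- bubble ground truth (pre-motion coordinates) ----
  tracks <- list(); next_id <- 1L
  for (v in config$vessels) {
    par <- .polyline_param(v$centerline)
    entry <- if (v$direction_sign > 0) 0 else par$total
    transit <- if (v$flow_speed > 0) par$total / v$flow_speed else nf
    spawns <- list()
    n0 <- stats::rpois(1, config$bubble_rate * min(transit, nf))
    if (n0 > 0)
      spawns[[1]] <- data.frame(t0 = 0L, s0 = stats::runif(n0, 0, par$total))
    for (t in seq_len(nf - 1L)) {
      n <- stats::rpois(1, config$bubble_rate)
      if (n > 0)
        spawns[[length(spawns) + 1L]] <- data.frame(
          t0 = t, s0 = entry + v$direction_sign * v$flow_speed * stats::runif(n))
    }
    if (!length(spawns)) next
    spawns <- do.call(rbind, spawns)
    # enforce along-vessel headway: co-vessel bubbles share one speed, so
    # the spawn phase s0 - dir*v*t0 fixes their spacing for all time
    if (config$min_spawn_spacing > 0) {
      phase <- spawns$s0 - v$direction_sign * v$flow_speed * spawns$t0
      keep <- logical(nrow(spawns)); kept <- numeric(0)
      for (i in order(spawns$t0, spawns$s0)) {
        if (!length(kept) ||
            min(abs(kept - phase[i])) >= config$min_spawn_spacing) {
          keep[i] <- TRUE
          kept <- c(kept, phase[i])
        }
      }
      spawns <- spawns[keep, , drop = FALSE]
    }
    for (i in seq_len(nrow(spawns))) {
      u <- stats::runif(1, -0.8, 0.8) * v$radius
      b <- stats::runif(1, config$brightness_range[1], config$brightness_range[2])
      t0 <- spawns$t0[i]
      tt <- t0:(nf - 1L)
      s <- spawns$s0[i] + v$direction_sign * v$flow_speed * (tt - t0)
      alive <- s >= 0 & s <= par$total
      if (!any(alive)) next
      tt <- tt[alive]; s <- s[alive]
      ev <- .polyline_eval(par, s)
      nrm <- cbind(-ev$tangent[, 2], ev$tangent[, 1])
      pos <- ev$pos + u * nrm
      inside <- pos[, 1] >= 0 & pos[, 1] <= nc - 1 & pos[, 2] >= 0 & pos[, 2] <= nr - 1
      if (any(!inside)) {  # die permanently on first exit
        last <- which(!inside)[1] - 1L
        if (last < 1L) next
        tt <- tt[seq_len(last)]; pos <- pos[seq_len(last), , drop = FALSE]
      }
      tracks[[length(tracks) + 1L]] <- data.frame(
        track_id = next_id, frame = tt, x = pos[, 1], y = pos[, 2], brightness = b)
      next_id <- next_id + 1L
    }
  }
  tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(track_id = integer(), frame = integer(),
               x = numeric(), y = numeric(), brightness = numeric())
  rownames(tracks) <- NULL

  # ---- clutter components: separable smooth patterns x slow sinusoids ----
  # each component is separable (rank 1 in the Casorati matrix): a textured
  # smooth spatial profile pair times a slow, positive temporal modulation.
  # Positivity keeps the tissue pattern quasi-static (contrast never inverts),
  # as in real speckle, while the stack remains exactly rank <= clutter_rank.
  rank <- if (config$clutter_amplitude > 0) config$clutter_rank else 0L
  smooth_profile <- function(n) {
    z <- stats::rnorm(n + 24)
    k <- exp(-(-8:8)^2 / (2 * 3^2)); k <- k / sum(k)
    s <- stats::filter(z, k, sides = 2)[13:(n + 12)]
    s <- (s - mean(s)) / stats::sd(s)
    pmax(1 + 0.45 * s, 0.05)
  }
  cl_spatial <- vector("list", rank); cl_temporal <- vector("list", rank)
  for (r in seq_len(rank)) {
    cl_spatial[[r]] <- (config$clutter_amplitude / rank) *
      outer(smooth_profile(nr), smooth_profile(nc))
    per <- nf * stats::runif(1, 0.8, 1.6)   # slower than the record length
    cl_temporal[[r]] <- 1 + 0.15 * cos(2 * pi * (0:(nf - 1)) / per +
                                         stats::runif(1, 0, 2 * pi))
  }

  # ---- motion trajectory ----
  t0 <- 0:(nf - 1)
  dx_t <- config$motion_amplitude[1] * sin(2 * pi * t0 / config$motion_period)
  dy_t <- config$motion_amplitude[2] * sin(2 * pi * t0 / config$motion_period)
  moving <- any(config$motion_amplitude > 0)

  # ---- render ----
  stack <- array(0, c(nr, nc, nf))
  clutter_layer <- if (keep_layers) array(0, c(nr, nc, nf)) else NULL
  bubble_layer <- if (keep_layers) array(0, c(nr, nc, nf)) else NULL
  noise_layer <- if (keep_layers) array(0, c(nr, nc, nf)) else NULL
  by_frame <- if (nrow(tracks)) split(tracks, tracks$frame) else list()
  for (t in seq_len(nf)) {
    cl <- matrix(0, nr, nc)
    for (r in seq_len(rank)) cl <- cl + cl_spatial[[r]] * cl_temporal[[r]][t]
    bu <- matrix(0, nr, nc)
    tf <- by_frame[[as.character(t - 1L)]]
    if (!is.null(tf))
      for (i in seq_len(nrow(tf)))
        bu <- .add_blob(bu, tf$x[i], tf$y[i], tf$brightness[i], config$psf_sigma)
    if (moving) {
      cl <- shift_image(cl, dx_t[t], dy_t[t])
      bu <- shift_image(bu, dx_t[t], dy_t[t])
    }
    noi <- if (config$noise_sigma > 0)
      matrix(stats::rnorm(nr * nc, 0, config$noise_sigma), nr, nc) else matrix(0, nr, nc)
    stack[, , t] <- cl + bu + noi
    if (keep_layers) {
      clutter_layer[, , t] <- cl
      bubble_layer[, , t] <- bu
      noise_layer[, , t] <- noi
    }
  }

  # density sanity: localization assumes separable bubbles
  if (nrow(tracks)) {
    sp <- vapply(by_frame, function(tf) {
      if (nrow(tf) < 2) return(NA_real_)
      d <- as.matrix(stats::dist(tf[, c("x", "y")]))
      diag(d) <- Inf
      mean(apply(d, 1, min))
    }, numeric(1))
    if (!all(is.na(sp)) && mean(sp, na.rm = TRUE) < 2 * config$psf_sigma)
      warning("mean nearest-neighbour bubble spacing < 2*psf_sigma; ",
              "localization assumptions violated")
  }

  truth <- list(
    tracks = tracks,
    displacements = data.frame(frame = t0, dx = dx_t, dy = dy_t),
    vessel_mask = render_vessel_mask(config$vessels, config$grid_shape, mask_sr_factor),
    sr_factor = as.integer(mask_sr_factor))
  if (keep_layers)
    truth$layers <- list(clutter = clutter_layer, bubbles = bubble_layer,
                         noise = noise_layer)

  list(stack = frame_stack(stack, frame_rate = config$frame_rate),
       truth = truth)
}

#' Render a binary vessel mask at super-resolution
#'
#' @param vessels list of [vessel_spec()].
#' @param grid_shape (rows, cols) of the original pixel grid.
#' @param sr_factor integer upsampling factor.
#' @return logical matrix of size `grid_shape * sr_factor`; TRUE inside a
#'   vessel lumen.
#' @export
render_vessel_mask <- function(vessels, grid_shape, sr_factor = 8L) {
  f <- as.integer(sr_factor)
  nr <- grid_shape[1] * f; nc <- grid_shape[2] * f
  mask <- matrix(FALSE, nr, nc)
  for (v in vessels) {
    par <- .polyline_param(v$centerline)
    s <- seq(0, par$total, by = max(0.25 / f, 1e-6))
    pos <- .polyline_eval(par, s)$pos
    rad_sr <- v$radius * f
    w <- ceiling(rad_sr)
    off <- expand.grid(dr = -w:w, dc = -w:w)
    off <- off[off$dr^2 + off$dc^2 <= rad_sr^2, ]
    # continuous (x, y) -> 0-based SR index floor((coord + 0.5) * f)
    cc <- floor((pos[, 1] + 0.5) * f) + 1L
    rr <- floor((pos[, 2] + 0.5) * f) + 1L
    for (k in seq_len(nrow(off))) {
      r2 <- rr + off$dr[k]; c2 <- cc + off$dc[k]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      mask[cbind(r2[ok], c2[ok])] <- TRUE
    }
  }
  mask
}
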