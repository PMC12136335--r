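# shared fixtures: small phantoms and synthetic images built in code

# a Gaussian blob with peak amplitude b at 0-based subpixel (x0, y0)
make_blob <- function(x0, y0, sigma = 1.2, nr = 64, nc = 64, b = 8) {
  xs <- 0:(nc - 1)
  img <- matrix(0, nr, nc)
  for (r in seq_len(nr))
    img[r, ] <- b * exp(-((xs - x0)^2 + ((r - 1) - y0)^2) / (2 * sigma^2))
  img
}

# single straight vertical vessel down the middle of a small grid
straight_vessel <- function(x = 30, flow_speed = 1, nr = 64, radius = 1.2) {
  vessel_spec(rbind(c(x, 0), c(x, nr - 1)), radius = radius,
              flow_speed = flow_speed)
}

# clean phantom: one vessel, no clutter/noise/motion
clean_phantom_config <- function(n_frames = 40, flow_speed = 1, seed = 11,
                                 bubble_rate = 0.05) {
  phantom_config(grid_shape = c(64L, 64L), n_frames = n_frames,
                 vessels = list(straight_vessel(flow_speed = flow_speed)),
                 bubble_rate = bubble_rate, clutter_amplitude = 0,
                 noise_sigma = 0, seed = seed)
}

# moderate-density two-vessel phantom with clutter and noise
busy_phantom_config <- function(n_frames = 120, seed = 5, noise_sigma = 0.3,
                                motion_amplitude = c(0, 0), motion_period = 40L,
                                bubble_rate = 0.12) {
  v1 <- vessel_spec(rbind(c(18, 0), c(18, 95)), radius = 1.4, flow_speed = 1.0)
  v2 <- vessel_spec(rbind(c(70, 95), c(70, 0)), radius = 1.4, flow_speed = 1.2)
  v3 <- vessel_spec(rbind(c(0, 20), c(95, 75)), radius = 1.4, flow_speed = 1.1)
  phantom_config(grid_shape = c(96L, 96L), n_frames = n_frames,
                 vessels = list(v1, v2, v3), bubble_rate = bubble_rate,
                 clutter_amplitude = 20, clutter_rank = 2L,
                 noise_sigma = noise_sigma,
                 motion_amplitude = motion_amplitude,
                 motion_period = motion_period, seed = seed)
}

# textured pseudo-tissue image for motion-estimation tests (smooth, seeded)
textured_image <- function(nr = 64, nc = 64, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- exp(-(-6:6)^2 / (2 * 2^2)); k <- k / sum(k)
  for (r in seq_len(nr)) z[r, ] <- stats::filter(z[r, ], k, circular = TRUE)
  for (c in seq_len(nc)) z[, c] <- stats::filter(z[, c], k, circular = TRUE)
  z <- z - min(z) + 0.1
  z / max(z)
}

# default tracker used in small linking tests
test_tracker <- function(...) tracker_config(min_track_length = 3L, ...)
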