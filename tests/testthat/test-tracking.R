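cfg0 <- tracker_config(brightness_scale = 1)

test_that("prediction follows the constant-velocity model", {
  s <- track_state(0, 0, 5, cfg0)
  s$S <- c(0, 0, 5, 1, 2)
  p <- kalman_predict(s, cfg0)
  expect_equal(p$S, c(1, 2, 5, 1, 2))

  s2 <- track_state(3, 4, 2, cfg0)     # zero velocity: position fixed, P grows
  p2 <- kalman_predict(s2, cfg0)
  expect_equal(p2$S[1:2], c(3, 4))
  expect_gt(p2$P[3, 3], s2$P[3, 3])

  s3 <- track_state(0, 0, 1, cfg0)
  s3$S[4:5] <- c(1, 0)
  for (i in 1:10) s3 <- kalman_predict(s3, cfg0)
  expect_equal(s3$S[1], 10)
})

test_that("update reproduces the stated Kalman-gain limits", {
  # R -> infinity: gain ~ 0, estimate = prediction
  cfg_r <- tracker_config(r_pos = 1e12, r_I = 1e12, brightness_scale = 1)
  s <- track_state(1, 2, 3, cfg_r)
  s$P <- diag(5) * 1e-4
  u <- kalman_update(s, c(10, 20, 30), cfg_r)
  expect_equal(u$S[1:3], c(1, 2, 3), tolerance = 1e-6)

  # P >> R: gain ~ identity on observed components, estimate = measurement
  cfg_p <- tracker_config(r_pos = 1e-9, r_I = 1e-9, brightness_scale = 1)
  s2 <- track_state(1, 2, 3, cfg_p)
  s2$P <- diag(5) * 1e6
  u2 <- kalman_update(s2, c(10, 20, 30), cfg_p)
  expect_equal(u2$S[1:3], c(10, 20, 30), tolerance = 1e-6)

  # 1D hand algebra: P = R on an observed axis gives K = 1/2, the midpoint
  cfg_m <- tracker_config(r_pos = 0.3, r_I = 0.3, brightness_scale = 1)
  s3 <- track_state(0, 0, 0, cfg_m)
  s3$P <- diag(c(0.3, 0.3, 0.3, 1e-12, 1e-12))
  u3 <- kalman_update(s3, c(4, -2, 6), cfg_m)
  expect_equal(u3$S[1:3], c(2, -1, 3), tolerance = 1e-9)
})

test_that("statistical velocity averages the last three displacements", {
  pts <- data.frame(frame = 0:3, x = c(0, 1, 2, 3), y = 0)
  expect_equal(statistical_velocity(pts), c(1, 0))
  pts2 <- data.frame(frame = 0:2, x = 0, y = c(0, 1, 4))
  expect_equal(statistical_velocity(pts2), c(0, 2))
  # 5-point track: only the last 3 displacements count (windowed-mean oracle)
  pts3 <- data.frame(frame = 0:4, x = c(0, 100, 101, 103, 106), y = 0)
  expect_equal(statistical_velocity(pts3), c(mean(c(1, 2, 3)), 0))
  expect_equal(statistical_velocity(data.frame(frame = 0, x = 5, y = 5)),
               c(0, 0))
  # displacements across a gap are per-frame rates
  pts4 <- data.frame(frame = c(0, 2), x = c(0, 4), y = c(0, 2))
  expect_equal(statistical_velocity(pts4), c(2, 1))
})

test_that("match cost normalizes distance by the gate and weighs brightness", {
  cfg <- tracker_config(gate_radius = 4, brightness_weight = 0.5,
                        brightness_scale = 2)
  s <- track_state(10, 10, 6, cfg)
  expect_equal(match_cost(s, list(x = 10, y = 10, brightness = 6), cfg), 0)
  expect_equal(match_cost(s, list(x = 14, y = 10, brightness = 6), cfg), 1)
  expect_equal(match_cost(s, list(x = 14.01, y = 10, brightness = 6), cfg), Inf)
  expect_equal(match_cost(s, list(x = 10, y = 10, brightness = 8), cfg), 0.5)
})

test_that("brightness weighting flips an otherwise tied assignment", {
  # two predictions equidistant from two detections; brightness disambiguates
  mk <- function(lambda) {
    cfg <- tracker_config(gate_radius = 5, brightness_weight = lambda,
                          brightness_scale = 1)
    s1 <- track_state(0, 0, 10, cfg); s2 <- track_state(2, 0, 2, cfg)
    dets <- data.frame(x = c(1, 1), y = c(0.5, -0.5),
                       brightness = c(2, 10))
    match_frame(list(s1, s2), dets, cfg)$matches
  }
  m0 <- mk(0); m1 <- mk(1)
  # oracle: enumerate both permutations' total costs by hand — with lambda=1
  # track 1 (bright) must take detection 2 (bright)
  expect_equal(unname(m1[m1[, 1] == 1, 2]), 2)
  expect_equal(nrow(m0), 2)  # lambda=0 is indifferent but matches both
})

test_that("frame matching equals the exhaustive-permutation optimum", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(2:4, 1)
    cfg <- tracker_config(gate_radius = 50, brightness_weight = 0.5,
                          brightness_scale = 1)
    states <- lapply(seq_len(n), function(i)
      track_state(runif(1, 0, 20), runif(1, 0, 20), runif(1, 1, 5), cfg))
    dets <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20),
                       brightness = runif(n, 1, 5))
    res <- match_frame(states, dets, cfg)
    C <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      match_cost(states[[i]], dets[j, ], cfg)))
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- min(vapply(perms(seq_len(n)),
                       function(p) sum(C[cbind(seq_len(n), p)]), 1))
    got <- sum(C[res$matches])
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("out-of-gate detections start new tracks instead of matching", {
  cfg <- tracker_config(gate_radius = 3, brightness_scale = 1)
  s <- track_state(0, 0, 5, cfg)
  dets <- data.frame(x = 10, y = 10, brightness = 5)
  res <- match_frame(list(s), dets, cfg)
  expect_equal(nrow(res$matches), 0)
  expect_equal(res$unmatched_tracks, 1L)
  expect_equal(res$unmatched_detections, 1L)
})

test_that("covariance stays symmetric PSD through 1000 predict/update cycles", {
  cfg <- tracker_config(brightness_scale = 1)
  s <- track_state(0, 0, 5, cfg)
  set.seed(3)
  for (i in 1:1000) {
    s <- kalman_predict(s, cfg)
    s <- kalman_update(s, c(s$S[1] + rnorm(1, 0, 0.1),
                            s$S[2] + rnorm(1, 0, 0.1),
                            5 + rnorm(1, 0, 0.5)), cfg)
    if (i %% 100 == 0) {
      expect_equal(s$P, t(s$P))
      expect_gt(min(eigen(s$P, symmetric = TRUE, only.values = TRUE)$values),
                -1e-9)
    }
  }
})

test_that("state estimates converge to truth on noiseless constant velocity", {
  cfg <- tracker_config(brightness_scale = 1)
  s <- track_state(0, 0, 5, cfg)
  err <- NA
  for (k in 1:15) {
    s <- kalman_predict(s, cfg)
    s <- kalman_update(s, c(k * 1.0, k * 0.5, 5), cfg)
    if (k >= 10) expect_lt(abs(s$S[1] - k) + abs(s$S[2] - k * 0.5), 1e-6)
  }
})

test_that("a single noiseless bubble yields one track with its positions", {
  dets <- data.frame(frame = 0:19, x = 10 + (0:19) * 0.8, y = 5 + (0:19) * 0.3,
                     brightness = 7, degenerate = FALSE)
  tr <- track_stack(dets, test_tracker())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)
  expect_equal(tr$x, dets$x, tolerance = 1e-6)
  expect_equal(tr$y, dets$y, tolerance = 1e-6)
})

test_that("a one-frame dropout is bridged into a single track", {
  dets <- data.frame(frame = 0:14, x = 10 + (0:14) * 1.0, y = 20,
                     brightness = 7)
  dets <- dets[dets$frame != 7, ]    # forced detection loss
  tr <- track_stack(dets, test_tracker(max_coast = 1))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(sort(tr$frame), setdiff(0:14, 7))

  tr0 <- track_stack(dets, test_tracker(max_coast = 0))
  expect_equal(length(unique(tr0$track_id)), 2)  # no coasting: split
})

test_that("no detection is assigned to more than one track", {
  ph <- generate_phantom(busy_phantom_config(n_frames = 60))
  filt <- svd_filter(ph$stack, svd_config(2, noise_threshold = 1))
  det <- localize_stack(filt, localization_config(min_peak_intensity = 1.5))
  tr <- track_stack(det, tracker_config())
  key <- paste(tr$frame, round(tr$x, 9), round(tr$y, 9))
  expect_equal(anyDuplicated(key), 0)
  # bookkeeping: every track long enough, frames strictly increasing
  for (id in unique(tr$track_id)) {
    f <- tr$frame[tr$track_id == id]
    expect_true(all(diff(f) >= 1))
    expect_gte(length(f), 5)
  }
})

test_that("with brightness weighting, crossing bubbles of distinct brightness
           are never swapped; without it swaps occur", {
  swaps <- function(lambda, trials = 100) {
    n_swap <- 0
    for (k in seq_len(trials)) {
      set.seed(1000 + k)
      # two bubbles crossing at the midpoint with jitter; distinct brightness
      f <- 0:10
      a <- data.frame(frame = f, x = f * 1.0, y = 5 + rnorm(11, 0, 0.05),
                      brightness = 10 + rnorm(11, 0, 0.2))
      b <- data.frame(frame = f, x = 10 - f * 1.0, y = 5 + rnorm(11, 0, 0.05),
                      brightness = 3 + rnorm(11, 0, 0.2))
      dets <- rbind(a, b)
      tr <- track_stack(dets, test_tracker(gate_radius = 2.5,
                                           brightness_weight = lambda,
                                           brightness_scale = 6))
      for (id in unique(tr$track_id)) {
        br <- tr$brightness[tr$track_id == id]
        if (max(br) - min(br) > 3) n_swap <- n_swap + 1
      }
    }
    n_swap
  }
  expect_equal(swaps(1), 0)
  expect_gt(swaps(0), 0)
})

test_that("vc-Kalman beats the nearest-neighbour baseline on a busy phantom", {
  ph <- generate_phantom(busy_phantom_config(n_frames = 120, seed = 8,
                                             bubble_rate = 0.15))
  filt <- svd_filter(ph$stack, svd_config(2, noise_threshold = 1))
  det <- localize_stack(filt, localization_config(min_peak_intensity = 1.5))
  kal <- track_stack(det, tracker_config(max_cost = 1))
  nn <- track_stack(det, tracker_config(mode = "nn", brightness_weight = 0,
                                        max_coast = 0))
  f_kal <- track_identity_f1(kal, ph$truth$tracks)
  f_nn <- track_identity_f1(nn, ph$truth$tracks)
  expect_gt(f_kal$f1, f_nn$f1)
})
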