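# closed-form oracle: sample a true cosine profile I(u) = cos(a (u - x0))
cosine_profile <- function(a, x0) cos(a * (c(-1, 0, 1) - x0))

test_that("cosine fit inverts a true cosine profile exactly", {
  # hand-checked sample: a = 0.8, x0 = 0.3
  p <- cosine_profile(0.8, 0.3)
  expect_equal(p, c(0.50622, 0.97134, 0.84726), tolerance = 1e-4)
  xi <- cosine_subpixel_offset(p[1], p[2], p[3])
  expect_lt(abs(as.numeric(xi) - 0.3), 1e-6)
  expect_false(attr(xi, "degenerate"))

  # sweep of true offsets and frequencies: exact inversion to 1e-9
  for (a in c(0.5, 0.8, 1.2)) {
    for (x0 in seq(-0.4, 0.4, by = 0.05)) {
      p <- cosine_profile(a, x0)
      expect_lt(abs(as.numeric(cosine_subpixel_offset(p[1], p[2], p[3])) - x0),
                1e-9)
    }
  }
})

test_that("symmetric neighbours give zero offset; degenerate input is flagged", {
  expect_equal(as.numeric(cosine_subpixel_offset(0.5, 1, 0.5)), 0)
  # the printed arccos form does NOT vanish for symmetric input
  expect_gt(abs(as.numeric(cosine_subpixel_offset(0.5, 1, 0.5,
                                                  method = "acos"))), 0.1)
  d <- cosine_subpixel_offset(1, 1, 0.5)    # not a strict peak
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
  d2 <- cosine_subpixel_offset(-0.2, 0.1, -0.3)  # arccos argument < -1
  expect_true(attr(d2, "degenerate"))
})

test_that("peak detection finds blobs and merges near-duplicates", {
  cfg <- localization_config(gaussian_sigma = 1, min_peak_intensity = 1,
                             min_peak_separation = 3)
  expect_equal(nrow(detect_peaks(matrix(0, 32, 32), cfg)), 0)

  img <- make_blob(20, 30, b = 8)
  pk <- detect_peaks(img, cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x, pk$y), c(20, 30))

  # two blobs 1 px apart merge to the brighter one; oracle: exhaustive
  # local-max scan + greedy merge by descending intensity
  img2 <- make_blob(20, 30, b = 8) + make_blob(21, 30, b = 5)
  sm <- img2
  pk2 <- detect_peaks(img2, cfg)
  brute <- list()
  for (r in 2:(nrow(sm) - 1)) for (c in 2:(ncol(sm) - 1)) {
    nb <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (sm[r, c] == max(nb) && sum(nb == max(nb)) == 1 && sm[r, c] >= 1)
      brute[[length(brute) + 1]] <- c(c - 1, r - 1, sm[r, c])
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(-brute[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(brute))
  for (i in seq_len(nrow(brute))) if (keep[i] && i < nrow(brute))
    for (j in (i + 1):nrow(brute))
      if (sum((brute[i, 1:2] - brute[j, 1:2])^2) < 9) keep[j] <- FALSE
  expect_equal(nrow(pk2), sum(keep))
  expect_equal(pk2$x[1], 20)  # the brighter of the pair
})

test_that("subpixel localization recovers blob centers to < 0.1 px", {
  cfg <- localization_config(gaussian_sigma = 1, min_peak_intensity = 1)
  d <- localize_frame(make_blob(20.3, 30.0), cfg)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 20.3), 0.1)
  expect_lt(abs(d$y - 30.0), 0.1)

  d0 <- localize_frame(make_blob(20, 30), cfg)
  expect_equal(d0$x, 20)
  expect_equal(d0$y, 30)
})

test_that("phantom bubbles are localized within 0.2 px at high SNR", {
  cfg <- clean_phantom_config(bubble_rate = 0.04, seed = 9, n_frames = 50)
  cfg$noise_sigma <- 0.05   # SNR ~ 40 dB on brightness 5-10 bubbles
  ph <- generate_phantom(cfg)
  det <- localize_stack(abs(ph$stack),
                        localization_config(min_peak_intensity = 1))
  tr <- ph$truth$tracks
  # interior truth points (full PSF support inside the grid)
  tr <- tr[tr$x > 3 & tr$x < 60 & tr$y > 3 & tr$y < 60, ]
  # keep isolated bubbles only: overlapping PSFs are merged by design
  iso <- vapply(seq_len(nrow(tr)), function(i) {
    s <- tr[tr$frame == tr$frame[i], ]
    d <- sqrt((s$x - tr$x[i])^2 + (s$y - tr$y[i])^2)
    all(d[d > 0] > 6) || length(d) == 1
  }, TRUE)
  tr <- tr[iso, ]
  expect_gt(nrow(tr), 20)
  err <- vapply(seq_len(nrow(tr)), function(i) {
    d <- det[det$frame == tr$frame[i], ]
    if (!nrow(d)) return(NA_real_)
    min(sqrt((d$x - tr$x[i])^2 + (d$y - tr$y[i])^2))
  }, 1)
  expect_lt(stats::quantile(err, 0.9, na.rm = TRUE), 0.2)
})

test_that("integer translation shifts all detections by exactly that amount", {
  cfg <- localization_config(gaussian_sigma = 1, min_peak_intensity = 0.5)
  img <- make_blob(20.3, 24.7, b = 6) + make_blob(40.1, 12.4, b = 9)
  base <- localize_frame(img, cfg)
  shifted <- matrix(0, 64, 64)
  shifted[1:59, 1:57] <- img[6:64, 8:64]    # translate by (-7, -5) in (x, y)
  moved <- localize_frame(shifted, cfg)
  base <- base[order(base$x), ]; moved <- moved[order(moved$x), ]
  expect_equal(moved$x, base$x - 7, tolerance = 1e-9)
  expect_equal(moved$y, base$y - 5, tolerance = 1e-9)
})

test_that("localization error grows with noise", {
  errs <- vapply(c(0.05, 0.5, 1.5), function(ns) {
    set.seed(31)
    e <- replicate(50, {
      x0 <- runif(1, 20, 40); y0 <- runif(1, 20, 40)
      img <- make_blob(x0, y0, b = 8) + matrix(rnorm(64 * 64, 0, ns), 64, 64)
      d <- localize_frame(abs(img), localization_config(min_peak_intensity = 3))
      if (!nrow(d)) return(NA_real_)
      min(sqrt((d$x - x0)^2 + (d$y - y0)^2))
    })
    mean(e, na.rm = TRUE)
  }, 1)
  expect_true(all(diff(errs) > 0))
})
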