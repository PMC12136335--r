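# brute-force NCC oracle: direct double summation, no prefix sums
ncc_brute <- function(ref, target, block, dx, dy) {
  r <- block[1]; c <- block[2]; h <- block[3]; w <- block[4]
  if (r + dy < 1 || c + dx < 1 || r + dy + h - 1 > nrow(target) ||
      c + dx + w - 1 > ncol(target)) return(NA_real_)
  a <- ref[r:(r + h - 1), c:(c + w - 1)]
  b <- target[(r + dy):(r + dy + h - 1), (c + dx):(c + dx + w - 1)]
  num <- 0; ea <- 0; eb <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- num + a[i, j] * b[i, j]
    ea <- ea + a[i, j]^2; eb <- eb + b[i, j]^2
  }
  if (ea == 0 || eb == 0) 0 else num / sqrt(ea * eb)
}

test_that("NCC basics: self-match 1, disjoint support 0, scale invariance", {
  b <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(ncc(b, b), 1)
  s1 <- matrix(c(1, 0, 2, 0), 2); s2 <- matrix(c(0, 3, 0, 4), 2)
  expect_equal(ncc(s1, s2), 0)
  expect_equal(ncc(matrix(c(1, 3, 2, 4), 2), matrix(c(2, 6, 4, 8), 2)), 1)
  expect_equal(ncc(b, b * 17.3), 1, tolerance = 1e-12)
  expect_equal(ncc(matrix(0, 2, 2), b), 0)
})

test_that("prefix-sum rectangle sums equal direct summation", {
  set.seed(12)
  m <- matrix(rnorm(40 * 30), 40, 30)
  P <- prefix_sum2(m)
  for (k in 1:100) {
    r <- sample(40, 1); c <- sample(30, 1)
    h <- sample(40 - r + 1, 1); w <- sample(30 - c + 1, 1)
    direct <- sum(m[r:(r + h - 1), c:(c + w - 1)])
    fast <- P[r + h, c + w] - P[r, c + w] - P[r + h, c] + P[r, c]
    expect_equal(fast, direct, tolerance = 1e-10)
  }
})

test_that("accelerated NCC agrees with the brute-force oracle to 1e-10", {
  set.seed(4)
  shifts <- as.matrix(expand.grid(dx = -3:3, dy = -3:3))
  for (rep in 1:5) {
    ref <- matrix(runif(64 * 64), 64, 64)
    target <- matrix(runif(64 * 64), 64, 64)
    block <- c(sample(10:30, 1), sample(10:30, 1), 16, 16)
    fast <- ncc_fast(ref, target, block, shifts)
    slow <- vapply(seq_len(nrow(shifts)), function(k)
      ncc_brute(ref, target, block, shifts[k, 1], shifts[k, 2]), 1)
    expect_lt(max(abs(fast - slow) / pmax(abs(slow), 1)), 1e-10)
  }
  ones <- matrix(1, 32, 32)
  expect_true(all(ncc_fast(ones, ones, c(8, 8, 8, 8),
                           as.matrix(expand.grid(-2:2, -2:2))) == 1))
})

test_that("parabolic interpolation recovers parabola vertices exactly", {
  expect_equal(as.numeric(parabolic_subpixel_offset(0.5, 1, 0.5)), 0)
  # R(u) = 1 - (u - 0.2)^2 sampled at -1, 0, 1
  expect_equal(as.numeric(parabolic_subpixel_offset(-0.44, 0.96, 0.36)), 0.2,
               tolerance = 1e-15)
  for (v in seq(-0.4, 0.4, by = 0.05)) {
    R <- 1 - (c(-1, 0, 1) - v)^2
    expect_lt(abs(as.numeric(parabolic_subpixel_offset(R[1], R[2], R[3])) - v),
              1e-12)
  }
  flat <- parabolic_subpixel_offset(1, 1, 1)
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("a static stack yields identically zero fields with corr 1", {
  img <- textured_image(64, 64, seed = 2)
  st <- frame_stack(replicate(5, img), frame_rate = 100)
  f <- estimate_displacement_field(st, motion_config(block_size = 16,
                                                     search_range = 3))
  for (fl in f$fields) {
    expect_equal(max(abs(fl$dx)), 0)
    expect_equal(max(abs(fl$dy)), 0)
    expect_equal(min(fl$corr), 1, tolerance = 1e-9)
  }
})

test_that("integer self-shifts are recovered exactly at informative blocks", {
  img <- textured_image(96, 96, seed = 3)
  shifted <- shift_image(img, 3, -2)
  st <- frame_stack(simplify2array(list(img, img, shifted)), frame_rate = 100)
  cfg <- motion_config(block_size = 24, search_range = 4, reference = 1)
  f <- estimate_displacement_field(st, cfg, search = "exhaustive")
  fl <- f$fields[[3]]
  # interior blocks see pure translation (border blocks lose support)
  expect_equal(unname(fl$dx[2:3, 2:3]), matrix(3, 2, 2), tolerance = 1e-9)
  expect_equal(unname(fl$dy[2:3, 2:3]), matrix(-2, 2, 2), tolerance = 1e-9)
})

test_that("subpixel global shifts are recovered with mean error < 0.1 px", {
  img <- textured_image(96, 96, seed = 8)
  set.seed(21)
  errs <- replicate(8, {
    dx <- runif(1, -0.4, 0.4); dy <- runif(1, -0.4, 0.4)
    st <- frame_stack(simplify2array(list(img, img, shift_image(img, dx, dy))),
                      frame_rate = 100)
    f <- estimate_displacement_field(st, motion_config(block_size = 24,
                                                       search_range = 3,
                                                       reference = 1))
    fl <- f$fields[[3]]
    mean(abs(fl$dx[2:3, 2:3] - dx)) + mean(abs(fl$dy[2:3, 2:3] - dy))
  })
  expect_lt(mean(errs) / 2, 0.1)
})

test_that("continuity-seeded search equals exhaustive search on smooth motion", {
  img <- textured_image(96, 96, seed = 5)
  nfr <- 9
  frames <- lapply(0:(nfr - 1), function(t)
    shift_image(img, 2 * sin(2 * pi * t / nfr), 1.2 * cos(2 * pi * t / nfr)))
  st <- frame_stack(frames, frame_rate = 100)
  cfg <- motion_config(block_size = 24, search_range = 4)
  rep <- dp_search_vs_exhaustive(st, cfg)
  expect_gt(rep$n_informative, 50)
  expect_gte(rep$agreement, 0.99)
})

test_that("detection compensation subtracts the interpolated field", {
  img <- textured_image(64, 64, seed = 6)
  st <- frame_stack(replicate(3, img), frame_rate = 100)
  f0 <- estimate_displacement_field(st, motion_config(block_size = 16,
                                                      search_range = 2))
  dets <- data.frame(frame = c(0, 2), x = c(20, 40), y = c(15, 30),
                     brightness = 5)
  out0 <- compensate_detections(dets, f0)
  expect_equal(out0$x, dets$x)       # zero field: identity
  expect_equal(out0$y, dets$y)

  # uniform field (3, -2): all detections move by (-3, +2)
  fu <- f0
  for (i in seq_along(fu$fields)) {
    fu$fields[[i]]$dx[] <- 3
    fu$fields[[i]]$dy[] <- -2
  }
  outu <- compensate_detections(dets, fu)
  expect_equal(outu$x, dets$x - 3)
  expect_equal(outu$y, dets$y + 2)
})

test_that("compensating a rigidly shifted stack is idempotent", {
  img <- textured_image(96, 96, seed = 9)
  nfr <- 7
  frames <- lapply(0:(nfr - 1), function(t)
    shift_image(img, 1.5 * sin(2 * pi * t / nfr), 0.8 * sin(2 * pi * t / nfr)))
  st <- frame_stack(frames, frame_rate = 100)
  cfg <- motion_config(block_size = 24, search_range = 3)
  f <- estimate_displacement_field(st, cfg)
  # re-align each frame by its estimated mean displacement, then re-estimate
  aligned <- lapply(seq_len(nfr), function(i)   # rigid shift: interior blocks
    shift_image(st[, , i], -mean(f$fields[[i]]$dx[2:3, 2:3]),
                -mean(f$fields[[i]]$dy[2:3, 2:3])))
  st2 <- frame_stack(aligned, frame_rate = 100)
  f2 <- estimate_displacement_field(st2, cfg)
  resid <- unlist(lapply(f2$fields, function(fl)
    c(fl$dx[2:3, 2:3], fl$dy[2:3, 2:3])))
  expect_lt(sqrt(mean(resid^2)), 0.05)
})

test_that("rescaling either frame changes no estimate", {
  img <- textured_image(64, 64, seed = 10)
  st <- frame_stack(list(img, img, shift_image(img, 1.3, -0.7) * 5),
                    frame_rate = 100)
  f <- estimate_displacement_field(st, motion_config(block_size = 16,
                                                     search_range = 2,
                                                     reference = 1))
  st2 <- frame_stack(list(img * 0.2, img * 0.2, shift_image(img, 1.3, -0.7)),
                     frame_rate = 100)
  f2 <- estimate_displacement_field(st2, motion_config(block_size = 16,
                                                       search_range = 2,
                                                       reference = 1))
  expect_equal(f$fields[[3]]$dx, f2$fields[[3]]$dx, tolerance = 1e-9)
  expect_equal(f$fields[[3]]$dy, f2$fields[[3]]$dy, tolerance = 1e-9)
})
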