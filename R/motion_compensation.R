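#' Motion-estimation configuration
#'
#' Block-wise normalized cross-correlation (NCC) against a reference frame.
#' The middle frame of the series is the default reference; each other frame
#' is compared to it block by block over integer shifts, and the NCC peak is
#' refined to subpixel precision by parabolic interpolation within its 3x3
#' neighbourhood.
#'
#' @param block_size block edge length in px (>= 8).
#' @param block_stride distance between block origins (default: non-overlapping).
#' @param search_range maximum integer displacement searched, per axis
#'   (1 <= search_range <= block_size / 2).
#' @param reference `"middle"` or a 0-based frame index.
#' @param dp_window half-width of the continuity-seeded local search: each
#'   block's search is centred on the best neighbouring estimate and spans
#'   `+/- dp_window` (the 3x3 candidate window for the default 1).
#' @param zero_mean subtract block means before correlating (robustness
#'   variant; the standard definition used everywhere by default does not).
#' @export
motion_config <- function(block_size = 32L, block_stride = block_size,
                          search_range = 4L, reference = "middle",
                          dp_window = 1L, zero_mean = FALSE) {
  stopifnot(block_size >= 8, search_range >= 1,
            search_range <= block_size / 2, block_stride >= 1, dp_window >= 1)
  structure(list(block_size = as.integer(block_size),
                 block_stride = as.integer(block_stride),
                 search_range = as.integer(search_range),
                 reference = reference,
                 dp_window = as.integer(dp_window),
                 zero_mean = isTRUE(zero_mean)),
            class = "motion_config")
}

#' Normalized cross-correlation of a block at one shift
#'
#' `R_nc = sum(S_r S_d) / sqrt(sum(S_r^2) sum(S_d^2))` over the block window,
#' where the target window is taken from `target_region` displaced by the
#' integer `shift = (dx, dy)` relative to the reference block's position
#' (the region's top-left corresponds to shift (0, 0)). No mean subtraction
#' unless `zero_mean`. Returns 0 if either energy term vanishes; the value
#' is invariant under positive rescaling of either image.
#'
#' @param ref_block reference block matrix.
#' @param target_region target matrix, at least as large as `ref_block`.
#' @param shift integer (dx, dy); the shifted window must lie inside
#'   `target_region`.
#' @param zero_mean subtract means first.
#' @export
ncc <- function(ref_block, target_region, shift = c(0, 0), zero_mean = FALSE) {
  h <- nrow(ref_block); w <- ncol(ref_block)
  dx <- shift[1]; dy <- shift[2]
  if (dy < 0 || dx < 0 || dy + h > nrow(target_region) ||
      dx + w > ncol(target_region))
    stop("shifted target window falls outside the target region")
  tw <- target_region[(dy + 1):(dy + h), (dx + 1):(dx + w), drop = FALSE]
  a <- ref_block; b <- tw
  if (zero_mean) { a <- a - mean(a); b <- b - mean(b) }
  ea <- sum(a^2); eb <- sum(b^2)
  if (ea == 0 || eb == 0) return(0)
  sum(a * b) / sqrt(ea * eb)
}

#' 2D prefix-sum (integral image) table
#'
#' Returns an (nr+1) x (nc+1) table `P` with a zero first row/column such
#' that the sum over any `h x w` window with 1-based top-left `(r, c)` is
#' `P[r+h, c+w] - P[r, c+w] - P[r+h, c] + P[r, c]` — a constant-time
#' rectangle sum used to accelerate the NCC energy terms.
#'
#' @param mat numeric matrix.
#' @export
prefix_sum2 <- function(mat) {
  mat <- as.matrix(mat)
  cs <- apply(mat, 2, cumsum)              # cumulative over rows
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  if (ncol(cs) > 1L)
    for (j in 2:ncol(cs)) cs[, j] <- cs[, j] + cs[, j - 1L]  # then columns
  P <- matrix(0, nrow(mat) + 1L, ncol(mat) + 1L)
  P[-1, -1] <- cs
  P
}

.window_sum <- function(P, r, c, h, w) {
  P[r + h, c + w] - P[r, c + w] - P[r + h, c] + P[r, c]
}

#' Prefix-sum accelerated NCC over candidate shifts
#'
#' Identical values to [ncc()] (to floating-point round-off): the target
#' window energies are read from precomputed integral images of the squared
#' target frame, only the cross term is summed per shift.
#'
#' @param ref reference frame matrix.
#' @param target target frame matrix (same size).
#' @param block integer c(r, c, h, w): 1-based top-left and size of the block
#'   in the reference frame.
#' @param shifts integer matrix (n x 2) of candidate (dx, dy).
#' @param P2 optional precomputed `prefix_sum2(target^2)`.
#' @param zero_mean see [motion_config()]; when TRUE the target-window mean
#'   is also obtained from an integral image of `target`.
#' @param P1 optional precomputed `prefix_sum2(target)` (zero-mean variant).
#' @return numeric vector of R_nc per shift; `NA` where the shifted window
#'   leaves the frame.
#' @export
ncc_fast <- function(ref, target, block, shifts, P2 = NULL, zero_mean = FALSE,
                     P1 = NULL) {
  r <- block[1]; c <- block[2]; h <- block[3]; w <- block[4]
  if (is.null(P2)) P2 <- prefix_sum2(target^2)
  if (zero_mean && is.null(P1)) P1 <- prefix_sum2(target)
  rb <- ref[r:(r + h - 1L), c:(c + w - 1L), drop = FALSE]
  if (zero_mean) rb <- rb - mean(rb)
  e_ref <- sum(rb^2)
  out <- rep(NA_real_, nrow(shifts))
  for (k in seq_len(nrow(shifts))) {
    dx <- shifts[k, 1]; dy <- shifts[k, 2]
    r2 <- r + dy; c2 <- c + dx
    if (r2 < 1L || c2 < 1L || r2 + h - 1L > nrow(target) ||
        c2 + w - 1L > ncol(target)) next
    tw <- target[r2:(r2 + h - 1L), c2:(c2 + w - 1L), drop = FALSE]
    if (zero_mean) {
      mu <- .window_sum(P1, r2, c2, h, w) / (h * w)
      e_t <- .window_sum(P2, r2, c2, h, w) - h * w * mu^2
      cr <- sum(rb * tw)            # rb already zero-mean; cross term unaffected by mu
    } else {
      e_t <- .window_sum(P2, r2, c2, h, w)
      cr <- sum(rb * tw)
    }
    out[k] <- if (e_ref == 0 || e_t <= 0) 0 else cr / sqrt(e_ref * e_t)
  }
  out
}

#' Parabolic subpixel peak offset
#'
#' Vertex of the parabola through `(u, R(u))` at `u = -1, 0, 1`:
#' `xi = (R(-1) - R(1)) / (2 (R(-1) - 2 R(0) + R(1)))`, clamped to
#' [-0.5, 0.5]. Requires `R_0 >= max(R_m1, R_p1)` (pixel-level peak); a flat
#' triple (zero curvature) returns 0 with the `degenerate` attribute set.
#'
#' @param R_m1,R_0,R_p1 correlation samples; vectorized.
#' @export
parabolic_subpixel_offset <- function(R_m1, R_0, R_p1) {
  den <- R_m1 - 2 * R_0 + R_p1
  deg <- den == 0
  den[deg] <- 1
  xi <- (R_m1 - R_p1) / (2 * den)
  xi[deg] <- 0
  xi <- pmin(pmax(xi, -0.5), 0.5)
  attr(xi, "degenerate") <- deg
  xi
}

# evaluate R_nc at one integer shift for one block, NA when out of bounds
.ncc_at <- function(ref, target, block, dx, dy, P2, zero_mean, P1) {
  ncc_fast(ref, target, block, cbind(dx, dy), P2 = P2,
           zero_mean = zero_mean, P1 = P1)[1]
}

#' Estimate per-frame displacement fields against a reference frame
#'
#' For every frame the image is divided into blocks and the integer shift
#' maximizing the NCC with the corresponding reference-frame block is found,
#' then refined per axis by [parabolic_subpixel_offset()] on the 3x3
#' correlation neighbourhood. Two search strategies are available:
#' `"exhaustive"` scans all shifts in `+/- search_range`;
#' `"dp"` (default) exploits the spatial/temporal continuity of tissue
#' motion — blocks are processed in scan order, each search centred on the
#' best already-computed neighbour estimate (left/up block of the same
#' frame, else the same block of the temporally adjacent processed frame,
#' else zero) and restricted to `+/- dp_window` around it, clamped to the
#' overall `search_range`. Frames are processed outward from the reference
#' so a temporal seed always exists.
#'
#' @param stack a [frame_stack()] with >= 3 frames; motion is estimated on
#'   the raw (tissue-bearing) stack, not the clutter-filtered one.
#' @param config a [motion_config()].
#' @param search `"dp"` or `"exhaustive"`.
#' @return object of class `displacement_fields`: list with `reference`
#'   (0-based index), `centers_x`/`centers_y` (block-center coordinate
#'   vectors, 0-based px), and `fields` — one element per frame with
#'   matrices `dx`, `dy` (subpixel px), `corr` (peak R_nc) and `flagged`.
#' @export
estimate_displacement_field <- function(stack, config,
                                        search = c("dp", "exhaustive")) {
  search <- match.arg(search)
  stopifnot(inherits(config, "motion_config"), n_frames(stack) >= 3)
  nf <- n_frames(stack)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  bs <- config$block_size; st <- config$block_stride; sr <- config$search_range
  refi <- if (identical(config$reference, "middle")) nf %/% 2L
          else as.integer(config$reference)
  stopifnot(refi >= 0, refi < nf)
  ref <- stack[, , refi + 1L]
  # inset the grid by the search range so every block can evaluate its full
  # candidate window (flush blocks would see an asymmetric, biased search)
  r0 <- seq(1L + sr, nr - bs + 1L - sr, by = st)
  c0 <- seq(1L + sr, nc - bs + 1L - sr, by = st)
  if (!length(r0)) r0 <- 1L + (nr - bs) %/% 2L
  if (!length(c0)) c0 <- 1L + (nc - bs) %/% 2L
  nby <- length(r0); nbx <- length(c0)
  centers_x <- (c0 - 1) + (bs - 1) / 2
  centers_y <- (r0 - 1) + (bs - 1) / 2
  e_ref <- matrix(0, nby, nbx)
  for (bi in seq_len(nby)) for (bj in seq_len(nbx))
    e_ref[bi, bj] <- sum(ref[r0[bi]:(r0[bi] + bs - 1L), c0[bj]:(c0[bj] + bs - 1L)]^2)

  zero_field <- list(dx = matrix(0, nby, nbx), dy = matrix(0, nby, nbx),
                     corr = matrix(1, nby, nbx),
                     flagged = matrix(FALSE, nby, nbx))
  fields <- vector("list", nf)
  fields[[refi + 1L]] <- zero_field

  order_fwd <- if (refi + 2L <= nf) (refi + 2L):nf else integer(0)
  order_bwd <- if (refi >= 1L) refi:1L else integer(0)

  process <- function(fidx, prev_field) {
    target <- stack[, , fidx]
    P2 <- prefix_sum2(target^2)
    P1 <- if (config$zero_mean) prefix_sum2(target) else NULL
    dxm <- matrix(0, nby, nbx); dym <- matrix(0, nby, nbx)
    dxi <- matrix(0L, nby, nbx); dyi <- matrix(0L, nby, nbx)
    corr <- matrix(0, nby, nbx); flg <- matrix(FALSE, nby, nbx)
    for (bi in seq_len(nby)) for (bj in seq_len(nbx)) {
      block <- c(r0[bi], c0[bj], bs, bs)
      # seed: best already-computed neighbour of this frame, else the same
      # block of the temporally adjacent processed frame, else zero
      seed <- c(0L, 0L)
      if (search == "dp") {
        cand_seed <- list()
        if (bj > 1L) cand_seed$left <- list(d = c(dxi[bi, bj - 1L], dyi[bi, bj - 1L]),
                                            w = corr[bi, bj - 1L])
        if (bi > 1L) cand_seed$up <- list(d = c(dxi[bi - 1L, bj], dyi[bi - 1L, bj]),
                                          w = corr[bi - 1L, bj])
        if (length(cand_seed)) {
          wbest <- which.max(vapply(cand_seed, `[[`, 1, "w"))
          seed <- cand_seed[[wbest]]$d
        } else if (!is.null(prev_field)) {
          seed <- c(round(prev_field$dx[bi, bj]), round(prev_field$dy[bi, bj]))
        }
      }
      if (e_ref[bi, bj] == 0) {
        dxi[bi, bj] <- seed[1]; dyi[bi, bj] <- seed[2]
        dxm[bi, bj] <- seed[1]; dym[bi, bj] <- seed[2]
        corr[bi, bj] <- 0; flg[bi, bj] <- TRUE
        next
      }
      cache <- new.env(parent = emptyenv())
      val <- function(dx, dy) {
        key <- paste0(dx, ",", dy)
        if (!is.null(cache[[key]])) return(cache[[key]])
        v <- .ncc_at(ref, target, block, dx, dy, P2, config$zero_mean, P1)
        cache[[key]] <- v
        v
      }
      if (search == "dp") {
        # hill-climb the 3x3 window from the seed until the peak is interior,
        # bounded by the overall search range
        ctr <- pmin(pmax(seed, -sr), sr)
        best <- NULL
        for (iter in seq_len(2L * sr + 2L)) {
          w <- config$dp_window
          cand <- as.matrix(expand.grid(
            dx = max(-sr, ctr[1] - w):min(sr, ctr[1] + w),
            dy = max(-sr, ctr[2] - w):min(sr, ctr[2] + w)))
          cand <- unique(rbind(cand, c(0L, 0L)))  # zero shift always feasible
          Rc <- vapply(seq_len(nrow(cand)),
                       function(k) val(cand[k, 1], cand[k, 2]), 1)
          if (all(is.na(Rc))) break
          k <- which.max(Rc)
          best <- list(d = cand[k, ], R = Rc[k])
          if (all(cand[k, ] == ctr)) break
          ctr <- cand[k, ]
        }
        if (is.null(best)) {
          dxi[bi, bj] <- seed[1]; dyi[bi, bj] <- seed[2]
          dxm[bi, bj] <- seed[1]; dym[bi, bj] <- seed[2]
          corr[bi, bj] <- 0; flg[bi, bj] <- TRUE
          next
        }
        bx <- best$d[1]; by <- best$d[2]; R0 <- best$R
      } else {
        shifts <- as.matrix(expand.grid(dx = -sr:sr, dy = -sr:sr))
        R <- vapply(seq_len(nrow(shifts)),
                    function(k) val(shifts[k, 1], shifts[k, 2]), 1)
        if (all(is.na(R))) {
          dxi[bi, bj] <- seed[1]; dyi[bi, bj] <- seed[2]
          dxm[bi, bj] <- seed[1]; dym[bi, bj] <- seed[2]
          corr[bi, bj] <- 0; flg[bi, bj] <- TRUE
          next
        }
        k <- which.max(R)
        bx <- shifts[k, 1]; by <- shifts[k, 2]; R0 <- R[k]
      }
      if (R0 >= 1 - 1e-12) {
        # Cauchy-Schwarz equality: the integer shift aligns the block exactly
        xi_x <- 0; xi_y <- 0
      } else {
        Rxm <- val(bx - 1L, by); Rxp <- val(bx + 1L, by)
        Rym <- val(bx, by - 1L); Ryp <- val(bx, by + 1L)
        xi_x <- if (is.na(Rxm) || is.na(Rxp) || R0 < max(Rxm, Rxp)) 0
                else parabolic_subpixel_offset(Rxm, R0, Rxp)[1]
        xi_y <- if (is.na(Rym) || is.na(Ryp) || R0 < max(Rym, Ryp)) 0
                else parabolic_subpixel_offset(Rym, R0, Ryp)[1]
      }
      dxi[bi, bj] <- bx; dyi[bi, bj] <- by
      dxm[bi, bj] <- bx + xi_x; dym[bi, bj] <- by + xi_y
      corr[bi, bj] <- R0
    }
    list(dx = dxm, dy = dym, dx_int = dxi, dy_int = dyi,
         corr = corr, flagged = flg)
  }

  prev <- zero_field
  for (fidx in order_fwd) {
    fields[[fidx]] <- process(fidx, prev)
    prev <- fields[[fidx]]
  }
  prev <- zero_field
  for (fidx in order_bwd) {
    fields[[fidx]] <- process(fidx, prev)
    prev <- fields[[fidx]]
  }

  structure(list(reference = refi, centers_x = centers_x,
                 centers_y = centers_y, config = config,
                 fields = fields),
            class = "displacement_fields")
}

#' Agreement between continuity-seeded and exhaustive NCC search
#'
#' Runs [estimate_displacement_field()] both ways and reports the fraction
#' of informative blocks (nonzero energy, exhaustive peak correlation above
#' `corr_min`) whose integer displacements agree. On smooth motion the
#' seeded local search should match the exhaustive one essentially
#' everywhere; discontinuous motion may produce reported disagreements.
#'
#' @param stack a [frame_stack()].
#' @param config a [motion_config()].
#' @param corr_min informative-block correlation cutoff.
#' @return list with `agreement`, `n_informative`, `n_disagree`.
#' @export
dp_search_vs_exhaustive <- function(stack, config, corr_min = 0.7) {
  fd <- estimate_displacement_field(stack, config, search = "dp")
  fe <- estimate_displacement_field(stack, config, search = "exhaustive")
  n_inf <- 0L; n_dis <- 0L
  for (i in seq_along(fd$fields)) {
    if (i == fd$reference + 1L) next
    a <- fd$fields[[i]]; b <- fe$fields[[i]]
    inf <- !b$flagged & b$corr >= corr_min
    n_inf <- n_inf + sum(inf)
    n_dis <- n_dis + sum(inf & (a$dx_int != b$dx_int | a$dy_int != b$dy_int))
  }
  list(agreement = if (n_inf > 0) 1 - n_dis / n_inf else 1,
       n_informative = n_inf, n_disagree = n_dis)
}

# bilinear interpolation of one displacement grid at query points (0-based px);
# queries outside the block-center hull are clamped to it (nearest-edge block)
.interp_grid <- function(grid, centers_x, centers_y, x, y) {
  cx <- pmin(pmax(x, centers_x[1]), centers_x[length(centers_x)])
  cy <- pmin(pmax(y, centers_y[1]), centers_y[length(centers_y)])
  jx <- findInterval(cx, centers_x, rightmost.closed = TRUE)
  jy <- findInterval(cy, centers_y, rightmost.closed = TRUE)
  jx <- pmin(pmax(jx, 1L), length(centers_x) - 1L)
  jy <- pmin(pmax(jy, 1L), length(centers_y) - 1L)
  if (length(centers_x) == 1L) jx <- rep(1L, length(cx))
  if (length(centers_y) == 1L) jy <- rep(1L, length(cy))
  tx <- if (length(centers_x) > 1L)
    (cx - centers_x[jx]) / (centers_x[jx + 1L] - centers_x[jx]) else 0
  ty <- if (length(centers_y) > 1L)
    (cy - centers_y[jy]) / (centers_y[jy + 1L] - centers_y[jy]) else 0
  jx2 <- pmin(jx + 1L, length(centers_x))
  jy2 <- pmin(jy + 1L, length(centers_y))
  grid[cbind(jy, jx)] * (1 - tx) * (1 - ty) +
    grid[cbind(jy, jx2)] * tx * (1 - ty) +
    grid[cbind(jy2, jx)] * (1 - tx) * ty +
    grid[cbind(jy2, jx2)] * tx * ty
}

#' Align detections to the reference frame
#'
#' Subtracts from each detection the bilinear interpolation of its frame's
#' displacement field at the detection position, producing a
#' position-aligned localization set. Detections outside the block-center
#' hull use the nearest-edge block displacement (clamped interpolation) and
#' are counted in the `n_clamped` attribute. Frames and brightness are
#' unchanged.
#'
#' @param detections data.frame from [localize_stack()].
#' @param fields a `displacement_fields` object covering every detection
#'   frame.
#' @return detections data.frame with compensated `x`, `y`.
#' @export
compensate_detections <- function(detections, fields) {
  stopifnot(inherits(fields, "displacement_fields"))
  if (!nrow(detections)) return(detections)
  out <- detections
  n_clamped <- 0L
  hull_x <- range(fields$centers_x); hull_y <- range(fields$centers_y)
  for (f in unique(detections$frame)) {
    fl <- fields$fields[[f + 1L]]
    if (is.null(fl)) stop("no displacement field for frame ", f)
    i <- detections$frame == f
    x <- detections$x[i]; y <- detections$y[i]
    n_clamped <- n_clamped +
      sum(x < hull_x[1] | x > hull_x[2] | y < hull_y[1] | y > hull_y[2])
    out$x[i] <- x - .interp_grid(fl$dx, fields$centers_x, fields$centers_y, x, y)
    out$y[i] <- y - .interp_grid(fl$dy, fields$centers_x, fields$centers_y, x, y)
  }
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Per-frame mean displacement summary
#'
#' @param fields a `displacement_fields` object.
#' @return data.frame `frame, mean_dx, mean_dy, mean_corr`.
#' @export
displacement_summary <- function(fields) {
  do.call(rbind, lapply(seq_along(fields$fields), function(i) {
    fl <- fields$fields[[i]]
    data.frame(frame = i - 1L, mean_dx = mean(fl$dx), mean_dy = mean(fl$dy),
               mean_corr = mean(fl$corr))
  }))
}
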