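#' Tracker configuration
#'
#' Parameters of the multidimensional Kalman tracker. The state vector is
#' `S = [x, y, I, dx, dy]` (position px, brightness, velocity px/frame) with
#' a constant-velocity, constant-brightness transition model; position and
#' brightness are observed. Matching combines gated Euclidean distance with a
#' brightness-consistency term so that two equidistant candidates are
#' disambiguated by their brightness (`lambda` weighs the brightness term).
#'
#' @param gate_radius maximum plausible inter-frame displacement (px);
#'   candidate detections farther than this from the predicted position are
#'   infeasible.
#' @param brightness_weight lambda >= 0; weight of the normalized brightness
#'   difference in the matching cost.
#' @param brightness_scale normalization of brightness differences; `NULL`
#'   (default) uses the median detection brightness of the processed stack.
#' @param q_pos,q_vel,q_I diagonal process-noise variances (px^2, (px/frame)^2,
#'   intensity^2).
#' @param r_pos,r_I measurement-noise variances for position and brightness.
#' @param init_vel_var prior velocity variance of a newborn track; large, so
#'   the first observed displacement dominates.
#' @param max_cost ceiling on the combined matching cost; candidate pairs
#'   whose cost (gate-normalized distance plus weighted brightness
#'   difference) exceeds it are infeasible even inside the gate. Setting it
#'   to 1 (the cost of a gate-edge match with identical brightness) demands
#'   that a far candidate have consistent brightness and vice versa; the
#'   default `Inf` gates on distance only.
#' @param max_coast consecutive unmatched frames a track may survive
#'   (coasting on its prediction) before termination.
#' @param min_track_length minimum number of detections for a track to be
#'   reported.
#' @param mode `"kalman"` for the full tracker; `"nn"` for the traditional
#'   nearest-neighbour baseline (no prediction, greedy matching, lambda
#'   ignored).
#' @export
tracker_config <- function(gate_radius = 5, brightness_weight = 0.5,
                           brightness_scale = NULL,
                           q_pos = 0.05, q_vel = 0.05, q_I = 0.5,
                           r_pos = 0.01, r_I = 1,
                           init_vel_var = 25, max_cost = Inf,
                           max_coast = 1L, min_track_length = 5L,
                           mode = c("kalman", "nn")) {
  mode <- match.arg(mode)
  stopifnot(gate_radius > 0, brightness_weight >= 0,
            q_pos > 0, q_vel > 0, q_I > 0, r_pos > 0, r_I > 0,
            max_coast >= 0, min_track_length >= 2)
  structure(list(gate_radius = gate_radius,
                 brightness_weight = brightness_weight,
                 brightness_scale = brightness_scale,
                 q_pos = q_pos, q_vel = q_vel, q_I = q_I,
                 r_pos = r_pos, r_I = r_I, init_vel_var = init_vel_var,
                 max_cost = max_cost,
                 max_coast = as.integer(max_coast),
                 min_track_length = as.integer(min_track_length),
                 mode = mode),
            class = "tracker_config")
}

.F5 <- local({
  F <- diag(5); F[1, 4] <- 1; F[2, 5] <- 1; F
})
.H35 <- local({
  H <- matrix(0, 3, 5); H[1, 1] <- 1; H[2, 2] <- 1; H[3, 3] <- 1; H
})

#' Create a Kalman track state
#'
#' @param x,y,I initial position (px) and brightness.
#' @param config a [tracker_config()]; sets the initial covariance (position
#'   and brightness at measurement noise, velocity at `init_vel_var`).
#' @return list with `S` (5-vector `[x, y, I, dx, dy]`), `P` (5x5
#'   covariance), `age`, `misses`.
#' @export
track_state <- function(x, y, I, config) {
  list(S = c(x, y, I, 0, 0),
       P = diag(c(config$r_pos, config$r_pos, config$r_I,
                  config$init_vel_var, config$init_vel_var)),
       age = 1L, misses = 0L)
}

#' Kalman prediction step
#'
#' Advances the state one frame with the constant-velocity transition
#' (`x <- x + dx`, `y <- y + dy`, brightness and velocity unchanged) and
#' grows the covariance: `P <- F P F^T + Q`, Q diagonal from the config.
#'
#' @param state a [track_state()].
#' @param config a [tracker_config()].
#' @export
kalman_predict <- function(state, config) {
  Q <- diag(c(config$q_pos, config$q_pos, config$q_I,
              config$q_vel, config$q_vel))
  state$S <- as.numeric(.F5 %*% state$S)
  P <- .F5 %*% state$P %*% t(.F5) + Q
  state$P <- (P + t(P)) / 2
  state
}

#' Kalman measurement update
#'
#' Fuses a measurement `z = (x, y, I)` into a predicted state:
#' `K = P H^T (H P H^T + R)^{-1}`, `S <- S + K (z - H S)`,
#' `P <- (I - K H) P`, followed by symmetrization. With vanishing gain the
#' estimate equals the prediction; with dominant prior uncertainty it equals
#' the measurement on the observed components.
#'
#' @param state a predicted [track_state()].
#' @param z numeric length-3 measurement (x, y, I).
#' @param config a [tracker_config()].
#' @export
kalman_update <- function(state, z, config) {
  H <- .H35
  R <- diag(c(config$r_pos, config$r_pos, config$r_I))
  Sinn <- H %*% state$P %*% t(H) + R
  K <- state$P %*% t(H) %*% solve(Sinn)
  state$S <- as.numeric(state$S + K %*% (z - H %*% state$S))
  P <- (diag(5) - K %*% H) %*% state$P
  state$P <- (P + t(P)) / 2
  state
}

#' Statistical velocity from recent track history
#'
#' Mean of the up-to-3 most recent observed per-frame displacement vectors
#' (displacements across detection gaps are divided by the frame gap).
#' Used to seed the velocity of young tracks and to re-seed tracks whose
#' prediction failed. A single-point history returns (0, 0).
#'
#' @param points data.frame or matrix with columns `frame`, `x`, `y` in
#'   temporal order.
#' @return numeric (dx, dy) in px/frame.
#' @export
statistical_velocity <- function(points) {
  pts <- as.matrix(points[, c("frame", "x", "y")])
  n <- nrow(pts)
  if (n < 2) return(c(0, 0))
  df <- diff(pts[, 1]); dx <- diff(pts[, 2]) / df; dy <- diff(pts[, 3]) / df
  w <- max(1L, length(dx) - 2L):length(dx)
  c(mean(dx[w]), mean(dy[w]))
}

#' Matching cost between a predicted state and a detection
#'
#' `Inf` (infeasible) when the Euclidean distance `d` between the predicted
#' position and the detection exceeds `gate_radius`; otherwise
#' `d / gate_radius + lambda * |I_pred - I_det| / brightness_scale`.
#'
#' @param state predicted [track_state()].
#' @param det list/row with `x`, `y`, `brightness`.
#' @param config a [tracker_config()] (its `brightness_scale` must be set).
#' @export
match_cost <- function(state, det, config) {
  d <- sqrt((state$S[1] - det$x)^2 + (state$S[2] - det$y)^2)
  if (d > config$gate_radius) return(Inf)
  scale <- if (is.null(config$brightness_scale)) 1 else config$brightness_scale
  cost <- d / config$gate_radius +
    config$brightness_weight * abs(state$S[3] - det$brightness) / scale
  if (cost > config$max_cost) Inf else cost
}

# cost matrix (tracks x detections) with Inf outside the gate
.cost_matrix <- function(states, dets, config) {
  px <- vapply(states, function(s) s$S[1], 1)
  py <- vapply(states, function(s) s$S[2], 1)
  pI <- vapply(states, function(s) s$S[3], 1)
  d <- sqrt(outer(px, dets$x, "-")^2 + outer(py, dets$y, "-")^2)
  scale <- if (is.null(config$brightness_scale)) 1 else config$brightness_scale
  C <- d / config$gate_radius +
    config$brightness_weight * abs(outer(pI, dets$brightness, "-")) / scale
  C[d > config$gate_radius | C > config$max_cost] <- Inf
  C
}

#' Optimal gated one-to-one matching for one frame
#'
#' Solves the minimum-total-cost linear assignment over feasible
#' (within-gate) track/detection pairs, with unmatched options available to
#' every track and detection; the solution maximizes the number of matches
#' and, among those, minimizes total cost. Solved globally (Hungarian method
#' via `clue::solve_LSAP` on an augmented square matrix), not greedily.
#'
#' @param states list of predicted [track_state()]s.
#' @param detections data.frame with `x`, `y`, `brightness`.
#' @param config a [tracker_config()].
#' @return list with `matches` (2-column matrix of track/detection indices),
#'   `unmatched_tracks`, `unmatched_detections` (integer vectors).
#' @export
match_frame <- function(states, detections, config) {
  n <- length(states); m <- nrow(detections)
  if (n == 0L || m == 0L)
    return(list(matches = matrix(integer(), 0, 2),
                unmatched_tracks = seq_len(n),
                unmatched_detections = seq_len(m)))
  C <- .cost_matrix(states, detections, config)
  UNMATCH <- 1e6; BIG <- 1e9
  A <- matrix(BIG, n + m, m + n)
  A[seq_len(n), seq_len(m)] <- ifelse(is.finite(C), C, BIG)
  A[cbind(seq_len(n), m + seq_len(n))] <- UNMATCH
  A[cbind(n + seq_len(m), seq_len(m))] <- UNMATCH
  A[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- clue::solve_LSAP(A)
  mt <- cbind(track = seq_len(n), det = as.integer(sol)[seq_len(n)])
  mt <- mt[mt[, 2] <= m, , drop = FALSE]
  mt <- mt[is.finite(C[mt]), , drop = FALSE]
  list(matches = mt,
       unmatched_tracks = setdiff(seq_len(n), mt[, 1]),
       unmatched_detections = setdiff(seq_len(m), mt[, 2]))
}

# greedy nearest-first matching (traditional baseline)
.match_greedy <- function(states, detections, config) {
  n <- length(states); m <- nrow(detections)
  if (n == 0L || m == 0L)
    return(list(matches = matrix(integer(), 0, 2),
                unmatched_tracks = seq_len(n),
                unmatched_detections = seq_len(m)))
  px <- vapply(states, function(s) s$S[1], 1)
  py <- vapply(states, function(s) s$S[2], 1)
  d <- sqrt(outer(px, detections$x, "-")^2 + outer(py, detections$y, "-")^2)
  feas <- which(d <= config$gate_radius, arr.ind = TRUE)
  mt <- matrix(integer(), 0, 2)
  if (nrow(feas)) {
    feas <- feas[order(d[feas]), , drop = FALSE]
    used_t <- logical(n); used_d <- logical(m)
    for (k in seq_len(nrow(feas))) {
      i <- feas[k, 1]; j <- feas[k, 2]
      if (!used_t[i] && !used_d[j]) {
        mt <- rbind(mt, c(i, j)); used_t[i] <- TRUE; used_d[j] <- TRUE
      }
    }
  }
  list(matches = mt,
       unmatched_tracks = setdiff(seq_len(n), mt[, 1]),
       unmatched_detections = setdiff(seq_len(m), mt[, 2]))
}

#' Track a full detection set into trajectories
#'
#' Runs the frame-by-frame predict / match / update loop over all frames.
#' Matched tracks ("successful predictions") are Kalman-updated with the
#' measurement; tracks left unmatched ("failed predictions") coast on their
#' prediction with velocity re-seeded from [statistical_velocity()] for up
#' to `max_coast` frames, then terminate. Unmatched detections seed new
#' tracks whose velocity is unknown at birth and is seeded from the first
#' observed displacement. In `mode = "nn"` the traditional baseline is run
#' instead: no prediction (gate centred on the last observed position) and
#' greedy nearest-first matching.
#'
#' Track points record the measured detections, so every detection belongs
#' to at most one track; the Kalman state is used for prediction and
#' matching.
#'
#' @param detections data.frame from [localize_stack()] sorted by frame.
#' @param config a [tracker_config()].
#' @return data.frame `track_id, frame, x, y, brightness` containing all
#'   tracks with at least `min_track_length` detections.
#' @export
track_stack <- function(detections, config) {
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), brightness = numeric())
  if (!nrow(detections)) return(empty)
  if (is.null(config$brightness_scale)) {
    config$brightness_scale <- stats::median(detections$brightness)
    if (!is.finite(config$brightness_scale) || config$brightness_scale <= 0)
      config$brightness_scale <- 1
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  by_frame <- split(detections, detections$frame)
  frames <- min(detections$frame):max(detections$frame)
  kal <- config$mode == "kalman"

  live <- list(); done <- list(); next_id <- 1L
  for (f in frames) {
    dets <- by_frame[[as.character(f)]]
    if (is.null(dets)) dets <- detections[0, , drop = FALSE]
    if (kal) for (i in seq_along(live)) live[[i]]$state <- kalman_predict(live[[i]]$state, config)
    states <- lapply(live, `[[`, "state")
    res <- if (kal) match_frame(states, dets, config)
           else .match_greedy(states, dets, config)
    if (nrow(res$matches)) for (k in seq_len(nrow(res$matches))) {
      i <- res$matches[k, 1]; j <- res$matches[k, 2]
      tr <- live[[i]]
      z <- c(dets$x[j], dets$y[j], dets$brightness[j])
      if (kal) {
        tr$state <- kalman_update(tr$state, z, config)
      } else {
        tr$state$S[1:3] <- z
      }
      tr$points <- rbind(tr$points,
                         data.frame(frame = f, x = z[1], y = z[2], brightness = z[3]))
      if (kal && nrow(tr$points) == 2L)
        tr$state$S[4:5] <- statistical_velocity(tr$points)
      tr$state$age <- tr$state$age + 1L
      tr$misses <- 0L
      live[[i]] <- tr
    }
    drop <- integer(0)
    for (i in res$unmatched_tracks) {
      tr <- live[[i]]
      tr$misses <- tr$misses + 1L
      if (tr$misses > config$max_coast) {
        done[[length(done) + 1L]] <- tr
        drop <- c(drop, i)
      } else if (kal) {
        tr$state$S[4:5] <- statistical_velocity(tr$points)
        live[[i]] <- tr
      } else {
        live[[i]] <- tr
      }
    }
    if (length(drop)) live <- live[-drop]
    for (j in res$unmatched_detections) {
      tr <- list(id = next_id,
                 state = track_state(dets$x[j], dets$y[j], dets$brightness[j], config),
                 points = data.frame(frame = f, x = dets$x[j], y = dets$y[j],
                                     brightness = dets$brightness[j]),
                 misses = 0L)
      next_id <- next_id + 1L
      live[[length(live) + 1L]] <- tr
    }
  }
  done <- c(done, live)
  keep <- Filter(function(tr) nrow(tr$points) >= config$min_track_length, done)
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(tr) cbind(track_id = tr$id, tr$points)))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track-to-truth identity F1 score
#'
#' Each estimated point is associated with the spatially nearest
#' ground-truth point of the same frame within `tol` pixels. Estimated and
#' true tracks are then matched one-to-one greedily by shared-point count;
#' precision is the fraction of estimated points inside a matched pair's
#' overlap, recall the corresponding fraction of true points, and F1 their
#' harmonic mean. Fragmented or identity-switching tracks lose overlap and
#' therefore score lower.
#'
#' @param tracks data.frame from [track_stack()].
#' @param true_tracks ground-truth data.frame (`track_id, frame, x, y`).
#' @param tol association tolerance in px.
#' @return list with `f1`, `precision`, `recall`.
#' @export
track_identity_f1 <- function(tracks, true_tracks, tol = 1) {
  if (!nrow(tracks) || !nrow(true_tracks))
    return(list(f1 = 0, precision = 0, recall = 0))
  truth_by_frame <- split(true_tracks, true_tracks$frame)
  tid <- rep(NA_integer_, nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    tf <- truth_by_frame[[as.character(tracks$frame[i])]]
    if (is.null(tf)) next
    d2 <- (tf$x - tracks$x[i])^2 + (tf$y - tracks$y[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol^2) tid[i] <- tf$track_id[j]
  }
  ov <- table(est = tracks$track_id[!is.na(tid)], truth = tid[!is.na(tid)])
  if (!length(ov)) return(list(f1 = 0, precision = 0, recall = 0))
  ovm <- as.data.frame(ov, stringsAsFactors = FALSE)
  ovm <- ovm[ovm$Freq > 0, , drop = FALSE]
  ovm <- ovm[order(-ovm$Freq), , drop = FALSE]
  used_e <- character(0); used_t <- character(0); tp <- 0L
  for (k in seq_len(nrow(ovm))) {
    if (ovm$est[k] %in% used_e || ovm$truth[k] %in% used_t) next
    tp <- tp + ovm$Freq[k]
    used_e <- c(used_e, ovm$est[k]); used_t <- c(used_t, ovm$truth[k])
  }
  prec <- tp / nrow(tracks)
  rec <- tp / nrow(true_tracks)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(f1 = f1, precision = prec, recall = rec)
}

#' Write / read a tracks table as CSV
#' @param tracks data.frame from [track_stack()].
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) utils::read.csv(path)
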