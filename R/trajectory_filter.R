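#' Velocity-difference (VD) coefficient of a trajectory
#'
#' Ratio of the summed step magnitudes to the magnitude of the vector sum of
#' the steps: `VD = sum_i |v_i| / |sum_i v_i|`, with
#' `v_i = p(x_{i+1}, y_{i+1}) - p(x_i, y_i)`. By the triangle inequality
#' `VD >= 1`, with equality exactly for collinear, same-signed steps; erratic
#' paths score high. A vanishing vector sum (perfect back-tracking) yields
#' `+Inf`. The quantity is dimensionless and invariant under translation,
#' rotation and uniform scaling of the trajectory.
#'
#' @param positions n x 2 matrix or data.frame of (x, y), n >= 3.
#' @return scalar VD >= 1 (possibly `Inf`).
#' @export
vd_coefficient <- function(positions) {
  p <- as.matrix(positions)
  if (nrow(p) < 3) stop("VD requires at least 3 positions")
  v <- diff(p)
  num <- sum(sqrt(rowSums(v^2)))
  den <- sqrt(sum(colSums(v)^2))
  if (den == 0) return(Inf)
  num / den
}

#' Reject physically implausible trajectories by the VD constraint
#'
#' Intravascular flow does not twist erratically over a few frames, so the
#' summed step magnitudes of a genuine trajectory should not exceed the
#' magnitude of their vector sum by more than 100%: tracks with
#' `VD > vd_max` (default 2) are discarded as erroneous. With a finite
#' `window` w, the VD is evaluated over every sliding window of w
#' consecutive points and a track is rejected if any window violates the
#' bound; the default evaluates one VD over the full track.
#'
#' @param tracks data.frame from [track_stack()] (tracks with < 3 points are
#'   rejected as unevaluable).
#' @param vd_max acceptance threshold (>= 1).
#' @param window `"full"` or an integer >= 3 window length in points.
#' @return list with `accepted` (subset of `tracks`) and `report`
#'   (data.frame `track_id, vd, accepted`; `vd` is the maximum window VD when
#'   a sliding window is used).
#' @export
filter_tracks <- function(tracks, vd_max = 2, window = "full") {
  ids <- unique(tracks$track_id)
  vd <- numeric(length(ids)); acc <- logical(length(ids))
  for (k in seq_along(ids)) {
    p <- tracks[tracks$track_id == ids[k], c("x", "y")]
    n <- nrow(p)
    if (n < 3) { vd[k] <- NA_real_; acc[k] <- FALSE; next }
    if (identical(window, "full")) {
      vd[k] <- vd_coefficient(p)
    } else {
      w <- as.integer(window)
      stopifnot(w >= 3)
      if (n <= w) {
        vd[k] <- vd_coefficient(p)
      } else {
        vd[k] <- max(vapply(seq_len(n - w + 1L),
                            function(i) vd_coefficient(p[i:(i + w - 1L), ]), 1))
      }
    }
    acc[k] <- is.finite(vd[k]) && vd[k] <= vd_max
  }
  report <- data.frame(track_id = ids, vd = vd, accepted = acc)
  list(accepted = tracks[tracks$track_id %in% ids[acc], , drop = FALSE],
       report = report)
}
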