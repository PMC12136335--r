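#' Read a phantom configuration from YAML
#'
#' The YAML mirrors the [phantom_config()] field names; vessels are a list
#' of maps with `centerline` (list of `[x, y]` pairs), `radius`,
#' `flow_speed`, `direction_sign`.
#'
#' @param path YAML file path.
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  vessels <- lapply(y[["vessels"]] %||% list(), function(v) {
    vessel_spec(centerline = do.call(rbind, v$centerline),
                radius = v$radius, flow_speed = v$flow_speed,
                direction_sign = v$direction_sign %||% 1)
  })
  y[["vessels"]] <- NULL
  y[["schema_version"]] <- NULL
  args <- y[names(y) %in% names(formals(phantom_config))]
  do.call(phantom_config, c(args, list(vessels = vessels)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sub_config <- function(y, fun) {
  if (is.null(y)) return(fun())
  do.call(fun, y[names(y) %in% names(formals(fun))])
}

#' Read a pipeline configuration from YAML
#'
#' Nested blocks `svd`, `localization`, `tracker`, `motion` mirror the
#' corresponding config constructors; missing fields take the package
#' defaults. Note that bare YAML `off` parses as logical false, so
#' `motion_comp` accepts both `FALSE` (meaning `"off"`) and the quoted
#' strings `"off"`, `"pre"`, `"post"`.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- y[["motion_comp"]] %||% "off"
  if (isFALSE(mc)) mc <- "off"
  svd <- if (isFALSE(y[["svd"]])) NULL else .sub_config(y[["svd"]], svd_config)
  pipeline_config(
    svd = svd,
    localization = .sub_config(y[["localization"]], localization_config),
    tracker = .sub_config(y[["tracker"]], tracker_config),
    motion = .sub_config(y[["motion"]], motion_config),
    vd = y[["vd"]] %||% TRUE,
    vd_max = y[["vd_max"]] %||% 2,
    vd_window = y[["vd_window"]] %||% "full",
    motion_comp = mc,
    sr_factor = y[["sr_factor"]] %||% 8L,
    seed = y[["seed"]] %||% 1L)
}

#' Write phantom ground truth to CSV files
#'
#' Writes `true_tracks.csv` (track_id, frame, x, y, brightness) and
#' `true_motion.csv` (frame, dx, dy) into `dir`.
#'
#' @param truth the `truth` element of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @export
write_ground_truth_csv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$tracks, file.path(dir, "true_tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$displacements, file.path(dir, "true_motion.csv"),
                   row.names = FALSE)
  invisible(dir)
}
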