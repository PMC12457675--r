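# Track tables, configuration files and run reports.

#' Write a track set to CSV
#'
#' Writes the point table (one row per detection: track, frame, x, y) to
#' `path` and the per-track metric summary (pixel/frame and um/min twins)
#' to `*_summary.csv` alongside.
#'
#' @param tracks An `aw_tracks`.
#' @param path Output CSV path for the point table.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  stopifnot(inherits(tracks, "aw_tracks"))
  utils::write.csv(as.data.frame(tracks)[, c("track", "frame", "x", "y")],
                   path, row.names = FALSE)
  summary_path <- sub("\\.csv$", "_summary.csv", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, "_summary.csv")
  m <- if (nrow(tracks)) track_metrics(tracks) else
    track_metrics(as_tracks(data.frame(track = integer(), frame = integer(),
                                       x = numeric(), y = numeric()),
                            attr(tracks, "calibration")))
  utils::write.csv(m, summary_path, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_track_table()]
#'
#' @param path Point-table CSV path.
#' @param calibration An [calibration()].
#' @param n_frames Optional total frame count to attach.
#' @return An `aw_tracks`.
#' @export
read_track_table <- function(path, calibration = actinwaves::calibration(),
                             n_frames = NA_integer_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("track", "frame", "x", "y") %in% names(df)))
  df <- df[order(df$track, df$frame), c("track", "frame", "x", "y")]
  rownames(df) <- NULL
  df$track <- as.integer(df$track); df$frame <- as.integer(df$frame)
  as_tracks(df, calibration, list(), n_frames)
}

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline, one namespace per stage, with the
#' published acquisition values as defaults (0.36 um/px, 2 s/frame; flow
#' sigma 2 px, reliability 0.1; coherence 11 x 11 / sigma 5; peaks diameter
#' 5 / separation 15; linking range 5 / memory 1; filters >= 8 frames and
#' > 0.5 px/frame; recurrence 1 min / 10 um / >= 5 tracks).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    calibration = list(pixel_size = 0.36, frame_interval = 2),
    preprocess = list(window = 5, sigma = 1, max_shift = 16),
    flow = list(weight_sigma = 2, reliability_threshold = 0.1),
    coherence = list(window = 11, sigma = 5),
    peaks = list(diameter = 5, min_separation = 15, min_score = 0.25,
                 smooth_sigma = 2.5),
    linking = list(search_range = 5, memory = 1),
    filter = list(min_frames = 8, min_avg_inst_speed = 0.5),
    recurrence = list(window_min = 1, radius_um = 10, min_tracks = 5),
    mask = list(tophat_radius = 15, threshold_block = 51, threshold_offset = 0,
                n_open_iter = 2, n_components = 1, contrast_threshold = 0.05),
    orientation = list(n_angles = 36, log_sigma = 2, elongation = 3),
    alignment = list(n_bins = 20, max_dist = 10),
    simulate = list(n_frames = 150, frame_shape = c(256, 256),
                    rate_per_min_per_process = 2, speed_um_min = 21,
                    speed_cv = 0.3, lifetime_s_mean = 30, reversal_prob = 0.05,
                    hotspot_recurrence_p = 0.5, background = 100,
                    neurite_intensity = 50, noise_sd = 5, bleach_rate = 0.002,
                    jitter_sd_px = 0.5)
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file; keys mirror [default_config()]. Missing keys keep
#'   their defaults.
#' @return Nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (ns in names(user)) {
    if (!is.list(user[[ns]])) { cfg[[ns]] <- user[[ns]]; next }
    for (k in names(user[[ns]])) cfg[[ns]][[k]] <- user[[ns]][[k]]
  }
  cfg
}
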