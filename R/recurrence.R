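# Spatial recurrence of track start positions across successive time
# windows: how consistently new waves are born where waves were recently
# born.

#' Spatial recurrence of track starts
#'
#' The movie is partitioned into non-overlapping windows of `window` frames
#' (a trailing partial window is discarded); each track belongs to the
#' window containing its first detection. For every adjacent window pair in
#' which both windows hold at least `min_tracks` new tracks, the recurrence
#' fraction is the share of win2 starts lying within `radius` (inclusive) of
#' any win1 start. The mean and SEM (SD of the fractions over the number of
#' valid pairs) aggregate the pairs.
#'
#' @param tracks An `aw_tracks` (normally filtered).
#' @param window Window length, frames (default 1 min at the track set's
#'   calibration).
#' @param radius Search radius, px (default 10 um at the calibration).
#' @param min_tracks Minimum new tracks per window for a pair to count.
#' @param total_frames Number of frames in the movie; defaults to the
#'   track set's `n_frames` attribute.
#' @return An `aw_recurrence` list: `pair_fractions`, `mean`, `sem`,
#'   `n_valid_pairs`, `window`, `radius`; `mean` is NA when no pair is valid.
#' @export
recurrence <- function(tracks, window = NULL, radius = NULL, min_tracks = 5,
                       total_frames = NULL) {
  stopifnot(inherits(tracks, "aw_tracks"))
  cal <- attr(tracks, "calibration")
  if (is.null(window)) window <- max(1L, round(60 / cal$frame_interval))
  if (is.null(radius)) radius <- 10 / cal$pixel_size
  stopifnot(window >= 1, radius >= 0, min_tracks >= 1)
  if (is.null(total_frames)) total_frames <- attr(tracks, "n_frames")
  if (is.null(total_frames) || is.na(total_frames))
    total_frames <- if (nrow(tracks)) max(tracks$frame) else 0L
  n_win <- floor(total_frames / window)
  starts <- if (nrow(tracks)) {
    m <- track_metrics(tracks)
    first <- vapply(split(tracks$frame, tracks$track), min, numeric(1))
    data.frame(x = m$start_x, y = m$start_y,
               win = floor((first[as.character(m$track)] - 1) / window) + 1)
  } else data.frame(x = numeric(), y = numeric(), win = numeric())
  fr <- numeric(0)
  if (n_win >= 2) {
    for (w in seq_len(n_win - 1)) {
      s1 <- starts[starts$win == w, , drop = FALSE]
      s2 <- starts[starts$win == w + 1, , drop = FALSE]
      if (nrow(s1) < min_tracks || nrow(s2) < min_tracks) next
      rec <- vapply(seq_len(nrow(s2)), function(i)
        min(sqrt((s1$x - s2$x[i])^2 + (s1$y - s2$y[i])^2)) <= radius,
        logical(1))
      fr <- c(fr, mean(rec))
    }
  }
  structure(list(pair_fractions = fr,
                 mean = if (length(fr)) mean(fr) else NA_real_,
                 sem = if (length(fr) > 1) stats::sd(fr) / sqrt(length(fr))
                       else if (length(fr) == 1) 0 else NA_real_,
                 n_valid_pairs = length(fr),
                 window = window, radius = radius, min_tracks = min_tracks),
            class = "aw_recurrence")
}

#' @export
print.aw_recurrence <- function(x, ...) {
  cat(sprintf("recurrence: mean %.3f +/- %.3f SEM over %d window pair(s) (window %d frames, radius %.1f px)\n",
              x$mean, x$sem, x$n_valid_pairs, x$window, x$radius))
  invisible(x)
}

#' Recurrence over a grid of radii and window lengths
#'
#' @param tracks An `aw_tracks`.
#' @param radii Radii to evaluate, px.
#' @param windows Window lengths to evaluate, frames.
#' @param ... Passed to [recurrence()].
#' @return data.frame with one row per (radius, window): `radius`, `window`,
#'   `mean`, `sem`, `n_valid_pairs`.
#' @export
recurrence_sweep <- function(tracks, radii, windows, ...) {
  grid <- expand.grid(radius = radii, window = windows)
  res <- lapply(seq_len(nrow(grid)), function(i)
    recurrence(tracks, window = grid$window[i], radius = grid$radius[i], ...))
  data.frame(radius = grid$radius, window = grid$window,
             mean = vapply(res, function(r) r$mean, numeric(1)),
             sem = vapply(res, function(r) r$sem, numeric(1)),
             n_valid_pairs = vapply(res, function(r) r$n_valid_pairs,
                                    numeric(1)))
}
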