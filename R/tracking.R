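# Coherence clustering of flow fields, peak detection, frame-to-frame
# linking and track metrics.

#' Local flow-coherence map
#'
#' For each valid pixel, the dot product of its flow vector with the
#' Gaussian-weighted mean flow of its neighbourhood (default 11 x 11 window,
#' sigma = 5 px ~ 1.8 um); invalid neighbours are excluded and the weights
#' renormalised. For a spatially uniform field `v` the interior score is
#' `|v|^2`; locally aligned motion scores high, antagonistic motion negative.
#'
#' Clustering is spatiotemporal: for a flow-field sequence the score stack
#' is additionally smoothed along time with a short NA-aware Gaussian
#' (default 3 frames, sigma 1), so a wave is a coherent object in space and
#' time rather than in single frame pairs.
#'
#' @param flow An `aw_flow` (one pair) or `aw_flow_movie`.
#' @param window Neighbourhood side, px (odd).
#' @param sigma Gaussian weight sigma, px.
#' @param temporal_window Odd temporal support in frame pairs (movie input
#'   only); 1 disables temporal smoothing.
#' @param temporal_sigma Temporal Gaussian sigma, frames.
#' @return Matrix (or `H x W x (T-1)` array) of scores, NA where flow is
#'   invalid or has no valid neighbour.
#' @export
coherence_map <- function(flow, window = 11, sigma = 5, temporal_window = 3,
                          temporal_sigma = 1) {
  stopifnot(window %% 2 == 1, sigma > 0, temporal_window %% 2 == 1)
  k <- EBImage::makeBrush(window, shape = "gaussian", sigma = sigma)
  k <- k / sum(k)
  one_pair <- function(u, v, valid) {
    u0 <- ifelse(valid, u, 0); v0 <- ifelse(valid, v, 0)
    wsum <- conv2(valid * 1, k)
    ubar <- conv2(u0, k) / wsum
    vbar <- conv2(v0, k) / wsum
    score <- u * ubar + v * vbar
    score[!valid | wsum <= 0] <- NA_real_
    score
  }
  if (inherits(flow, "aw_flow"))
    return(one_pair(flow$u, flow$v, flow$valid))
  stopifnot(inherits(flow, "aw_flow_movie"))
  d <- dim(flow$u)
  out <- array(NA_real_, d)
  for (t in seq_len(d[3]))
    out[, , t] <- one_pair(flow$u[, , t], flow$v[, , t], flow$valid[, , t])
  if (temporal_window > 1 && d[3] > 1) {
    h <- (temporal_window - 1) / 2
    w <- exp(-(-h:h)^2 / (2 * temporal_sigma^2))
    sm <- array(NA_real_, d)
    for (t in seq_len(d[3])) {
      acc <- 0; wacc <- 0
      for (k in -h:h) {
        tk <- t + k
        if (tk < 1 || tk > d[3]) next
        m <- out[, , tk]; fin <- is.finite(m); m[!fin] <- 0
        acc <- acc + w[k + h + 1] * m
        wacc <- wacc + w[k + h + 1] * fin
      }
      m <- acc / pmax(wacc, 1e-9)
      m[wacc < 1e-9] <- NA_real_
      sm[, , t] <- m
    }
    out <- sm
  }
  out
}

#' Detect coherence peaks in one score map
#'
#' Local maxima at the blob scale (`diameter`), thresholded at `min_score`,
#' then greedily pruned so no two retained peaks are closer than
#' `min_separation` (higher score wins; ties by scan order). Positions are
#' refined to sub-pixel precision by the positive-score centroid within the
#' diameter window.
#'
#' @param score Matrix of coherence scores (NA = undefined).
#' @param diameter Approximate blob diameter, px.
#' @param min_separation Minimum distance between retained peaks, px.
#' @param min_score Absolute score threshold. The default 0.25 (px/frame)^2
#'   is the square of the 0.5 px/frame track speed floor: a coherence peak
#'   below it corresponds to motion the downstream filter discards as
#'   static anyway.
#' @param smooth_sigma Gaussian sigma for pre-smoothing the score map at the
#'   blob scale (default `diameter / 2`); 0 disables. Stabilises the maximum
#'   of plateau-like coherence bumps.
#' @return data.frame with columns `x`, `y` (sub-pixel), `score`.
#' @export
detect_peaks <- function(score, diameter = 5, min_separation = 15,
                         min_score = 0.25, smooth_sigma = NULL) {
  stopifnot(is.matrix(score))
  if (is.null(smooth_sigma)) smooth_sigma <- diameter / 2
  ok <- is.finite(score)
  if (!any(ok)) return(data.frame(x = numeric(), y = numeric(), score = numeric()))
  if (smooth_sigma > 0) {
    k <- gaussian_brush(smooth_sigma)
    w <- conv2(ok * 1, k)
    sm <- conv2(ifelse(ok, score, 0), k) / pmax(w, 1e-9)
    sm[!ok] <- NA_real_
    score <- sm
  }
  low <- min(score[ok]) - 1
  s <- score; s[!ok] <- low
  mx <- EBImage::dilate(s - low, EBImage::makeBrush(diameter, "box")) + low
  cand <- which(ok & s >= mx - 1e-12 & s >= min_score, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(), y = numeric(), score = numeric()))
  sc <- s[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  keep <- logical(nrow(cand))
  kept_xy <- matrix(0, 0, 2)
  for (i in seq_len(nrow(cand))) {
    xy <- c(cand[i, 2], cand[i, 1])
    if (nrow(kept_xy) == 0 ||
        min(sqrt((kept_xy[, 1] - xy[1])^2 + (kept_xy[, 2] - xy[2])^2)) >=
        min_separation) {
      keep[i] <- TRUE
      kept_xy <- rbind(kept_xy, xy)
    }
  }
  cand <- cand[keep, , drop = FALSE]; sc <- sc[keep]
  # sub-pixel refinement: centroid of positive scores in the diameter
  # window, recentred iteratively (a la trackpy) to undo the integer-grid
  # quantisation of the maximum
  h <- floor(diameter / 2)
  H <- nrow(score); W <- ncol(score)
  res <- matrix(0, nrow(cand), 2)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    for (iter in 1:3) {
      ys <- max(1, round(r) - h):min(H, round(r) + h)
      xs <- max(1, round(c) - h):min(W, round(c) + h)
      wgt <- score[ys, xs, drop = FALSE]
      wgt[!is.finite(wgt) | wgt < 0] <- 0
      tot <- sum(wgt)
      if (tot == 0) break
      cx <- sum(rep(xs, each = length(ys)) * wgt) / tot
      cy <- sum(rep(ys, times = length(xs)) * wgt) / tot
      done <- abs(cx - c) < 0.01 && abs(cy - r) < 0.01
      c <- cx; r <- cy
      if (done) break
    }
    res[i, ] <- c(c, r)
  }
  data.frame(x = res[, 1], y = res[, 2], score = sc)
}

#' Detect wave positions in every frame pair of a coherence stack
#'
#' @param coherence Array `H x W x (T-1)` from [coherence_map()].
#' @param ... Passed to [detect_peaks()].
#' @return data.frame with columns `frame` (index of the first frame of the
#'   pair), `x`, `y`, `score`.
#' @export
detect_peaks_movie <- function(coherence, ...) {
  stopifnot(is.array(coherence), length(dim(coherence)) == 3L)
  out <- lapply(seq_len(dim(coherence)[3]), function(t) {
    p <- detect_peaks(coherence[, , t], ...)
    if (nrow(p)) cbind(frame = t, p) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(frame = integer(), x = numeric(),
                                      y = numeric(), score = numeric())
  out
}

# ---- optimal assignment ---------------------------------------------------

# O(n^3) Hungarian algorithm (Kuhn-Munkres with potentials) for a square
# finite cost matrix; returns col assigned to each row.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0) return(integer(0))
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1)        # p[jj]: row matched to column jj-1 (jj=1 virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(Inf, n + 1); used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (jj in 2:(n + 1)) {
        if (used[jj]) next
        cur <- cost[i0, jj - 1] - u[i0] - v[jj]
        if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
        if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
      }
      for (jj in seq_len(n + 1)) {
        if (used[jj]) {
          if (p[jj] > 0) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else minv[jj] <- minv[jj] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (jj in 2:(n + 1)) assignment[p[jj]] <- jj - 1L
  assignment
}

# one frame-pair linking step: rows = track ends, cols = detections.
# Objective: minimise sum of link distances + search_range per unlinked
# endpoint; links beyond search_range forbidden. Returns for each detection
# the matched track row index (0 = start new track).
link_step <- function(track_xy, det_xy, search_range) {
  nt <- nrow(track_xy); nd <- nrow(det_xy)
  if (nd == 0) return(integer(0))
  if (nt == 0) return(integer(nd))
  BIG <- 1e9
  D <- sqrt(outer(track_xy[, 1], det_xy[, 1], "-")^2 +
            outer(track_xy[, 2], det_xy[, 2], "-")^2)
  D[D > search_range] <- BIG
  n <- nt + nd
  C <- matrix(BIG, n, n)
  C[seq_len(nt), seq_len(nd)] <- D
  for (i in seq_len(nt)) C[i, nd + i] <- search_range       # track unlinked
  for (j in seq_len(nd)) C[nt + j, j] <- search_range       # detection unlinked
  C[nt + seq_len(nd), nd + seq_len(nt)] <- 0
  a <- hungarian(C)
  match_det <- integer(nd)
  for (i in seq_len(nt)) {
    j <- a[i]
    if (j <= nd && D[i, j] <= search_range) match_det[j] <- i
  }
  match_det
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment minimising the total linking distance, with
#' per-link distances capped at `search_range`; a track that misses a
#' detection for up to `memory` frames may reclaim one afterwards. Unmatched
#' detections start new tracks. The per-frame assignment is globally
#' cost-minimising (Hungarian algorithm), so the result is invariant to
#' detection order within a frame.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`.
#' @param search_range Maximum link distance, px.
#' @param memory Frames a track may go undetected and still be continued.
#' @param calibration Attached to the result for unit conversions.
#' @return An `aw_tracks` data.frame with columns `track`, `frame`, `x`, `y`,
#'   ordered by track then frame. Attributes: `calibration`, `params`,
#'   `n_frames`.
#' @export
link_tracks <- function(detections, search_range = 5, memory = 1,
                        calibration = actinwaves::calibration()) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)),
            search_range > 0, memory >= 0)
  det <- detections[order(detections$frame), , drop = FALSE]
  if (nrow(det) == 0) {
    out <- data.frame(track = integer(), frame = integer(),
                      x = numeric(), y = numeric())
    return(as_tracks(out, calibration, list(search_range = search_range,
                                            memory = memory), 0L))
  }
  frames_rng <- seq(min(det$frame), max(det$frame))
  # active track state
  ids <- integer(0); last_f <- integer(0)
  last_x <- numeric(0); last_y <- numeric(0)
  pts <- list()
  next_id <- 1L
  for (f in frames_rng) {
    d <- det[det$frame == f, , drop = FALSE]
    if (nrow(d) == 0) next
    cand <- which(f - last_f <= memory + 1L)
    cand <- cand[order(ids[cand])]
    m <- link_step(cbind(last_x[cand], last_y[cand]),
                   cbind(d$x, d$y), search_range)
    for (j in seq_len(nrow(d))) {
      if (length(m) >= j && m[j] > 0) {
        tr <- cand[m[j]]
      } else {
        ids <- c(ids, next_id); last_f <- c(last_f, 0L)
        last_x <- c(last_x, 0); last_y <- c(last_y, 0)
        pts[[next_id]] <- list()
        tr <- length(ids)
        next_id <- next_id + 1L
      }
      last_f[tr] <- f; last_x[tr] <- d$x[j]; last_y[tr] <- d$y[j]
      pts[[ids[tr]]] <- c(pts[[ids[tr]]], list(c(f, d$x[j], d$y[j])))
    }
  }
  rows <- lapply(seq_along(pts), function(id) {
    m <- do.call(rbind, pts[[id]])
    data.frame(track = id, frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$track, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  as_tracks(out, calibration,
            list(search_range = search_range, memory = memory),
            max(det$frame))
}

as_tracks <- function(df, calibration, params = list(), n_frames = NA_integer_) {
  structure(df, class = c("aw_tracks", "data.frame"),
            calibration = calibration, params = params,
            n_frames = as.integer(n_frames))
}

#' Per-step displacement table of a track set
#'
#' One row per inter-detection step: displacement, frame gap, instantaneous
#' speed (displacement per frame of gap) and movement angle in degrees
#' (`atan2(dy, dx)`, y = row axis).
#'
#' @param tracks An `aw_tracks`.
#' @return data.frame `track`, `frame0`, `frame1`, `dx`, `dy`, `dist`, `gap`,
#'   `speed`, `angle`.
#' @export
track_steps <- function(tracks) {
  stopifnot(inherits(tracks, "aw_tracks"))
  if (nrow(tracks) == 0)
    return(data.frame(track = integer(), frame0 = integer(), frame1 = integer(),
                      x0 = numeric(), y0 = numeric(),
                      dx = numeric(), dy = numeric(), dist = numeric(),
                      gap = integer(), speed = numeric(), angle = numeric()))
  sp <- split(seq_len(nrow(tracks)), tracks$track)
  out <- lapply(sp, function(idx) {
    if (length(idx) < 2) return(NULL)
    tt <- tracks[idx, ]
    n <- nrow(tt)
    dx <- diff(tt$x); dy <- diff(tt$y); gap <- diff(tt$frame)
    dist <- sqrt(dx^2 + dy^2)
    data.frame(track = tt$track[1], frame0 = tt$frame[-n], frame1 = tt$frame[-1],
               x0 = tt$x[-n], y0 = tt$y[-n],
               dx = dx, dy = dy, dist = dist, gap = gap, speed = dist / gap,
               angle = atan2(dy, dx) * 180 / pi)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(track = integer(), frame0 = integer(),
                                      frame1 = integer(), x0 = numeric(),
                                      y0 = numeric(), dx = numeric(),
                                      dy = numeric(), dist = numeric(),
                                      gap = integer(), speed = numeric(),
                                      angle = numeric())
  rownames(out) <- NULL
  out
}

#' Per-track summary metrics
#'
#' For each track with >= 2 detections: total path length (sum of
#' displacements), duration in frames (`last - first + 1`; the companion
#' `duration_intervals = duration_frames - 1` is what converts to seconds),
#' net start-to-end displacement, average speed (total length / duration in
#' frames), net velocity, sinuosity (total / net; NA when the net
#' displacement is zero) and average instantaneous speed (mean per-step
#' displacement per frame of gap). Physical-unit twins are derived with the
#' track set's calibration. Single-point tracks yield NA metrics.
#'
#' @param tracks An `aw_tracks`.
#' @return data.frame, one row per track.
#' @export
track_metrics <- function(tracks) {
  stopifnot(inherits(tracks, "aw_tracks"))
  cal <- attr(tracks, "calibration")
  if (nrow(tracks) == 0) {
    out <- data.frame(track = integer(), n_points = integer(),
                      duration_frames = integer(), duration_intervals = integer(),
                      total_length = numeric(), net_displacement = numeric(),
                      avg_speed = numeric(), net_velocity = numeric(),
                      sinuosity = numeric(), avg_inst_speed = numeric(),
                      start_x = numeric(), start_y = numeric())
    if (!is.null(cal))
      for (cn in c("total_length_um", "net_displacement_um", "avg_speed_um_min",
                   "net_velocity_um_min", "avg_inst_speed_um_min", "duration_s"))
        out[[cn]] <- numeric(0)
    return(out)
  }
  sp <- split(seq_len(nrow(tracks)), tracks$track)
  rows <- lapply(sp, function(idx) {
    tt <- tracks[idx, ]
    n <- nrow(tt)
    if (n < 2) {
      return(data.frame(track = tt$track[1], n_points = n,
                        duration_frames = 1L, duration_intervals = 0L,
                        total_length = NA_real_, net_displacement = NA_real_,
                        avg_speed = NA_real_, net_velocity = NA_real_,
                        sinuosity = NA_real_, avg_inst_speed = NA_real_,
                        start_x = tt$x[1], start_y = tt$y[1]))
    }
    dx <- diff(tt$x); dy <- diff(tt$y); gap <- diff(tt$frame)
    dist <- sqrt(dx^2 + dy^2)
    total <- sum(dist)
    dur <- tt$frame[n] - tt$frame[1] + 1L
    net <- sqrt((tt$x[n] - tt$x[1])^2 + (tt$y[n] - tt$y[1])^2)
    data.frame(track = tt$track[1], n_points = n,
               duration_frames = dur, duration_intervals = dur - 1L,
               total_length = total, net_displacement = net,
               avg_speed = total / dur, net_velocity = net / dur,
               sinuosity = if (net > 0) total / net else NA_real_,
               avg_inst_speed = mean(dist / gap),
               start_x = tt$x[1], start_y = tt$y[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cal) && nrow(out)) {
    out$total_length_um <- convert_length(out$total_length, cal)
    out$net_displacement_um <- convert_length(out$net_displacement, cal)
    out$avg_speed_um_min <- convert_speed(out$avg_speed, cal)
    out$net_velocity_um_min <- convert_speed(out$net_velocity, cal)
    out$avg_inst_speed_um_min <- convert_speed(out$avg_inst_speed, cal)
    out$duration_s <- out$duration_intervals * cal$frame_interval
  }
  out
}

#' Filter tracks by persistence and speed
#'
#' Keeps tracks spanning at least `min_frames` frames (8 frames = 14 s at
#' 2 s/frame) with average instantaneous speed strictly greater than
#' `min_avg_inst_speed` (0.5 px/frame = 5.4 um/min), excluding transient and
#' static clusters.
#'
#' @param tracks An `aw_tracks`.
#' @param min_frames Minimum `duration_frames`.
#' @param min_avg_inst_speed Exclusive lower bound on avg instantaneous
#'   speed, px/frame.
#' @return The filtered `aw_tracks` (attributes preserved).
#' @export
filter_tracks <- function(tracks, min_frames = 8, min_avg_inst_speed = 0.5) {
  stopifnot(inherits(tracks, "aw_tracks"))
  if (nrow(tracks) == 0) return(tracks)
  m <- track_metrics(tracks)
  keep <- m$track[!is.na(m$avg_inst_speed) &
                  m$duration_frames >= min_frames &
                  m$avg_inst_speed > min_avg_inst_speed]
  out <- tracks[tracks$track %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  as_tracks(out, attr(tracks, "calibration"),
            c(attr(tracks, "params"),
              list(min_frames = min_frames,
                   min_avg_inst_speed = min_avg_inst_speed)),
            attr(tracks, "n_frames"))
}

#' Track a movie end to end
#'
#' Convenience pipeline: preprocess (register, bleach-correct, smooth),
#' Lucas-Kanade flow, coherence clustering, per-frame peak detection,
#' linking, and persistence/speed filtering.
#'
#' @param movie An `aw_movie`.
#' @param flow_cfg An [flow_config()].
#' @param coherence_window,coherence_sigma Coherence neighbourhood.
#' @param diameter,min_separation,min_score,smooth_sigma Peak detection, see
#'   [detect_peaks()].
#' @param search_range,memory Linking, see [link_tracks()].
#' @param min_frames,min_avg_inst_speed Track filter, see [filter_tracks()].
#' @param preprocess Set `FALSE` if `movie` is already preprocessed.
#' @return List: `tracks` (filtered `aw_tracks`), `all_tracks` (unfiltered),
#'   `detections`, `report` (preprocessing report).
#' @export
track_waves <- function(movie, flow_cfg = flow_config(),
                        coherence_window = 11, coherence_sigma = 5,
                        diameter = 5, min_separation = 15, min_score = 0.25,
                        smooth_sigma = NULL,
                        search_range = 5, memory = 1,
                        min_frames = 8, min_avg_inst_speed = 0.5,
                        preprocess = TRUE) {
  rep <- NULL
  if (preprocess) {
    pp <- preprocess_movie(movie)
    movie <- pp$movie
    rep <- pp$report
  }
  fl <- flow_movie(movie, flow_cfg)
  coh <- coherence_map(fl, window = coherence_window, sigma = coherence_sigma)
  det <- detect_peaks_movie(coh, diameter = diameter,
                            min_separation = min_separation,
                            min_score = min_score, smooth_sigma = smooth_sigma)
  all_tracks <- link_tracks(det, search_range = search_range, memory = memory,
                            calibration = movie$calibration)
  attr(all_tracks, "n_frames") <- n_frames(movie)
  tracks <- filter_tracks(all_tracks, min_frames = min_frames,
                          min_avg_inst_speed = min_avg_inst_speed)
  list(tracks = tracks, all_tracks = all_tracks, detections = det,
       report = rep)
}
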