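# Shared fixtures and independent oracles for the test suite.

# textured image: sum of random Gaussian bumps on a flat background
textured_image <- function(H = 80, W = 80, n_blobs = 30, seed = 1) {
  set.seed(seed)
  img <- matrix(10, H, W)
  for (k in seq_len(n_blobs))
    img <- actinwaves:::add_blob(img, runif(1, 10, W - 10), runif(1, 10, H - 10),
                                 runif(1, 2, 4), runif(1, 50, 150))
  img
}

# movie from a list of matrices at default calibration
mk_movie <- function(frames, ...) movie(frames, ...)

# tracks object from a plain data.frame
mk_tracks <- function(df, n_frames = NA_integer_,
                      cal = calibration()) {
  actinwaves:::as_tracks(df[order(df$track, df$frame), ], cal, list(), n_frames)
}

# exhaustive integer-shift cross-correlation: best (dx, dy) aligning b to ref
oracle_best_shift <- function(ref, b, max_shift = 4) {
  best <- c(0, 0); best_cc <- -Inf
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    shifted <- actinwaves:::shift_frame(b, dx, dy, fill = mean(b))
    H <- nrow(ref); W <- ncol(ref)
    ys <- (max_shift + 1):(H - max_shift); xs <- (max_shift + 1):(W - max_shift)
    cc <- sum((ref[ys, xs] - mean(ref[ys, xs])) *
              (shifted[ys, xs] - mean(shifted[ys, xs])))
    if (cc > best_cc) { best_cc <- cc; best <- c(dx, dy) }
  }
  best
}

# brute-force local maxima + greedy separation pruning on a score matrix
oracle_peaks <- function(score, diameter = 5, min_separation = 15,
                         min_score = 0.25) {
  h <- floor(diameter / 2)
  H <- nrow(score); W <- ncol(score)
  cand <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- score[r, c]
    if (!is.finite(v) || v < min_score) next
    ys <- max(1, r - h):min(H, r + h); xs <- max(1, c - h):min(W, c + h)
    win <- score[ys, xs]
    if (v >= max(win, na.rm = TRUE) - 1e-12)
      cand <- rbind(cand, c(c, r, v))
  }
  if (is.null(cand)) return(matrix(0, 0, 3))
  cand <- cand[order(-cand[, 3], cand[, 2], cand[, 1]), , drop = FALSE]
  kept <- matrix(0, 0, 3)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0 ||
        min(sqrt((kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2)) >=
        min_separation)
      kept <- rbind(kept, cand[i, ])
  }
  kept
}

# exhaustive-enumeration optimum of the linking objective for one frame
# pair: minimise sum of link distances + search_range per unlinked endpoint,
# links beyond search_range forbidden. Returns the minimal objective value.
oracle_link_cost <- function(track_xy, det_xy, search_range) {
  nt <- nrow(track_xy); nd <- nrow(det_xy)
  D <- if (nt && nd)
    sqrt(outer(track_xy[, 1], det_xy[, 1], "-")^2 +
         outer(track_xy[, 2], det_xy[, 2], "-")^2)
  else matrix(0, nt, nd)
  best <- Inf
  # enumerate all partial injective mappings track -> detection
  rec <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > nt) {
      tot <- cost + search_range * (sum(!used) + 0)  # unlinked detections
      tot <- tot + 0
      best <<- min(best, tot)
      return()
    }
    # leave track i unlinked
    rec(i + 1, used, cost + search_range)
    for (j in seq_len(nd)) {
      if (!used[j] && D[i, j] <= search_range)
        rec(i + 1, replace(used, j, TRUE), cost + D[i, j])
    }
  }
  if (nt == 0) return(search_range * nd)
  rec(1, rep(FALSE, nd), 0)
  best
}

# objective value realised by a linking result for one frame pair
realised_link_cost <- function(track_xy, det_xy, match_det, search_range) {
  nt <- nrow(track_xy)
  cost <- 0
  linked_tracks <- match_det[match_det > 0]
  for (j in seq_along(match_det)) {
    i <- match_det[j]
    if (i > 0)
      cost <- cost + sqrt(sum((track_xy[i, ] - det_xy[j, ])^2))
    else cost <- cost + search_range
  }
  cost + search_range * (nt - length(linked_tracks))
}

# brute-force optimal assignment cost for a square matrix (permutations)
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# small well-separated simulation: 3 straight processes, one staggered event
# each, no reversals -- used for recovery checks
well_separated_sim <- function(speed_px_frame = 1.944, n_frames = 100,
                               seed = 42) {
  geo <- generate_geometry(n_processes = 3, mean_length_px = 90,
                           angle_dispersion_deg = 60, seed = seed)
  evs <- data.frame(event = 1:3, process_index = 1:3,
                    birth_frame = c(10, 30, 50), lifetime_frames = 25,
                    speed = speed_px_frame, reversal_prob = 0,
                    origin_arclength = c(20, 40, 30), blob_sigma = 2,
                    amplitude = 150)
  render_movie(geo, evs, n_frames = n_frames, noise_sd = 0, bleach_rate = 0,
               jitter_sd_px = 0, seed = seed + 1)
}

# straight bright ribbon through an otherwise flat image, axial angle deg
ribbon_image <- function(H = 96, W = 96, angle = 45, width_sigma = 1.5,
                         amplitude = 100, background = 10) {
  th <- angle * pi / 180
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  d <- c(cos(th), sin(th))
  a <- c(cx, cy) - (H + W) * d; b <- c(cx, cy) + (H + W) * d
  dist <- actinwaves:::segment_distance(H, W, a, b)
  background + amplitude * exp(-dist^2 / (2 * width_sigma^2))
}
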