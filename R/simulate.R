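# Ground-truthed synthetic time-lapse generator.
#
# Emulates the appearance the analysis assumes: a dim static neurite ribbon
# radiating from a soma, bright isotropic Gaussian blobs (actin waves)
# translocating along the processes with occasional reversals, exponential
# photobleaching, integer-pixel stage jitter, additive Gaussian noise, and a
# 16-bit camera quantisation step.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.na(seed) && abs(seed) >= 2^31)
    stop("seed must be a 32-bit integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic neurite geometry
#'
#' Places a soma near the frame centre and straight process polylines
#' radiating from its boundary. Process axial angles (degrees on `[0, 180)`)
#' are uniform, or wrapped-normal around `ridge_angle` when a nanoridge axis
#' is simulated.
#'
#' @param n_processes Number of processes (>= 1).
#' @param mean_length_px Mean process length in px; individual lengths are
#'   jittered by +/-20%.
#' @param angle_dispersion_deg SD of the wrapped-normal around `ridge_angle`.
#' @param ridge_angle Axial ridge angle in degrees, or `NULL` for a flat
#'   substrate (uniform axial angles).
#' @param frame_shape `c(H, W)` in px.
#' @param soma_radius Soma radius in px.
#' @param seed Optional RNG seed; identical seeds give identical geometry.
#' @return An `aw_geometry`: `soma_center` (x, y), `soma_radius`, `processes`
#'   (list of 2-column x,y vertex matrices), `process_angles` (axial, deg),
#'   `ridge_angle`, `frame_shape`.
#' @export
generate_geometry <- function(n_processes = 3, mean_length_px = 80,
                              angle_dispersion_deg = 20, ridge_angle = NULL,
                              frame_shape = c(256, 256), soma_radius = 12,
                              seed = NULL) {
  stopifnot(n_processes >= 1, mean_length_px > 0, soma_radius > 0)
  H <- frame_shape[1]; W <- frame_shape[2]
  margin <- 6
  if (2 * soma_radius + 20 > min(H, W))
    stop("frame too small to hold the soma and processes")
  with_seed(seed, {
    center <- c(x = W / 2 + stats::runif(1, -5, 5),
                y = H / 2 + stats::runif(1, -5, 5))
    axial <- if (is.null(ridge_angle))
      stats::runif(n_processes, 0, 180)
    else
      (ridge_angle + stats::rnorm(n_processes, 0, angle_dispersion_deg)) %% 180
    side <- sample(c(0, 180), n_processes, replace = TRUE)
    theta <- (axial + side) * pi / 180
    lens <- mean_length_px * stats::runif(n_processes, 0.8, 1.2)
    procs <- vector("list", n_processes)
    for (i in seq_len(n_processes)) {
      d <- c(cos(theta[i]), sin(theta[i]))
      # largest length keeping the endpoint inside the frame margin
      lim <- lens[i]
      if (d[1] != 0) lim <- min(lim,
        ((if (d[1] > 0) W - margin else margin) - center["x"]) / d[1] - soma_radius)
      if (d[2] != 0) lim <- min(lim,
        ((if (d[2] > 0) H - margin else margin) - center["y"]) / d[2] - soma_radius)
      if (lim < 10)
        stop("geometry cannot be placed inside the frame (process too short)")
      p0 <- unname(center) + soma_radius * d
      p1 <- unname(center) + (soma_radius + lim) * d
      procs[[i]] <- rbind(p0, p1)
      colnames(procs[[i]]) <- c("x", "y")
    }
    structure(list(soma_center = unname(center), soma_radius = soma_radius,
                   processes = procs, process_angles = axial,
                   ridge_angle = ridge_angle, frame_shape = c(H, W)),
              class = "aw_geometry")
  })
}

polyline_length <- function(p) {
  sum(sqrt(rowSums(diff(p)^2)))
}

# point at arclength s (clamped) along a polyline
point_at_arclength <- function(p, s) {
  seg <- diff(p)
  seglen <- sqrt(rowSums(seg^2))
  total <- sum(seglen)
  s <- min(max(s, 0), total)
  cum <- c(0, cumsum(seglen))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(seg))
  f <- if (seglen[i] > 0) (s - cum[i]) / seglen[i] else 0
  p[i, ] + f * seg[i, ]
}

#' Generate wave events on a geometry
#'
#' Event births follow an independent Poisson process on each process; origins
#' are uniform along the process, except that with probability
#' `hotspot_recurrence_p` a new origin is resampled within
#' `hotspot_radius_px` (arclength) of an earlier event's origin on the same
#' process, creating recurrence hotspots. Speeds are lognormal with the
#' stated mean and coefficient of variation; lifetimes are exponential.
#'
#' @param geometry From [generate_geometry()].
#' @param n_frames Number of movie frames (>= 2).
#' @param calibration An [calibration()] object.
#' @param rate_per_min_per_process Mean birth rate (events/min/process).
#' @param speed_um_min Mean wave speed in um/min.
#' @param speed_cv Coefficient of variation of the lognormal speeds.
#' @param lifetime_s_mean Mean lifetime in seconds (exponential).
#' @param reversal_prob Per-frame probability that the arclength velocity
#'   flips sign.
#' @param hotspot_recurrence_p Probability a birth reuses an earlier origin
#'   neighbourhood.
#' @param hotspot_radius_px Arclength radius of a hotspot, px.
#' @param blob_sigma Blob Gaussian sigma, px.
#' @param amplitude Blob peak amplitude, intensity units.
#' @param seed Optional RNG seed.
#' @return A data.frame of events (one row each) with columns
#'   `event`, `process_index`, `birth_frame`, `lifetime_frames`, `speed`
#'   (px/frame), `reversal_prob`, `origin_arclength`, `blob_sigma`,
#'   `amplitude`.
#' @export
generate_events <- function(geometry, n_frames, calibration = actinwaves::calibration(),
                            rate_per_min_per_process = 2, speed_um_min = 21,
                            speed_cv = 0.3, lifetime_s_mean = 30,
                            reversal_prob = 0.05, hotspot_recurrence_p = 0.5,
                            hotspot_radius_px = 10, blob_sigma = 2,
                            amplitude = 150, seed = NULL) {
  stopifnot(inherits(geometry, "aw_geometry"), n_frames >= 2,
            rate_per_min_per_process >= 0, speed_um_min >= 0, speed_cv >= 0,
            lifetime_s_mean > 0, reversal_prob >= 0, reversal_prob <= 1,
            hotspot_recurrence_p >= 0, hotspot_recurrence_p <= 1)
  dur_min <- n_frames * calibration$frame_interval / 60
  mean_px_frame <- speed_um_min / 60 * calibration$frame_interval /
    calibration$pixel_size
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(geometry$processes)) {
      n_i <- stats::rpois(1, rate_per_min_per_process * dur_min)
      if (n_i == 0) next
      rows[[i]] <- data.frame(process_index = i,
                              birth_frame = sample.int(max(n_frames - 1L, 1L), n_i,
                                                       replace = TRUE))
    }
    ev <- if (length(rows)) do.call(rbind, rows) else
      data.frame(process_index = integer(), birth_frame = integer())
    ev <- ev[order(ev$birth_frame, ev$process_index), , drop = FALSE]
    n <- nrow(ev)
    if (n == 0) {
      out <- data.frame(event = integer(), process_index = integer(),
                        birth_frame = integer(), lifetime_frames = integer(),
                        speed = numeric(), reversal_prob = numeric(),
                        origin_arclength = numeric(), blob_sigma = numeric(),
                        amplitude = numeric())
      return(out)
    }
    if (speed_cv > 0 && mean_px_frame > 0) {
      sdlog <- sqrt(log(1 + speed_cv^2))
      mulog <- log(mean_px_frame) - sdlog^2 / 2
      speeds <- stats::rlnorm(n, mulog, sdlog)
    } else speeds <- rep(mean_px_frame, n)
    lifetimes <- pmax(1L, as.integer(round(
      stats::rexp(n, 1 / lifetime_s_mean) / calibration$frame_interval)))
    origin <- numeric(n)
    prev <- vector("list", length(geometry$processes))
    for (k in seq_len(n)) {
      p <- ev$process_index[k]
      L <- polyline_length(geometry$processes[[p]])
      reuse <- length(prev[[p]]) > 0 && stats::runif(1) < hotspot_recurrence_p
      if (reuse) {
        anchor <- prev[[p]][sample.int(length(prev[[p]]), 1)]
        origin[k] <- min(max(anchor + stats::runif(1, -hotspot_radius_px,
                                                   hotspot_radius_px), 0), L)
      } else {
        origin[k] <- stats::runif(1, 0, L)
      }
      prev[[p]] <- c(prev[[p]], origin[k])
    }
    data.frame(event = seq_len(n), process_index = ev$process_index,
               birth_frame = ev$birth_frame, lifetime_frames = lifetimes,
               speed = speeds, reversal_prob = reversal_prob,
               origin_arclength = origin, blob_sigma = blob_sigma,
               amplitude = amplitude)
  })
}

# distance from every pixel to a segment a-b; returns H x W matrix
segment_distance <- function(H, W, a, b) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((xs - a[1])^2 + (ys - a[2])^2))
  t <- ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((xs - (a[1] + t * ab[1]))^2 + (ys - (a[2] + t * ab[2]))^2)
}

static_scene <- function(geometry, background, neurite_intensity,
                         ribbon_sigma = 1.5) {
  H <- geometry$frame_shape[1]; W <- geometry$frame_shape[2]
  img <- matrix(background, H, W)
  for (p in geometry$processes) {
    for (i in seq_len(nrow(p) - 1)) {
      d <- segment_distance(H, W, p[i, ], p[i + 1, ])
      img <- img + neurite_intensity * exp(-d^2 / (2 * ribbon_sigma^2))
    }
  }
  dsoma <- segment_distance(H, W, geometry$soma_center, geometry$soma_center)
  img + 1.5 * neurite_intensity / (1 + exp((dsoma - geometry$soma_radius) / 1.5))
}

# integer-pixel translation with constant fill; out[y+dy, x+dx] = in[y, x]
shift_frame <- function(m, dx, dy, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sy <- seq_len(H) - dy; sx <- seq_len(W) - dx
  oky <- sy >= 1 & sy <= H; okx <- sx >= 1 & sx <= W
  out[oky, okx] <- m[sy[oky], sx[okx]]
  out
}

add_blob <- function(img, x, y, sigma, amp) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(4 * sigma)
  xs <- max(1, floor(x - r)):min(W, ceiling(x + r))
  ys <- max(1, floor(y - r)):min(H, ceiling(y + r))
  if (!length(xs) || !length(ys)) return(img)
  g <- amp * outer(exp(-(ys - y)^2 / (2 * sigma^2)),
                   exp(-(xs - x)^2 / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + g
  img
}

# simulate the on-polyline path of one event; returns data.frame(frame, x, y)
event_path <- function(event, geometry, n_frames) {
  p <- geometry$processes[[event$process_index]]
  L <- polyline_length(p)
  frames <- event$birth_frame:min(event$birth_frame + event$lifetime_frames - 1L,
                                  n_frames)
  s <- event$origin_arclength
  dir <- if (stats::runif(1) < 0.5) 1 else -1
  out <- matrix(NA_real_, length(frames), 2)
  for (k in seq_along(frames)) {
    pt <- point_at_arclength(p, s)
    out[k, ] <- pt
    if (stats::runif(1) < event$reversal_prob) dir <- -dir
    s_new <- s + dir * event$speed
    if (s_new < 0) { s_new <- -s_new; dir <- -dir }
    if (s_new > L) { s_new <- 2 * L - s_new; dir <- -dir }
    s <- min(max(s_new, 0), L)
  }
  data.frame(frame = frames, x = out[, 1], y = out[, 2])
}

#' Render a synthetic movie with full ground truth
#'
#' Frame `t` is `[static scene + sum of moving Gaussian blobs] *
#' exp(-bleach_rate * (t - 1))`, shifted by an integer stage jitter, plus
#' Gaussian noise, then (by default) rounded to integers and clamped at zero,
#' emulating a 16-bit camera. Frame 1 carries zero jitter so registered
#' coordinates coincide with ground-truth coordinates.
#'
#' @param geometry From [generate_geometry()].
#' @param events From [generate_events()].
#' @param n_frames Number of frames.
#' @param calibration An [calibration()] object.
#' @param background Baseline intensity.
#' @param neurite_intensity Ribbon intensity above background.
#' @param noise_sd Gaussian noise SD (0 disables).
#' @param bleach_rate Per-frame exponential decay constant.
#' @param jitter_sd_px SD of the integer per-frame stage jitter (0 disables).
#' @param quantize Round to integer camera counts (default `TRUE`). Disable
#'   for closed-form photometric checks.
#' @param seed Optional RNG seed.
#' @return A list of class `aw_simulation`: `movie` (an `aw_movie`) and
#'   `ground_truth` with `events`, `true_tracks` (event, frame, x, y in
#'   jitter-free coordinates), `geometry`, `applied_jitter` (frame, dx, dy),
#'   `bleach_rate`, and the scene parameters.
#' @export
render_movie <- function(geometry, events, n_frames = 150,
                         calibration = actinwaves::calibration(),
                         background = 100, neurite_intensity = 50,
                         noise_sd = 5, bleach_rate = 0.002, jitter_sd_px = 0.5,
                         quantize = TRUE, seed = NULL) {
  stopifnot(inherits(geometry, "aw_geometry"), n_frames >= 2,
            background >= 0, noise_sd >= 0, bleach_rate >= 0, jitter_sd_px >= 0)
  H <- geometry$frame_shape[1]; W <- geometry$frame_shape[2]
  with_seed(seed, {
    static <- static_scene(geometry, background, neurite_intensity)
    paths <- if (nrow(events)) lapply(seq_len(nrow(events)), function(i)
      cbind(event = events$event[i], event_path(events[i, ], geometry, n_frames)))
    else list()
    truth <- if (length(paths)) do.call(rbind, paths) else
      data.frame(event = integer(), frame = integer(), x = numeric(), y = numeric())
    jx <- c(0L, as.integer(round(stats::rnorm(n_frames - 1, 0, jitter_sd_px))))
    jy <- c(0L, as.integer(round(stats::rnorm(n_frames - 1, 0, jitter_sd_px))))
    frames <- array(0, dim = c(H, W, n_frames))
    for (t in seq_len(n_frames)) {
      f <- static
      if (nrow(truth)) {
        here <- truth[truth$frame == t, , drop = FALSE]
        for (i in seq_len(nrow(here))) {
          ev <- events[events$event == here$event[i], ]
          f <- add_blob(f, here$x[i], here$y[i], ev$blob_sigma, ev$amplitude)
        }
      }
      decay <- exp(-bleach_rate * (t - 1))
      f <- f * decay
      if (jx[t] != 0 || jy[t] != 0)
        f <- shift_frame(f, jx[t], jy[t], fill = background * decay)
      if (noise_sd > 0)
        f <- f + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      if (quantize) f <- pmax(round(f), 0)
      frames[, , t] <- f
    }
    mv <- movie(frames, calibration$pixel_size, calibration$frame_interval,
                name = "synthetic")
    gt <- list(events = events, true_tracks = truth, geometry = geometry,
               applied_jitter = data.frame(frame = seq_len(n_frames),
                                           dx = jx, dy = jy),
               bleach_rate = bleach_rate, background = background,
               neurite_intensity = neurite_intensity, noise_sd = noise_sd)
    structure(list(movie = mv, ground_truth = gt), class = "aw_simulation")
  })
}

#' One-call synthetic movie with the package's default study conditions
#'
#' Convenience wrapper chaining [generate_geometry()], [generate_events()]
#' and [render_movie()] with a single seed. Defaults follow the regime of the
#' real acquisitions: 0.36 um/px, 2 s/frame, waves at a mean 21 um/min with
#' ~30 s lifetimes, 150 frames of 256 x 256 px.
#'
#' @param seed RNG seed for the whole simulation.
#' @param n_frames,frame_shape Movie size.
#' @param calibration An [calibration()] object.
#' @param ridge_angle Optional axial nanoridge angle (degrees).
#' @param geometry_args,event_args,render_args Named lists of overrides passed
#'   to the three stages.
#' @return An `aw_simulation`, see [render_movie()].
#' @export
simulate_movie <- function(seed = 1, n_frames = 150, frame_shape = c(256, 256),
                           calibration = actinwaves::calibration(),
                           ridge_angle = NULL, geometry_args = list(),
                           event_args = list(), render_args = list()) {
  geo <- do.call(generate_geometry, c(list(
    frame_shape = frame_shape, ridge_angle = ridge_angle, seed = seed),
    geometry_args))
  ev <- do.call(generate_events, c(list(
    geometry = geo, n_frames = n_frames, calibration = calibration,
    seed = seed + 1000L), event_args))
  do.call(render_movie, c(list(
    geometry = geo, events = ev, n_frames = n_frames,
    calibration = calibration, seed = seed + 2000L), render_args))
}
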