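# Ground-truthed movie generator.

test_that("geometry generation is deterministic and respects the ridge axis", {
  g1 <- generate_geometry(seed = 9)
  g2 <- generate_geometry(seed = 9)
  expect_identical(g1, g2)
  # zero dispersion around a ridge: every process parallel to it
  g <- generate_geometry(n_processes = 4, angle_dispersion_deg = 0,
                         ridge_angle = 30, seed = 2)
  expect_true(all(abs(g$process_angles - 30) < 1e-9))
  # all polyline vertices inside the frame
  for (p in g$processes) {
    expect_true(all(p[, "x"] >= 1 & p[, "x"] <= 256))
    expect_true(all(p[, "y"] >= 1 & p[, "y"] <= 256))
  }
})

test_that("uniform-mode process angles are uniform on [0, 180)", {
  set.seed(1)
  angs <- unlist(lapply(1:400, function(s)
    generate_geometry(n_processes = 4, seed = s)$process_angles))
  cnt <- table(cut(angs, seq(0, 180, by = 18)))
  p <- stats::chisq.test(cnt)$p.value
  expect_gt(p, 0.01)
})

test_that("event births follow the configured Poisson process", {
  geo <- generate_geometry(seed = 3)
  cal <- calibration()
  # zero rate: no events
  e0 <- generate_events(geo, n_frames = 100, rate_per_min_per_process = 0,
                        seed = 1)
  expect_equal(nrow(e0), 0)
  # rate 2/min/process, 3 processes, 10 min -> mean 60 events
  n_frames <- 10 * 60 / cal$frame_interval
  counts <- vapply(1:200, function(s)
    nrow(generate_events(geo, n_frames = n_frames,
                         rate_per_min_per_process = 2, seed = s)),
    numeric(1))
  mu <- 60
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("full hotspot recurrence pins origins to the seeded origin", {
  geo <- generate_geometry(n_processes = 1, seed = 4)
  ev <- generate_events(geo, n_frames = 300, rate_per_min_per_process = 4,
                        hotspot_recurrence_p = 1, hotspot_radius_px = 6,
                        seed = 5)
  expect_gt(nrow(ev), 3)
  # chained resampling within radius 6 of *some* previous origin: successive
  # origins never jump farther than the radius from the nearest predecessor
  o <- ev$origin_arclength
  for (k in 2:length(o))
    expect_lte(min(abs(o[k] - o[seq_len(k - 1)])), 6 + 1e-9)
})

test_that("rendering is deterministic and photometrically correct", {
  geo <- generate_geometry(seed = 6, frame_shape = c(64, 64))
  ev <- generate_events(geo, n_frames = 10, seed = 7)
  s1 <- render_movie(geo, ev, n_frames = 10, seed = 8)
  s2 <- render_movie(geo, ev, n_frames = 10, seed = 8)
  expect_identical(s1$movie$frames, s2$movie$frames)
  # closed-form bleaching of an event-free movie
  k <- 0.03
  sb <- render_movie(geo, ev[0, ], n_frames = 6, noise_sd = 0,
                     bleach_rate = k, jitter_sd_px = 0, quantize = FALSE,
                     seed = 1)
  means <- apply(sb$movie$frames, 3, mean)
  expect_equal(means[-1] / means[-6], rep(exp(-k), 5), tolerance = 1e-12)
})

test_that("a noise-free blob advances at its configured speed", {
  # one horizontal process, one event at 1 px/frame, no reversals
  geo <- generate_geometry(n_processes = 1, angle_dispersion_deg = 0,
                           ridge_angle = 0, mean_length_px = 80,
                           frame_shape = c(96, 96), seed = 10)
  ev <- data.frame(event = 1L, process_index = 1L, birth_frame = 2L,
                   lifetime_frames = 12L, speed = 1, reversal_prob = 0,
                   origin_arclength = 10, blob_sigma = 2, amplitude = 150)
  sim <- render_movie(geo, ev, n_frames = 15, noise_sd = 0, bleach_rate = 0,
                      jitter_sd_px = 0, quantize = FALSE, seed = 1)
  tt <- sim$ground_truth$true_tracks
  expect_equal(nrow(tt), 12)
  steps <- sqrt(diff(tt$x)^2 + diff(tt$y)^2)
  expect_equal(steps, rep(1, 11), tolerance = 1e-9)
  # rendered blob centroid (blob-only image) matches ground truth < 0.1 px
  base <- render_movie(geo, ev[0, ], n_frames = 15, noise_sd = 0,
                       bleach_rate = 0, jitter_sd_px = 0, quantize = FALSE,
                       seed = 1)
  for (k in c(1, 6, 12)) {
    t <- tt$frame[k]
    blob <- sim$movie$frames[, , t] - base$movie$frames[, , t]
    ys <- round(tt$y[k]) + (-6:6); xs <- round(tt$x[k]) + (-6:6)
    w <- blob[ys, xs]
    cx <- sum(rep(xs, each = 13) * w) / sum(w)
    cy <- sum(rep(ys, 13) * w) / sum(w)
    expect_lt(abs(cx - tt$x[k]), 0.1)
    expect_lt(abs(cy - tt$y[k]), 0.1)
  }
  # blob mass is conserved across frames before bleaching
  mass <- vapply(tt$frame, function(t)
    sum(sim$movie$frames[, , t] - base$movie$frames[, , t]), numeric(1))
  expect_lt(diff(range(mass)) / mean(mass), 1e-6)
})

test_that("ground-truth tracks stay on their process polyline", {
  geo <- generate_geometry(n_processes = 2, seed = 11)
  ev <- generate_events(geo, n_frames = 60, seed = 12)
  sim <- render_movie(geo, ev, n_frames = 60, seed = 13)
  tt <- sim$ground_truth$true_tracks
  for (i in seq_len(nrow(tt))) {
    p <- geo$processes[[ev$process_index[ev$event == tt$event[i]]]]
    d <- min(vapply(seq_len(nrow(p) - 1), function(s) {
      a <- p[s, ]; b <- p[s + 1, ]; q <- c(tt$x[i], tt$y[i])
      ab <- b - a; t0 <- sum((q - a) * ab) / sum(ab^2)
      t0 <- min(max(t0, 0), 1)
      sqrt(sum((q - (a + t0 * ab))^2))
    }, numeric(1)))
    expect_lt(d, 1e-6)
  }
})
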