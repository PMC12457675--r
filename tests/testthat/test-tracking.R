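# Coherence, peak detection, linking and track metrics.

mk_flow <- function(u, v, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  structure(list(u = u, v = v, valid = valid,
                 reliability = valid * 1, config = flow_config()),
            class = "aw_flow")
}

test_that("coherence of a uniform field is |v|^2 in the interior", {
  for (vec in list(c(1, 0), c(2, 0), c(0.3, -0.4))) {
    fl <- mk_flow(matrix(vec[1], 30, 30), matrix(vec[2], 30, 30))
    cm <- coherence_map(fl)
    expect_equal(cm[10:20, 10:20], matrix(sum(vec^2), 11, 11),
                 tolerance = 1e-9)
  }
})

test_that("antagonistic flow scores negative at the centre", {
  u <- matrix(-1, 21, 21); u[11, 11] <- 1
  fl <- mk_flow(u, matrix(0, 21, 21))
  cm <- coherence_map(fl)
  # hand check: weighted mean at the centre is dominated by the -1 ring
  k <- EBImage::makeBrush(11, "gaussian", sigma = 5); k <- k / sum(k)
  expected <- 1 * (sum(-k) + 2 * k[6, 6])
  expect_equal(cm[11, 11], expected, tolerance = 1e-9)
  expect_lt(cm[11, 11], 0)
})

test_that("invalid neighbours are excluded and weights renormalised", {
  u <- matrix(1, 30, 30)
  valid <- matrix(TRUE, 30, 30); valid[, 1:15] <- FALSE
  fl <- mk_flow(u, matrix(0, 30, 30), valid)
  cm <- coherence_map(fl)
  # just right of the invalid half: mean over valid neighbours is still 1
  expect_equal(cm[20, 16], 1, tolerance = 1e-9)
  expect_true(is.na(cm[20, 10]))
})

test_that("peak detection localises bumps and enforces separation", {
  mkbump <- function(centres, H = 60, W = 60) {
    m <- matrix(0, H, W)
    for (ct in centres) m <- actinwaves:::add_blob(m, ct[1], ct[2], 2.5, 5)
    m
  }
  p1 <- detect_peaks(mkbump(list(c(30, 40))), min_score = 0.5)
  expect_equal(nrow(p1), 1)
  expect_lt(sqrt((p1$x - 30)^2 + (p1$y - 40)^2), 1)
  # two equal bumps 10 px apart, min separation 15: one survivor
  p2 <- detect_peaks(mkbump(list(c(25, 30), c(35, 30))), min_score = 0.5)
  expect_equal(nrow(p2), 1)
  # 20 px apart: both retained
  p3 <- detect_peaks(mkbump(list(c(20, 30), c(40, 30))), min_score = 0.5)
  expect_equal(nrow(p3), 2)
})

test_that("integer peak candidates match a brute-force oracle on random maps", {
  # smoothing off so both sides see the same surface
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(stats::rnorm(40 * 40), 40, 40)
    m[sample(1600, 200)] <- NA
    got <- detect_peaks(m, diameter = 5, min_separation = 9, min_score = 0.5,
                        smooth_sigma = 0)
    want <- oracle_peaks(m, diameter = 5, min_separation = 9, min_score = 0.5)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      # both are ordered by descending score; identical scores pin the same
      # retained integer maxima. Recentred centroids stay within the
      # refinement window drift bound of the maximum.
      expect_equal(got$score, want[, 3])
      expect_true(all(abs(got$x - want[, 1]) < 5))
      expect_true(all(abs(got$y - want[, 2]) < 5))
    }
  }
})

test_that("the Hungarian solver matches exhaustive permutation search", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(2:6, 1)
    cost <- matrix(stats::runif(n * n, 0, 10), n, n)
    a <- actinwaves:::hungarian(cost)
    expect_equal(sort(a), 1:n)                     # a permutation
    expect_equal(sum(cost[cbind(1:n, a)]), oracle_assignment_cost(cost),
                 tolerance = 1e-9)
  }
})

test_that("frame-pair linking attains the exhaustive-enumeration optimum", {
  for (s in 1:15) {
    set.seed(s)
    nt <- sample(0:6, 1); nd <- sample(0:6, 1)
    track_xy <- matrix(stats::runif(2 * nt, 0, 30), ncol = 2)
    det_xy <- matrix(stats::runif(2 * nd, 0, 30), ncol = 2)
    m <- actinwaves:::link_step(track_xy, det_xy, search_range = 8)
    got <- realised_link_cost(track_xy, det_xy, m, 8)
    want <- oracle_link_cost(track_xy, det_xy, 8)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("linking bridges single-frame gaps within memory", {
  det <- data.frame(frame = c(1L, 2L, 4L), x = c(0, 2, 6), y = c(0, 0, 0))
  trk <- link_tracks(det, search_range = 5, memory = 1)
  expect_equal(length(unique(trk$track)), 1)
  expect_equal(nrow(trk), 3)
  # out of range: two singleton tracks
  far <- data.frame(frame = c(1L, 2L), x = c(0, 20), y = c(0, 0))
  t2 <- link_tracks(far, search_range = 5, memory = 1)
  expect_equal(length(unique(t2$track)), 2)
  # memory 0 does not bridge the frame-3 gap
  t3 <- link_tracks(det, search_range = 5, memory = 0)
  expect_equal(length(unique(t3$track)), 2)
})

test_that("parallel streams link without identity swaps and order-invariantly", {
  frames <- 1:10
  a <- data.frame(frame = frames, x = 2 * frames, y = 10)
  b <- data.frame(frame = frames, x = 2 * frames, y = 40)
  det <- rbind(a, b)
  trk <- link_tracks(det, search_range = 5)
  expect_equal(length(unique(trk$track)), 2)
  for (id in unique(trk$track))
    expect_equal(length(unique(trk$y[trk$track == id])), 1)  # no swaps
  # permuting detection order within frames changes nothing up to track
  # id relabelling: compare canonicalised trajectory sets
  canonical <- function(tr) {
    parts <- lapply(split(as.data.frame(tr)[c("frame", "x", "y")], tr$track),
                    function(d) { rownames(d) <- NULL; d[order(d$frame), ] })
    parts[order(vapply(parts, function(d)
      sprintf("%04d_%09.3f_%09.3f", d$frame[1], d$x[1], d$y[1]),
      character(1)))]
  }
  set.seed(3)
  det2 <- det[sample(nrow(det)), ]
  trk2 <- link_tracks(det2, search_range = 5)
  expect_equal(unname(canonical(trk2)), unname(canonical(trk)))
})

test_that("track metrics match their definitions on canonical paths", {
  # collinear path: sinuosity exactly 1
  trk <- mk_tracks(data.frame(track = 1L, frame = 0:2,
                              x = c(0, 3, 6), y = c(0, 4, 8)))
  m <- track_metrics(trk)
  expect_equal(m$total_length, 10)
  expect_equal(m$net_displacement, 10)
  expect_equal(m$sinuosity, 1)
  expect_equal(m$duration_frames, 3L)
  expect_equal(m$avg_inst_speed, 5)
  # closed square: zero net displacement, sinuosity undefined
  sq <- mk_tracks(data.frame(track = 1L, frame = 1:5,
                             x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0)))
  ms <- track_metrics(sq)
  expect_equal(ms$net_displacement, 0)
  expect_true(is.na(ms$sinuosity))
  # random walks: triangle inequality, and physical twins consistent
  set.seed(9)
  for (r in 1:20) {
    n <- sample(5:20, 1)
    w <- mk_tracks(data.frame(track = 1L, frame = seq_len(n),
                              x = cumsum(stats::rnorm(n)),
                              y = cumsum(stats::rnorm(n))))
    mm <- track_metrics(w)
    expect_gte(mm$total_length, mm$net_displacement - 1e-12)
    expect_gte(mm$sinuosity, 1 - 1e-12)
    expect_equal(mm$avg_speed_um_min, convert_speed(mm$avg_speed, calibration()))
  }
  # single-point track: metrics flagged NA
  p1 <- track_metrics(mk_tracks(data.frame(track = 1L, frame = 1L, x = 0, y = 0)))
  expect_true(is.na(p1$avg_speed))
})

test_that("track filtering applies both predicates (vs brute force)", {
  mk <- function(id, dur, step) data.frame(
    track = id, frame = seq_len(dur), x = cumsum(rep(step, dur)), y = 0)
  trk <- mk_tracks(rbind(mk(1L, 10, 1.0), mk(2L, 8, 0.3), mk(3L, 5, 2.0)))
  kept <- filter_tracks(trk)
  expect_equal(unique(kept$track), 1L)
  # empty in, empty out
  e <- filter_tracks(mk_tracks(data.frame(track = integer(), frame = integer(),
                                          x = numeric(), y = numeric())))
  expect_equal(nrow(e), 0)
  # 200 random tracks: survivor set equals independent re-evaluation
  set.seed(11)
  rows <- lapply(1:200, function(id) {
    n <- sample(2:15, 1)
    f0 <- sample(1:50, 1)
    data.frame(track = id, frame = f0 + cumsum(c(0, sample(1:2, n - 1, TRUE))),
               x = cumsum(stats::rnorm(n, 0, 1.2)), y = cumsum(stats::rnorm(n, 0, 1.2)))
  })
  trk2 <- mk_tracks(do.call(rbind, rows))
  kept2 <- unique(filter_tracks(trk2)$track)
  manual <- vapply(rows, function(d) {
    dur <- max(d$frame) - min(d$frame) + 1
    st <- sqrt(diff(d$x)^2 + diff(d$y)^2) / diff(d$frame)
    dur >= 8 && mean(st) > 0.5
  }, logical(1))
  expect_equal(sort(kept2), which(manual))
})

test_that("duration-weighted histograms are reproduced by a weighted-count oracle", {
  set.seed(13)
  angs <- stats::runif(100, 0, 90)
  wts <- sample(8:40, 100, replace = TRUE)          # track durations
  d <- angle_distribution(angs, weights = wts)
  expect_equal(sum(d$pdf), 1, tolerance = 1e-9)
  oracle <- vapply(1:20, function(b) {
    lo <- (b - 1) * 4.5; hi <- b * 4.5
    sel <- if (b == 20) angs >= lo & angs <= hi else angs >= lo & angs < hi
    sum(wts[sel])
  }, numeric(1))
  expect_equal(d$pdf, oracle / sum(oracle), tolerance = 1e-9)
})
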