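# Axial angles, alignment distributions, Wasserstein comparisons.

test_that("axial folding matches hand-computed cases and is idempotent", {
  expect_equal(axial_angle(30, 30), 0)
  expect_equal(axial_angle(120, 30), 90)
  expect_equal(axial_angle(350, 10), 20)     # 350 -> 170 axial, |170-10| -> 20
  expect_equal(axial_angle(-45, 45), 90)
  # folding a folded angle against axis 0 changes nothing
  set.seed(1)
  d <- stats::runif(100, -360, 360); a <- stats::runif(100, 0, 180)
  f <- axial_angle(d, a)
  expect_true(all(f >= 0 & f <= 90))
  expect_equal(axial_angle(f, 0), f)
})

test_that("ridge alignment concentrates and disperses as constructed", {
  # all steps along the ridge: all mass in the first bin
  trk <- mk_tracks(data.frame(track = 1L, frame = 1:10,
                              x = cumsum(rep(cos(pi / 6), 10)),
                              y = cumsum(rep(sin(pi / 6), 10))))
  d <- track_ridge_alignment(trk, ridge_angle = 30)
  expect_equal(d$pdf[1], 1)
  expect_equal(sum(d$pdf), 1)
  # isotropic random walks: uniform pdf within 3-sigma multinomial bands
  set.seed(2)
  rows <- lapply(1:60, function(id) {
    n <- 40
    ang <- stats::runif(n, 0, 2 * pi)
    data.frame(track = id, frame = seq_len(n + 1),
               x = cumsum(c(0, cos(ang))), y = cumsum(c(0, sin(ang))))
  })
  iso <- mk_tracks(do.call(rbind, rows))
  di <- track_ridge_alignment(iso, ridge_angle = 77)
  counts <- round(di$pdf * di$n_effective)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("process alignment uses the nearest masked pixel (vs brute force)", {
  # two ribbons: horizontal at y=20 (angle 0), vertical at x=60 (angle 90)
  angle <- matrix(NA_real_, 80, 80)
  angle[20, 5:55] <- 0
  angle[5:75, 60] <- 90
  of <- structure(list(angle = angle, response = angle * 0,
                       low_confidence = is.na(angle), angles = seq(0, 175, 5)),
                  class = "aw_orientation")
  # a track moving at 45 degrees near the horizontal ribbon, another moving
  # horizontally near the vertical ribbon
  trk <- mk_tracks(rbind(
    data.frame(track = 1L, frame = 1:6, x = 10 + (0:5), y = 18 + (0:5)),
    data.frame(track = 2L, frame = 1:6, x = 57 + (0:5) * 0.9, y = 40)))
  d <- track_process_alignment(trk, of, max_dist = 30)
  st <- track_steps(trk); st <- st[st$dist > 0, ]
  masked <- which(!is.na(angle), arr.ind = TRUE)
  want <- vapply(seq_len(nrow(st)), function(i) {
    mx <- st$x0[i] + st$dx[i] / 2; my <- st$y0[i] + st$dy[i] / 2
    j <- which.min((masked[, 2] - mx)^2 + (masked[, 1] - my)^2)
    axial_angle(st$angle[i], angle[masked[j, 1], masked[j, 2]])
  }, numeric(1))
  oracle <- angle_distribution(want, n_bins = 20)
  expect_equal(d$pdf, oracle$pdf)
  # orientation rotated 90 degrees pushes mass to the opposite end
  of90 <- of; of90$angle <- (of90$angle + 90) %% 180
  straight <- mk_tracks(data.frame(track = 1L, frame = 1:8,
                                   x = 10 + (0:7), y = 20))
  expect_equal(track_process_alignment(straight, of, max_dist = 5)$pdf[1], 1)
  expect_equal(track_process_alignment(straight, of90, max_dist = 5)$pdf[20], 1)
})

test_that("wasserstein distance reproduces closed forms and metric axioms", {
  # grid with one integer per bin, so sample positions are representable
  edges <- seq(-0.5, 9.5, by = 1)
  # identical CDFs
  F <- ecdf_on_grid(c(2, 5, 7), edges)
  expect_equal(wasserstein_1d(F, F, edges), 0)
  # point masses at 0 and d
  for (d in c(2, 5, 9)) {
    A <- ecdf_on_grid(0, edges); B <- ecdf_on_grid(d, edges)
    expect_equal(wasserstein_1d(A, B, edges), d)
  }
  # two-sample instance {0,1} vs {1,2}
  A <- ecdf_on_grid(c(0, 1), edges); B <- ecdf_on_grid(c(1, 2), edges)
  expect_equal(wasserstein_1d(A, B, edges), 1)
  # metric axioms on random CDF triples
  set.seed(4)
  for (r in 1:20) {
    mk <- function() { p <- stats::runif(10); cumsum(p / sum(p)) }
    X <- mk(); Y <- mk(); Z <- mk()
    e <- 0:10
    expect_equal(wasserstein_1d(X, Y, e), wasserstein_1d(Y, X, e))
    expect_gte(wasserstein_1d(X, Y, e) + wasserstein_1d(Y, Z, e),
               wasserstein_1d(X, Z, e) - 1e-12)
    expect_equal(wasserstein_1d(X, X, e), 0)
  }
  expect_error(wasserstein_1d(c(0.5, 1), c(0.2, 0.4, 1), 0:2), "differ")
})

test_that("CDF ensembles aggregate quantiles and W1 extremes correctly", {
  set.seed(5)
  mkdist <- function(shift) {
    ang <- pmin(pmax(stats::rnorm(300, 30 + shift, 12), 0), 90)
    angle_distribution(ang)
  }
  a <- aggregate_cdfs(lapply(rep(0, 5), mkdist))
  b <- aggregate_cdfs(lapply(rep(20, 5), mkdist))
  # identical videos degenerate: q25 = median = q75
  same <- mkdist(0)
  ens <- aggregate_cdfs(list(same, same, same))
  expect_equal(ens$q25_cdf, ens$median_cdf)
  expect_equal(ens$q75_cdf, ens$median_cdf)
  expect_true(all(diff(ens$median_cdf) >= -1e-12))
  # a known generative shift of 20 degrees appears in w1_median
  w <- w1_between(a, b)
  expect_gt(w$w1_median, 10); expect_lt(w$w1_median, 30)
  # min/max bound the four pairings by definition (enumerated)
  expect_equal(w$w1_min, min(w$pairings$w1))
  expect_equal(w$w1_max, max(w$pairings$w1))
  expect_lte(w$w1_min, w$w1_max)
  expect_gte(w$w1_median, 0)
})

test_that("ridge-constrained synthetic events concentrate alignment mass", {
  sim <- simulate_movie(seed = 31, n_frames = 80, frame_shape = c(160, 160),
                        ridge_angle = 40,
                        geometry_args = list(angle_dispersion_deg = 5,
                                             mean_length_px = 60),
                        event_args = list(reversal_prob = 0.02),
                        render_args = list(noise_sd = 2))
  # ground-truth steps, duration-weighted: >= 70% of mass below 22.5 degrees
  tt <- sim$ground_truth$true_tracks
  st <- do.call(rbind, lapply(split(tt, tt$event), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(a = atan2(diff(d$y), diff(d$x)) * 180 / pi,
               len = sqrt(diff(d$x)^2 + diff(d$y)^2))
  }))
  st <- st[st$len > 1e-9, ]
  d <- angle_distribution(axial_angle(st$a, 40))
  expect_gte(sum(d$pdf[1:5]), 0.7)
})
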