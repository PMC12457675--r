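# Alignment of wave motion with nanoridge and neurite axes, duration-
# weighted axial-angle distributions, CDF ensembles and 1-D Wasserstein
# comparisons.

#' Fold a direction onto an axis: axial alignment angle
#'
#' Ridges and process orientations are axes (defined modulo 180 degrees), so
#' the alignment of a movement direction with an axis lives on `[0, 90]`.
#'
#' @param direction_deg Movement direction(s), degrees (any real).
#' @param axis_deg Axis angle(s), degrees.
#' @return Folded angle(s) in `[0, 90]`.
#' @export
axial_angle <- function(direction_deg, axis_deg) {
  d <- (direction_deg - axis_deg) %% 180
  pmin(d, 180 - d)
}

#' Binned axial-angle distribution
#'
#' Histogram of alignment angles on `[0, 90]` (default 20 bins) with
#' arbitrary nonnegative weights; per-step weighting of track segments makes
#' long-lived tracks contribute proportionally to their duration.
#'
#' @param angles Angles in `[0, 90]`.
#' @param weights Nonnegative weights (default 1 per angle).
#' @param n_bins Number of equal bins.
#' @return An `aw_angledist` list: `bin_edges` (length `n_bins + 1`), `pdf`
#'   (sums to 1), `cdf` (ends at 1), `n_effective` (total weight).
#' @export
angle_distribution <- function(angles, weights = NULL, n_bins = 20) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  ok <- is.finite(angles) & is.finite(weights)
  angles <- angles[ok]; weights <- weights[ok]
  if (!length(angles) || sum(weights) == 0)
    stop("no finite, positively weighted angles to bin")
  stopifnot(all(angles >= 0), all(angles <= 90))
  edges <- seq(0, 90, length.out = n_bins + 1)
  bin <- pmin(findInterval(angles, edges, rightmost.closed = TRUE), n_bins)
  pdf <- vapply(seq_len(n_bins), function(b) sum(weights[bin == b]), numeric(1))
  pdf <- pdf / sum(pdf)
  structure(list(bin_edges = edges, pdf = pdf, cdf = cumsum(pdf),
                 n_effective = sum(weights)),
            class = "aw_angledist")
}

#' Alignment of track steps with the nanoridge axis
#'
#' Each inter-detection step contributes its axial alignment angle with the
#' ridge axis, weighted by 1 per step (duration weighting); zero-length
#' steps are skipped. The uniform reference mass per bin is `1/n_bins`.
#'
#' @param tracks An `aw_tracks` (normally filtered).
#' @param ridge_angle Axial ridge angle, degrees.
#' @param n_bins Histogram bins on `[0, 90]`.
#' @return An `aw_angledist`.
#' @export
track_ridge_alignment <- function(tracks, ridge_angle, n_bins = 20) {
  st <- track_steps(tracks)
  st <- st[st$dist > 0, , drop = FALSE]
  if (!nrow(st)) stop("track set has no nonzero steps")
  angle_distribution(axial_angle(st$angle, ridge_angle), n_bins = n_bins)
}

#' Alignment of track steps with the local neurite orientation
#'
#' Each step is compared with the orientation-field angle at the masked
#' pixel nearest to the step midpoint; steps whose midpoint lies farther
#' than `max_dist` from the mask are excluded and tallied.
#'
#' @param tracks An `aw_tracks`.
#' @param orientation An `aw_orientation` from [orientation_field()].
#' @param max_dist Largest allowed midpoint-to-mask distance, px.
#' @param n_bins Histogram bins.
#' @return An `aw_angledist` with an extra field `n_excluded`.
#' @export
track_process_alignment <- function(tracks, orientation, max_dist = 10,
                                    n_bins = 20) {
  stopifnot(inherits(orientation, "aw_orientation"))
  st <- track_steps(tracks)
  st <- st[st$dist > 0, , drop = FALSE]
  if (!nrow(st)) stop("track set has no nonzero steps")
  idx <- which(!is.na(orientation$angle), arr.ind = TRUE)
  if (!nrow(idx)) stop("orientation field is empty")
  mx <- idx[, 2]; my <- idx[, 1]
  mid_x <- st$x0 + st$dx / 2
  mid_y <- st$y0 + st$dy / 2
  ang <- numeric(nrow(st)); dist <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    d2 <- (mx - mid_x[i])^2 + (my - mid_y[i])^2
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j])
    ang[i] <- orientation$angle[idx[j, 1], idx[j, 2]]
  }
  keep <- dist <= max_dist
  if (!any(keep)) stop("all steps farther than max_dist from the mask")
  out <- angle_distribution(axial_angle(st$angle[keep], ang[keep]),
                            n_bins = n_bins)
  out$n_excluded <- sum(!keep)
  out
}

#' 1-D Wasserstein distance between two CDFs on a shared grid
#'
#' `W1 = integral of |F - G|`, computed as the rectangle sum of the
#' absolute CDF difference times the bin width (CDFs are step functions on
#' the bins).
#'
#' @param F,G CDF vectors (non-decreasing, ending at 1) on the same bin
#'   edges.
#' @param bin_edges Shared grid edges (length `length(F) + 1`).
#' @return Nonnegative distance in the units of the grid.
#' @export
wasserstein_1d <- function(F, G, bin_edges) {
  if (length(F) != length(G))
    stop("CDF grids differ")
  stopifnot(length(bin_edges) == length(F) + 1)
  widths <- diff(bin_edges)
  sum(abs(F - G) * widths)
}

#' Empirical CDF of samples on a binned grid
#'
#' Helper producing the step CDF used by [wasserstein_1d()]: the value at
#' bin b is the fraction of samples `<=` the right edge of b.
#'
#' @param x Numeric samples.
#' @param bin_edges Grid edges.
#' @return CDF vector of length `length(bin_edges) - 1`.
#' @export
ecdf_on_grid <- function(x, bin_edges) {
  vapply(bin_edges[-1], function(e) mean(x <= e), numeric(1))
}

#' Aggregate per-video angle distributions into a CDF ensemble
#'
#' Per-bin median and quartile curves across videos; quantile curves can be
#' locally non-monotone and are rectified by a running maximum (raw
#' quantiles are kept alongside).
#'
#' @param dists List of `aw_angledist` on identical bins (one per video).
#' @return An `aw_cdf_ensemble`: `bin_edges`, `cdfs` (videos x bins),
#'   `median_cdf`, `q25_cdf`, `q75_cdf` (rectified), `raw` (unrectified
#'   quantiles), `n_videos`.
#' @export
aggregate_cdfs <- function(dists) {
  stopifnot(length(dists) >= 1,
            all(vapply(dists, inherits, logical(1), "aw_angledist")))
  edges <- dists[[1]]$bin_edges
  for (d in dists) stopifnot(identical(d$bin_edges, edges))
  cdfs <- do.call(rbind, lapply(dists, function(d) d$cdf))
  qs <- apply(cdfs, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  rect <- function(v) cummax(v)
  structure(list(bin_edges = edges, cdfs = cdfs,
                 median_cdf = rect(qs[2, ]), q25_cdf = rect(qs[1, ]),
                 q75_cdf = rect(qs[3, ]),
                 raw = list(q25 = qs[1, ], median = qs[2, ], q75 = qs[3, ]),
                 n_videos = length(dists)),
            class = "aw_cdf_ensemble")
}

#' Wasserstein comparison of two condition ensembles
#'
#' Distance between the median CDFs, and the minimum and maximum distances
#' over the four pairings of the 25th/75th percentile CDFs, reported in the
#' "median (minimum to maximum)" convention.
#'
#' @param a,b `aw_cdf_ensemble` objects on the same bins.
#' @return An `aw_w1` list: `w1_median`, `w1_min`, `w1_max`, `pairings`.
#'   With a single video in either condition the extremes are degenerate and
#'   flagged.
#' @export
w1_between <- function(a, b) {
  stopifnot(inherits(a, "aw_cdf_ensemble"), inherits(b, "aw_cdf_ensemble"),
            identical(a$bin_edges, b$bin_edges))
  e <- a$bin_edges
  combos <- expand.grid(qa = c("q25_cdf", "q75_cdf"),
                        qb = c("q25_cdf", "q75_cdf"),
                        stringsAsFactors = FALSE)
  w <- vapply(seq_len(nrow(combos)), function(i)
    wasserstein_1d(a[[combos$qa[i]]], b[[combos$qb[i]]], e), numeric(1))
  structure(list(w1_median = wasserstein_1d(a$median_cdf, b$median_cdf, e),
                 w1_min = min(w), w1_max = max(w),
                 pairings = cbind(combos, w1 = w),
                 degenerate = a$n_videos < 2 || b$n_videos < 2),
            class = "aw_w1")
}

#' @export
print.aw_w1 <- function(x, ...) {
  cat(sprintf("W1: %.3g (%.3g to %.3g)%s\n", x$w1_median, x$w1_min, x$w1_max,
              if (x$degenerate) " [single-video condition: extremes degenerate]" else ""))
  invisible(x)
}
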