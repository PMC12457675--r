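# Base-graphics figure analogues: track overlays, flow quivers,
# distribution curves.

#' Plot track overlays
#'
#' Draws each trajectory in its own colour over an optional background
#' image, the standard way a tracked movie is eyeballed.
#'
#' @param x An `aw_tracks`.
#' @param background Optional matrix drawn as a grayscale image underlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aw_tracks <- function(x, background = NULL, ...) {
  if (!is.null(background)) {
    graphics::image(t(background)[, nrow(background):1],
                    col = grDevices::gray.colors(64), axes = FALSE,
                    useRaster = TRUE)
    graphics::par(new = TRUE)
  }
  ids <- unique(x$track)
  cols <- grDevices::rainbow(max(length(ids), 1))
  graphics::plot(NA, xlim = range(x$x, 0, 1), ylim = rev(range(x$y, 0, 1)),
                 xlab = "x (px)", ylab = "y (px)", asp = 1, ...)
  for (i in seq_along(ids)) {
    tt <- x[x$track == ids[i], ]
    graphics::lines(tt$x, tt$y, col = cols[i])
  }
  invisible(x)
}

#' Quiver plot of one flow field
#'
#' @param flow An `aw_flow` (single frame pair).
#' @param stride Plot every `stride`-th valid vector.
#' @param scale Arrow length multiplier.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_flow <- function(flow, stride = 4, scale = 3, ...) {
  stopifnot(inherits(flow, "aw_flow"))
  idx <- which(flow$valid, arr.ind = TRUE)
  idx <- idx[idx[, 1] %% stride == 0 & idx[, 2] %% stride == 0, , drop = FALSE]
  graphics::plot(NA, xlim = c(1, ncol(flow$u)), ylim = c(nrow(flow$u), 1),
                 xlab = "x (px)", ylab = "y (px)", asp = 1, ...)
  if (nrow(idx)) {
    u <- flow$u[idx]; v <- flow$v[idx]
    nz <- sqrt(u^2 + v^2) > 0
    graphics::arrows(idx[nz, 2], idx[nz, 1],
                     idx[nz, 2] + scale * u[nz], idx[nz, 1] + scale * v[nz],
                     length = 0.03, col = "steelblue")
  }
  invisible(flow)
}

#' Plot an axial-angle distribution with its uniform reference
#'
#' @param x An `aw_angledist`.
#' @param cdf Draw the CDF instead of the PDF.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aw_angledist <- function(x, cdf = FALSE, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  if (cdf) {
    graphics::plot(mids, x$cdf, type = "s", xlab = "alignment angle (deg)",
                   ylab = "CDF", ylim = c(0, 1), ...)
  } else {
    graphics::plot(mids, x$pdf, type = "h", xlab = "alignment angle (deg)",
                   ylab = "fraction of steps", ...)
    graphics::abline(h = 1 / length(x$pdf), lty = 2)
  }
  invisible(x)
}
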