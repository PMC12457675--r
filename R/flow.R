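# Gaussian-weighted Lucas-Kanade optical flow with reliability gating.
#
# For each pixel the 2x2 weighted least-squares system over spatial image
# gradients is solved with a Gaussian weight centred at the pixel; the
# confidence ("reliability") of the solution is the smaller eigenvalue of
# the weighted structure tensor, normalised by its image-wide maximum so the
# gating threshold is intensity-scale-free.

#' Optical-flow configuration
#'
#' @param weight_sigma Gaussian weighting sigma, px (0.72 um at default
#'   calibration). The window is truncated at 3 sigma.
#' @param reliability_threshold Pixels with normalised reliability below this
#'   are flagged invalid.
#' @return An `aw_flow_config` list.
#' @export
flow_config <- function(weight_sigma = 2, reliability_threshold = 0.1) {
  stopifnot(weight_sigma > 0, reliability_threshold >= 0)
  structure(list(weight_sigma = weight_sigma,
                 reliability_threshold = reliability_threshold),
            class = "aw_flow_config")
}

gaussian_brush <- function(sigma) {
  size <- 2 * ceiling(3 * sigma) + 1
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  k / sum(k)
}

conv2 <- function(m, kernel) {
  EBImage::filter2(m, kernel, boundary = "replicate")
}

# central-difference spatial gradients; x = column, y = row
gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]; gx[, W] <- m[, W] - m[, W - 1]
  gy[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]; gy[H, ] <- m[H, ] - m[H - 1, ]
  list(gx = gx, gy = gy)
}

#' Lucas-Kanade flow between two frames
#'
#' Spatial gradients are central differences on the average of the two
#' frames (symmetric in the pair); the temporal derivative is the two-frame
#' difference. Border pixels within the weighting window half-width are
#' invalid.
#'
#' @param frame_a,frame_b Equal-sized numeric matrices.
#' @param config An [flow_config()].
#' @return An `aw_flow` list for one frame pair: `u`, `v` (px/frame; NA where
#'   invalid), `reliability` (in `[0, 1]`), `valid` (logical matrix).
#' @export
lucas_kanade <- function(frame_a, frame_b, config = flow_config()) {
  stopifnot(identical(dim(frame_a), dim(frame_b)),
            all(is.finite(frame_a)), all(is.finite(frame_b)))
  g <- gradients((frame_a + frame_b) / 2)
  It <- frame_b - frame_a
  k <- gaussian_brush(config$weight_sigma)
  Jxx <- conv2(g$gx * g$gx, k)
  Jxy <- conv2(g$gx * g$gy, k)
  Jyy <- conv2(g$gy * g$gy, k)
  Jxt <- conv2(g$gx * It, k)
  Jyt <- conv2(g$gy * It, k)
  det <- Jxx * Jyy - Jxy^2
  tr <- Jxx + Jyy
  lam_min <- pmax((tr - sqrt(pmax((Jxx - Jyy)^2 + 4 * Jxy^2, 0))) / 2, 0)
  mx <- max(lam_min)
  reliability <- if (mx > 0) lam_min / mx else lam_min
  valid <- reliability >= config$reliability_threshold & det > 0
  half <- ceiling(3 * config$weight_sigma)
  H <- nrow(frame_a); W <- ncol(frame_a)
  if (H > 2 * half && W > 2 * half) {
    border <- matrix(TRUE, H, W)
    border[(half + 1):(H - half), (half + 1):(W - half)] <- FALSE
    valid[border] <- FALSE
  } else valid[] <- FALSE
  u <- (-Jxt * Jyy + Jyt * Jxy) / det
  v <- (-Jyt * Jxx + Jxt * Jxy) / det
  u[!valid] <- NA_real_
  v[!valid] <- NA_real_
  structure(list(u = u, v = v, reliability = reliability, valid = valid,
                 config = config),
            class = "aw_flow")
}

#' Optical flow for every successive frame pair of a movie
#'
#' @param movie A preprocessed `aw_movie`.
#' @param config An [flow_config()].
#' @return An `aw_flow_movie`: list with per-pair fields `u`, `v`,
#'   `reliability` (arrays `H x W x (T-1)`), `valid`, and the config.
#' @export
flow_movie <- function(movie, config = flow_config()) {
  stopifnot(inherits(movie, "aw_movie"))
  fr <- movie$frames
  T <- dim(fr)[3]
  H <- dim(fr)[1]; W <- dim(fr)[2]
  u <- array(NA_real_, c(H, W, T - 1)); v <- u
  rel <- array(0, c(H, W, T - 1))
  val <- array(FALSE, c(H, W, T - 1))
  for (t in seq_len(T - 1)) {
    f <- lucas_kanade(fr[, , t], fr[, , t + 1], config)
    u[, , t] <- f$u; v[, , t] <- f$v
    rel[, , t] <- f$reliability; val[, , t] <- f$valid
  }
  structure(list(u = u, v = v, reliability = rel, valid = val, config = config,
                 calibration = movie$calibration),
            class = "aw_flow_movie")
}
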