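# Stage-drift registration, photobleach correction and 5-frame temporal
# smoothing. Order is fixed as register -> bleach -> smooth and recorded in
# the preprocessing report.

# integer translation (dx, dy) of frame b that best aligns it to ref,
# by FFT cross-correlation on mean-subtracted frames
xcorr_shift <- function(ref, b) {
  a <- ref - mean(ref); bb <- b - mean(b)
  if (sum(a^2) == 0 || sum(bb^2) == 0) return(c(0L, 0L, degenerate = 1L))
  H <- nrow(a); W <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(bb)), inverse = TRUE))
  idx <- which.max(cc)
  iy <- (idx - 1) %% H; ix <- (idx - 1) %/% H
  # map circular lags into [-N/2, N/2)
  dy <- if (iy > H / 2) iy - H else iy
  dx <- if (ix > W / 2) ix - W else ix
  c(as.integer(dx), as.integer(dy), degenerate = 0L)
}

#' Register a movie to its first frame
#'
#' Translation-only, integer-resolution registration by cross-correlation:
#' each frame is shifted to align with frame 1; pixels shifted in from
#' outside the field are filled with the frame median. Constant (featureless)
#' frames get zero shift and raise the `degenerate` flag.
#'
#' @param movie An `aw_movie`.
#' @param max_shift Largest |shift| accepted per axis, px; larger estimates
#'   are clamped to 0 (treated as spurious).
#' @return List: `movie` (registered), `shifts` (data.frame frame, dx, dy of
#'   the applied correction), `degenerate` (logical flag).
#' @export
register_movie <- function(movie, max_shift = 16) {
  stopifnot(inherits(movie, "aw_movie"))
  fr <- movie$frames
  T <- dim(fr)[3]
  shifts <- matrix(0L, T, 2)
  degen <- FALSE
  ref <- fr[, , 1]
  for (t in 2:T) {
    s <- xcorr_shift(ref, fr[, , t])
    if (s[3] == 1L) { degen <- TRUE; next }
    dx <- s[1]; dy <- s[2]   # cross-correlation peak is already the correction
    if (abs(dx) > max_shift || abs(dy) > max_shift) next
    if (dx != 0 || dy != 0) {
      fr[, , t] <- shift_frame(fr[, , t], dx, dy,
                               fill = stats::median(fr[, , t]))
      shifts[t, ] <- c(dx, dy)
    }
  }
  if (degen) warning("constant frame(s): registration skipped for those frames")
  out <- movie
  out$frames <- fr
  list(movie = out,
       shifts = data.frame(frame = seq_len(T), dx = shifts[, 1], dy = shifts[, 2]),
       degenerate = degen)
}

#' Correct photobleaching by mean matching
#'
#' Rescales every frame so its mean intensity equals that of the first
#' frame, the simplest monotone correction; an exponential bleach
#' `exp(-k t)` is undone exactly.
#'
#' @param movie An `aw_movie`.
#' @return List: `movie` (corrected), `bleach_scale` (per-frame multiplier).
#' @export
correct_bleach <- function(movie) {
  stopifnot(inherits(movie, "aw_movie"))
  fr <- movie$frames
  T <- dim(fr)[3]
  means <- apply(fr, 3, mean)
  if (any(means <= 0)) stop("frame with nonpositive mean intensity")
  scale <- means[1] / means
  for (t in seq_len(T)) fr[, , t] <- fr[, , t] * scale[t]
  out <- movie
  out$frames <- fr
  list(movie = out, bleach_scale = scale)
}

#' Gaussian kernel over a window of frames
#' @param window Odd number of taps.
#' @param sigma SD in frames.
#' @return Normalised weights summing to 1.
#' @export
temporal_kernel <- function(window = 5, sigma = 1) {
  stopifnot(window %% 2 == 1, sigma > 0)
  h <- (window - 1) / 2
  w <- exp(-(-h:h)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Temporal Gaussian smoothing
#'
#' Convolves each pixel's time series with a normalised Gaussian kernel
#' (default 5 taps, sigma = 1 frame, i.e. a 10 s support at 2 s/frame —
#' well below the >= 14 s persistence scale the track filter enforces).
#' Time boundaries are handled by mirror reflection; spatial content is
#' untouched.
#'
#' @param movie An `aw_movie` with at least `window` frames.
#' @param window Odd kernel support in frames.
#' @param sigma Kernel SD in frames.
#' @return The smoothed `aw_movie`.
#' @export
smooth_temporal <- function(movie, window = 5, sigma = 1) {
  stopifnot(inherits(movie, "aw_movie"))
  fr <- movie$frames
  T <- dim(fr)[3]
  if (T < window) stop("movie shorter than the smoothing window")
  w <- temporal_kernel(window, sigma)
  h <- (window - 1) / 2
  out <- array(0, dim = dim(fr))
  for (k in -h:h) {
    idx <- seq_len(T) + k
    idx[idx < 1] <- 2 - idx[idx < 1]         # mirror: 0 -> 2, -1 -> 3
    idx[idx > T] <- 2 * T - idx[idx > T]
    out <- out + w[k + h + 1] * fr[, , idx, drop = FALSE]
  }
  res <- movie
  res$frames <- out
  res
}

#' Full preprocessing chain: register, bleach-correct, smooth
#'
#' @param movie An `aw_movie`.
#' @param window,sigma Temporal smoothing parameters.
#' @param max_shift Registration search bound, px.
#' @return List: `movie` (preprocessed) and `report` with the applied
#'   `shifts`, `bleach_scale`, `smoothing_kernel` and the stage order.
#' @export
preprocess_movie <- function(movie, window = 5, sigma = 1, max_shift = 16) {
  reg <- register_movie(movie, max_shift = max_shift)
  bl <- correct_bleach(reg$movie)
  sm <- smooth_temporal(bl$movie, window = window, sigma = sigma)
  list(movie = sm,
       report = list(order = c("register", "bleach", "smooth"),
                     shifts = reg$shifts, degenerate = reg$degenerate,
                     bleach_scale = bl$bleach_scale,
                     smoothing_kernel = temporal_kernel(window, sigma)))
}
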