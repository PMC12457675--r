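#' Single-channel time-lapse movie
#'
#' The central container of the package: a 3-D array of nonnegative
#' fluorescence intensities indexed `[row, column, frame]`, together with its
#' physical calibration. Intensities are held as doubles regardless of the
#' acquisition bit depth.
#'
#' Coordinate convention used throughout the package: `x` is the column index
#' and `y` the row index, both 1-based with pixel centres at integer values;
#' frames are 1-based. Angles are measured in degrees from the +x axis towards
#' +y (rows increase downwards); axial quantities (ridges, process
#' orientations) live on `[0, 180)` and alignment differences are folded into
#' `[0, 90]`.
#'
#' @param frames Numeric array `[H, W, T]` (or a list of equally sized
#'   matrices) with `T >= 2`; all values finite and >= 0.
#' @param pixel_size,frame_interval Physical calibration, see [calibration()].
#' @param name Identifier used in reports.
#' @return An object of class `aw_movie` with fields `frames`, `calibration`,
#'   `name`.
#' @export
movie <- function(frames, pixel_size = 0.36, frame_interval = 2, name = "movie") {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1L, all(vapply(frames, is.matrix, logical(1))))
    d <- dim(frames[[1]])
    stopifnot(all(vapply(frames, function(m) identical(dim(m), d), logical(1))))
    frames <- array(unlist(frames, use.names = FALSE), dim = c(d, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 2L)
    stop("a movie needs at least 2 frames")
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames)))
    stop("movie intensities must all be finite")
  if (any(frames < 0))
    stop("movie intensities must be nonnegative")
  structure(list(frames = frames,
                 calibration = calibration(pixel_size, frame_interval),
                 name = as.character(name)[1]),
            class = "aw_movie")
}

#' @export
print.aw_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie '%s': %d frames of %d x %d px, %.4g um/px, %.4g s/frame\n",
              x$name, d[3], d[1], d[2],
              x$calibration$pixel_size, x$calibration$frame_interval))
  invisible(x)
}

#' @export
dim.aw_movie <- function(x) dim(x$frames)

n_frames <- function(movie) dim(movie$frames)[3]

#' Load a single-channel multi-frame TIFF as a movie
#'
#' Frames are returned in acquisition order. Integer-valued TIFFs (8/16-bit)
#' are read bit-exactly; float TIFFs written by [save_movie()] are rescaled
#' back to their original range using the sidecar scale file when present.
#'
#' @param path Path to a readable grayscale multi-frame TIFF.
#' @param calibration An [calibration()] object.
#' @param name Movie identifier; defaults to the file name.
#' @return An `aw_movie`.
#' @export
load_movie <- function(path, calibration = actinwaves::calibration(),
                       name = basename(path)) {
  if (!file.exists(path)) stop("cannot read movie file: ", path)
  raw <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  if (length(raw) < 2L) stop("movie TIFF has fewer than 2 frames: ", path)
  if (any(vapply(raw, function(m) length(dim(m)) != 2L, logical(1))))
    stop("multi-channel TIFF not supported (expected one grayscale channel)")
  bits <- attr(raw[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (bits <= 16L) {
    # readTIFF normalises unsigned integers to [0, 1]; undo it bit-exactly
    raw <- lapply(raw, function(m) round(m * (2^bits - 1)))
  }                                  # 32-bit float frames arrive as stored
  scale_file <- paste0(path, ".scale.json")
  if (file.exists(scale_file)) {
    sc <- jsonlite::read_json(scale_file, simplifyVector = TRUE)
    raw <- lapply(raw, function(m) m * sc$scale + sc$offset)
  }
  movie(raw, calibration$pixel_size, calibration$frame_interval, name = name)
}

#' Write a movie to a multi-frame TIFF
#'
#' Movies whose intensities are integers in `[0, 65535]` (the native range of
#' the 16-bit acquisition this data model emulates, and what the synthetic
#' camera produces) are written as 16-bit and round-trip bit-exactly through
#' [load_movie()]. Other movies are range-normalised to `[0, 1]`, written as
#' 32-bit float, and the affine scale is recorded in a `.scale.json` sidecar
#' (round trip then exact to float32 precision).
#'
#' @param movie An `aw_movie`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
save_movie <- function(movie, path) {
  stopifnot(inherits(movie, "aw_movie"))
  fr <- movie$frames
  lst <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t])
  int_like <- max(abs(fr - round(fr))) == 0 && max(fr) <= 65535
  scale_file <- paste0(path, ".scale.json")
  if (int_like) {
    tiff::writeTIFF(lapply(lst, function(m) m / 65535), path, bits.per.sample = 16L)
    if (file.exists(scale_file)) unlink(scale_file)
  } else {
    lo <- min(fr); hi <- max(fr)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF(lapply(lst, function(m) (m - lo) / scale), path,
                    bits.per.sample = 32L)
    jsonlite::write_json(list(scale = scale, offset = lo), scale_file,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
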