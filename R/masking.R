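# Neuronal process mask and orientation field, built from the temporal mean
# frame: optional contrast-limited equalisation, white top-hat, adaptive
# local thresholding, iterative opening, largest-component selection,
# cell-body exclusion, and a rotating elongated Laplacian-of-Gaussian
# orientation estimate.

#' Temporal mean frame of a movie
#' @param movie An `aw_movie`.
#' @return Matrix of per-pixel temporal means.
#' @export
mean_frame <- function(movie) {
  stopifnot(inherits(movie, "aw_movie"))
  apply(movie$frames, c(1, 2), mean)
}

#' Contrast-limited adaptive histogram equalisation for low-contrast images
#'
#' Applies CLAHE only when the image's contrast ratio
#' `(p99 - p1) / dynamic_range` falls below `contrast_threshold`; otherwise
#' the image is returned unchanged (bit-exact pass-through).
#'
#' @param image Grayscale matrix.
#' @param contrast_threshold Ratio below which the image counts as
#'   low-contrast.
#' @param dynamic_range Reference intensity range; defaults to the image
#'   maximum (so a narrow band riding on a high baseline counts as
#'   low-contrast).
#' @param nx,ny CLAHE tile grid.
#' @param clip_limit CLAHE clip limit.
#' @return The (possibly equalised) image, on the input intensity scale.
#' @export
enhance_if_low_contrast <- function(image, contrast_threshold = 0.05,
                                    dynamic_range = NULL, nx = 8, ny = 8,
                                    clip_limit = 2) {
  stopifnot(is.matrix(image))
  q <- stats::quantile(image, c(0.01, 0.99), names = FALSE)
  if (is.null(dynamic_range)) dynamic_range <- max(image, 1e-12)
  if ((q[2] - q[1]) / dynamic_range >= contrast_threshold) return(image)
  norm <- pmin(pmax(image / dynamic_range, 0), 1)
  eq <- EBImage::clahe(EBImage::Image(norm), nx = nx, ny = ny,
                       limit = clip_limit)
  as.matrix(EBImage::imageData(eq)) * dynamic_range
}

#' Build the binary neuronal-process mask
#'
#' White top-hat with a disk structuring element (radius 15 px = 5.4 um at
#' default calibration) isolates thin bright processes, adaptive local-mean
#' thresholding binarises them, iterative binary opening with a 3 x 3 cross
#' removes speckle, and the `n_components` largest connected components are
#' retained.
#'
#' @param image Enhanced grayscale matrix (e.g. from
#'   [enhance_if_low_contrast()] of [mean_frame()]).
#' @param tophat_radius Disk radius, px.
#' @param threshold_block Side of the local-mean window, px (odd).
#' @param threshold_offset Added to the local mean before comparison,
#'   intensity units.
#' @param n_open_iter Binary opening iterations.
#' @param n_components Number of largest components kept.
#' @return Logical matrix. Errors if no foreground survives.
#' @export
build_process_mask <- function(image, tophat_radius = 15, threshold_block = 51,
                               threshold_offset = 0, n_open_iter = 2,
                               n_components = 1) {
  stopifnot(is.matrix(image), tophat_radius >= 1, threshold_block %% 2 == 1)
  disk <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
  th <- EBImage::whiteTopHat(image, disk)
  half <- (threshold_block - 1) / 2
  bin <- EBImage::thresh(th, w = half, h = half, offset = threshold_offset)
  cross <- EBImage::makeBrush(3, shape = "diamond")
  for (i in seq_len(n_open_iter)) bin <- EBImage::opening(bin, cross)
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(as.integer(lab))
  if (length(sizes) == 0 || all(sizes == 0))
    stop("empty mask after filtering: no structure above the local threshold",
         " (top-hat radius ", tophat_radius, ", block ", threshold_block,
         ", offset ", threshold_offset, ")")
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(n_components, sum(sizes > 0)))]
  matrix(as.integer(lab) %in% keep, nrow(image), ncol(image))
}

#' Exclude the cell body from a process mask
#'
#' @param mask Logical process mask.
#' @param cell_body Logical mask of the manually annotated soma region (same
#'   shape).
#' @param calibration For the physical area.
#' @return An `aw_neuron_mask` list: `process_mask`, `cell_body_mask`,
#'   `area_px`, `area_um2`.
#' @export
exclude_cell_body <- function(mask, cell_body,
                              calibration = actinwaves::calibration()) {
  stopifnot(identical(dim(mask), dim(cell_body)))
  mask <- mask > 0; cell_body <- cell_body > 0
  out <- mask & !cell_body
  if (sum(mask) > 0 && sum(out) == 0)
    stop("cell-body annotation covers the entire mask")
  structure(list(process_mask = out, cell_body_mask = cell_body,
                 area_px = sum(out),
                 area_um2 = sum(out) * calibration$pixel_size^2),
            class = "aw_neuron_mask")
}

# elongated LoG ridge-detection kernel at axial angle theta (degrees):
# second derivative across the short axis of an anisotropic Gaussian,
# negated so a bright ridge aligned with theta responds positively,
# zero-mean normalised.
log_kernel <- function(theta_deg, sigma = 2, elongation = 3) {
  sl <- sigma * elongation; sn <- sigma
  r <- ceiling(3 * sl)
  xs <- -r:r
  th <- theta_deg * pi / 180
  l <- outer(sin(th) * xs, cos(th) * xs, "+")       # rows=y offset, cols=x
  n <- outer(cos(th) * xs, -sin(th) * xs, "+")
  g <- exp(-l^2 / (2 * sl^2) - n^2 / (2 * sn^2))
  k <- (1 - n^2 / sn^2) * g
  k <- k - mean(k)
  k / sum(abs(k))
}

#' Orientation field of the neuronal processes
#'
#' Convolves the mean image with an elongated Laplacian-of-Gaussian ridge
#' kernel at `n_angles` axial orientations evenly spanning `[0, 180)`; each
#' masked pixel is assigned the angle of maximal response (ties to the
#' smallest angle). Pixels whose response varies little across angles are
#' flagged low-confidence.
#'
#' @param mean_image Grayscale matrix.
#' @param mask Logical process mask.
#' @param n_angles Number of orientations (default 36, i.e. 5 degree steps).
#' @param log_sigma Kernel sigma across the ridge, px.
#' @param elongation Long/short axis ratio of the kernel.
#' @param anisotropy_floor Minimum relative response spread
#'   `(max - min) / (|max| + |min| + eps)` for a confident estimate;
#'   isotropic structure scores near 0, a clean ridge near 1.
#' @return An `aw_orientation` list: `angle` (degrees `[0, 180)`, NA off the
#'   mask), `response`, `low_confidence` (logical), `angles` (the grid).
#' @export
orientation_field <- function(mean_image, mask, n_angles = 36, log_sigma = 2,
                              elongation = 3, anisotropy_floor = 0.3) {
  stopifnot(is.matrix(mean_image), identical(dim(mean_image), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  best <- matrix(-Inf, nrow(mean_image), ncol(mean_image))
  worst <- matrix(Inf, nrow(mean_image), ncol(mean_image))
  arg <- matrix(NA_real_, nrow(mean_image), ncol(mean_image))
  for (a in angles) {
    resp <- conv2(mean_image, log_kernel(a, log_sigma, elongation))
    sel <- resp > best + 1e-12          # strict: ties keep the smaller angle
    arg[sel] <- a
    best[sel] <- resp[sel]
    worst <- pmin(worst, resp)
  }
  aniso <- (best - worst) / (abs(best) + abs(worst) + 1e-9)
  low <- aniso < anisotropy_floor
  arg[!mask] <- NA_real_
  structure(list(angle = arg, response = best, low_confidence = low & mask,
                 angles = angles),
            class = "aw_orientation")
}
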