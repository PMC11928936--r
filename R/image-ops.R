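# Deterministic image transformations shared by all analysis stages.

#' Maximum intensity projection
#'
#' Projects a z-stack (or any plane stack) to a 2D image by the per-pixel
#' maximum over planes. Calibration is carried along as attributes.
#'
#' @param stack An [image_stack()] or a `(ny, nx, nplanes)` array; a matrix is
#'   treated as an already-projected single plane (idempotent).
#' @return Numeric matrix `(ny, nx)` with attribute `pixel_size_um` when the
#'   input carried calibration.
#' @export
max_intensity_projection <- function(stack) {
  arr <- as_stack_array(stack)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  if (!is.array(arr) || length(dim(arr)) != 3L || any(dim(arr) == 0))
    stop("stack must have at least one plane", call. = FALSE)
  d <- dim(arr)
  mip <- arr[, , 1]
  if (d[3] > 1L) for (k in 2:d[3]) mip <- pmax(mip, arr[, , k])
  if (inherits(stack, "image_stack"))
    attr(mip, "pixel_size_um") <- stack$pixel_size_um
  mip
}

#' Photobleaching correction by reference-region normalization
#'
#' Rescales every frame of a time series so that the mean intensity inside the
#' reference region equals that of the first frame. This is exact (to machine
#' precision) for any global multiplicative decay, with no assumption about
#' its functional form.
#'
#' @param series An [image_stack()] over t, or a `(ny, nx, nt)` array.
#' @param reference_mask A [nucleus_roi()] or a logical matrix (the
#'   whole-nucleus region used as the bleaching reference).
#' @return List with `corrected` (same type as the input) and `gains`
#'   (per-frame multiplicative factors; `gains[1]` is 1).
#' @export
correct_photobleaching <- function(series, reference_mask) {
  arr <- as_stack_array(series)
  if (!is.array(arr) || length(dim(arr)) != 3L || dim(arr)[3] < 2L)
    stop("series must have at least two frames", call. = FALSE)
  mask <- if (inherits(reference_mask, "nucleus_roi")) reference_mask$mask
          else reference_mask
  stopifnot(is.logical(mask), all(dim(mask) == dim(arr)[1:2]), any(mask))
  nt <- dim(arr)[3]
  means <- vapply(seq_len(nt), function(t) mean(arr[, , t][mask]), 0)
  if (any(means <= 0))
    stop("zero mean intensity in the reference region", call. = FALSE)
  gains <- means[1] / means
  out <- arr
  for (t in seq_len(nt)) out[, , t] <- arr[, , t] * gains[t]
  if (inherits(series, "image_stack")) {
    series$data <- out
    out <- series
  }
  list(corrected = out, gains = gains)
}

#' Crop the same nuclear region from two channels
#'
#' Applies identical crop geometry (the ROI bounding box) to a pair of
#' equal-shaped projected images, yielding the equal-sized nuclear crops used
#' for pixel-correlation analysis.
#'
#' @param image_a,image_b Numeric matrices of identical shape.
#' @param roi A [nucleus_roi()].
#' @return List with `crop_a` and `crop_b`.
#' @export
crop_paired_rois <- function(image_a, image_b, roi) {
  stopifnot(is.matrix(image_a), is.matrix(image_b),
            inherits(roi, "nucleus_roi"))
  if (!all(dim(image_a) == dim(image_b)))
    stop("channel images must share shape and calibration", call. = FALSE)
  bb <- roi$bbox
  if (bb["y1"] > nrow(image_a) || bb["x1"] > ncol(image_a))
    stop("ROI extends outside the image bounds", call. = FALSE)
  ys <- bb["y0"]:bb["y1"]; xs <- bb["x0"]:bb["x1"]
  list(crop_a = image_a[ys, xs, drop = FALSE],
       crop_b = image_b[ys, xs, drop = FALSE])
}

#' Segment nuclei on a projected image
#'
#' Plumbing segmentation for when ground-truth masks are not supplied: global
#' Otsu threshold, hole filling, light opening, distance-transform watershed
#' to split touching nuclei, and a minimum-area filter.
#'
#' @param mip 2D image (e.g. a DAPI or background-bearing channel MIP).
#' @param min_area_px Minimum object area kept, in pixels.
#' @return Integer label matrix (0 = background); may be empty.
#' @export
segment_nuclei <- function(mip, min_area_px = 400) {
  stopifnot(is.matrix(mip))
  # clip rare bright puncta so Otsu separates nuclei from background, not
  # foci from everything else
  clipped <- pmin(mip, stats::quantile(mip, 0.95))
  rng <- range(clipped)
  if (diff(rng) <= 0) return(matrix(0L, nrow(mip), ncol(mip)))
  sc <- (clipped - rng[1]) / diff(rng)
  img <- EBImage::gblur(EBImage::Image(sc), sigma = 2)
  thr <- EBImage::otsu(img)
  mask <- EBImage::fillHull(img > thr)
  mask <- EBImage::opening(mask, EBImage::makeBrush(5, "disc"))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = 3)
  lab <- matrix(as.integer(EBImage::imageData(labels)), nrow(mip), ncol(mip))
  keep <- which(tabulate(lab[lab > 0]) >= min_area_px)
  lab[!(lab %in% keep)] <- 0L
  # compact ids
  old <- sort(unique(lab[lab > 0]))
  if (length(old)) lab <- matrix(match(lab, old, nomatch = 0L),
                                 nrow(mip), ncol(mip))
  lab
}

# --- TIFF / label IO --------------------------------------------------------

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integer photon counts (must be < 65536).
#'
#' @param stack An [image_stack()] or array/matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  arr <- as_stack_array(stack)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  vals <- round(arr)
  if (max(vals) > 65535) stop("intensities exceed 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) vals[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path File path.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_um, z_step_um = 0.25,
                            kind = "z", channel = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , k] <- round(pg * 65535)
  }
  image_stack(arr, pixel_size_um, z_step_um = z_step_um, kind = kind,
              channel = channel)
}

#' Write / read a 16-bit label TIFF
#'
#' @param labels Integer matrix of nucleus labels.
#' @param path File path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  pg <- tiff::readTIFF(path)
  if (length(dim(pg)) == 3L) pg <- pg[, , 1]
  matrix(as.integer(round(pg * 65535)), nrow(pg), ncol(pg))
}
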