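#' Calibrated image stack
#'
#' A single-channel 3D intensity array with physical calibration. Planes along
#' the third dimension are either z-slices (`kind = "z"`) or time frames
#' (`kind = "t"`). Voxel indices are 1-based in `(y, x, plane)` order (the
#' native R matrix layout); physical positions in micrometres are measured
#' from the centre of voxel `(1, 1, 1)`.
#'
#' @param data Numeric array `(ny, nx, nplanes)` of non-negative intensities;
#'   a matrix is promoted to a single-plane stack.
#' @param pixel_size_um Lateral calibration, micrometres per pixel.
#' @param z_step_um Axial step between z-planes (ignored for time series).
#' @param frame_interval Frame spacing for time series, in arbitrary time
#'   units (minutes in the fusion workflow).
#' @param kind `"z"` for a z-stack, `"t"` for a time series.
#' @param channel Optional channel name.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, z_step_um = 0.25,
                        frame_interval = 1, kind = c("z", "t"),
                        channel = "ch1") {
  kind <- match.arg(kind)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a (ny, nx, nplanes) array", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(z_step_um, "z_step_um")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         frame_interval = frame_interval, kind = kind, channel = channel),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %s  %d x %d px, %d %s-planes, %.3g um/px\n",
              x$channel, d[1], d[2], d[3],
              x$kind, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_planes <- function(stack) dim(stack$data)[3]

as_stack_array <- function(x) {
  if (inherits(x, "image_stack")) x$data else x
}

#' Nucleus region of interest
#'
#' A per-cell binary mask on the projected frame, with its bounding box.
#'
#' @param mask Logical matrix, `TRUE` inside the nucleus.
#' @param cell_id Integer cell identifier.
#' @return An object of class `nucleus_roi` with fields `cell_id`, `mask`,
#'   and `bbox` (`y0, y1, x0, x1`, inclusive).
#' @export
nucleus_roi <- function(mask, cell_id = 1L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("nucleus mask is empty", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  structure(
    list(cell_id = as.integer(cell_id), mask = mask,
         bbox = c(y0 = min(idx[, 1]), y1 = max(idx[, 1]),
                  x0 = min(idx[, 2]), x1 = max(idx[, 2]))),
    class = "nucleus_roi")
}

#' Split a label image into per-cell nucleus ROIs
#'
#' @param labels Integer matrix; 0 is background, positive values are cell ids.
#' @return Named list of [nucleus_roi()] objects, one per non-empty label.
#' @export
rois_from_labels <- function(labels) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  out <- lapply(ids, function(id) nucleus_roi(labels == id, id))
  names(out) <- as.character(ids)
  out
}
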