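# Candidate detection, SBR scoring, empirical-null threshold calibration on
# mock cells, and per-cell foci counting.

#' Detection parameters
#'
#' @param psf_sigma_px Lateral PSF sigma in pixels; sets the LoG filter scale.
#' @param min_sep_px Minimum centre separation between candidates; ties
#'   between equal-response maxima are broken by smallest (y, x).
#' @param n_mads LoG response threshold in robust noise units (MADs of the
#'   in-nucleus response). Permissive enough that mock nuclei still yield
#'   noise candidates — required for empirical-null calibration.
#' @param mask_rel_level Spot mask level as a fraction of (peak - local
#'   background); a relative level keeps the masked fraction of a Gaussian
#'   spot's integral amplitude-independent.
#' @param bg_margin_px Dilation margin (pixels) applied to spot masks before
#'   they are excluded from the nucleoplasmic background region.
#' @param border_px Candidate centres must lie more than this many pixels
#'   inside the ROI boundary, where the nucleus/background intensity step
#'   would otherwise masquerade as blob response.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(psf_sigma_px = 1.5, min_sep_px = 3,
                          n_mads = 3.5, mask_rel_level = 0.3,
                          bg_margin_px = 2, border_px = 3) {
  stopifnot(psf_sigma_px > 0, min_sep_px >= 0, n_mads > 0,
            mask_rel_level > 0, mask_rel_level < 1, bg_margin_px >= 0,
            border_px >= 0)
  structure(list(psf_sigma_px = psf_sigma_px, min_sep_px = min_sep_px,
                 n_mads = n_mads, mask_rel_level = mask_rel_level,
                 bg_margin_px = bg_margin_px, border_px = border_px),
            class = "detect_params")
}

#' Parameters matched to a scene configuration
#' @param config A [scene_config()].
#' @param ... Overrides passed to [detect_params()].
#' @return A `detect_params` object with the LoG scale set to the config PSF.
#' @export
detect_params_for <- function(config, ...) {
  stopifnot(inherits(config, "scene_config"))
  args <- list(...)
  if (is.null(args$psf_sigma_px))
    args$psf_sigma_px <- config$psf_sigma_um[1] / config$pixel_size_um
  do.call(detect_params, args)
}

# Zero-mean scale-normalized Laplacian-of-Gaussian kernel, negated so bright
# blobs give positive response.
log_kernel <- function(sigma) {
  r <- max(ceiling(4 * sigma), 2)
  g <- expand.grid(y = -r:r, x = -r:r)
  rr2 <- g$y^2 + g$x^2
  k <- -(rr2 - 2 * sigma^2) / sigma^2 * exp(-rr2 / (2 * sigma^2))
  k <- matrix(k, 2 * r + 1, 2 * r + 1)
  k - mean(k)
}

# Strict 8-neighbour local maxima of a matrix (logical matrix out).
local_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  if (ny < 3 || nx < 3) return(matrix(FALSE, ny, nx))
  out <- matrix(FALSE, ny, nx)
  ci <- 2:(ny - 1); cj <- 2:(nx - 1)
  c0 <- m[ci, cj]
  out[ci, cj] <-
    c0 > m[ci - 1, cj] & c0 > m[ci + 1, cj] &
    c0 > m[ci, cj - 1] & c0 > m[ci, cj + 1] &
    c0 > m[ci - 1, cj - 1] & c0 > m[ci - 1, cj + 1] &
    c0 > m[ci + 1, cj - 1] & c0 > m[ci + 1, cj + 1]
  out
}

#' Detect candidate puncta in one nucleus
#'
#' Laplacian-of-Gaussian blob detection at the PSF scale inside a nucleus
#' ROI: local response maxima above a robust noise threshold, deduplicated by
#' a minimum centre separation, each given a connected spot mask by local
#' relative thresholding around its peak. Deterministic given its inputs.
#'
#' @param mip 2D projected image (numeric matrix).
#' @param roi A [nucleus_roi()].
#' @param params A [detect_params()].
#' @return Data frame of candidates (possibly empty): `cell_id`, `y_px`,
#'   `x_px` (intensity-weighted centroid), `peak` (maximum spot intensity,
#'   the SBR numerator), `area_px`, `integrated` (background-subtracted sum
#'   over the mask), `log_response`, and a list column `mask_px` of global
#'   linear pixel indices of the spot mask.
#' @export
detect_candidates <- function(mip, roi, params = detect_params()) {
  stopifnot(is.matrix(mip), inherits(roi, "nucleus_roi"),
            inherits(params, "detect_params"))
  if (!any(roi$mask)) stop("empty ROI", call. = FALSE)
  bb <- roi$bbox
  pad <- ceiling(4 * params$psf_sigma_px)
  ys <- max(1, bb["y0"] - pad):min(nrow(mip), bb["y1"] + pad)
  xs <- max(1, bb["x0"] - pad):min(ncol(mip), bb["x1"] + pad)
  sub <- mip[ys, xs, drop = FALSE]
  msub <- roi$mask[ys, xs, drop = FALSE]
  core <- msub
  if (params$border_px > 0) {
    brush <- EBImage::makeBrush(2 * params$border_px + 1, "disc")
    core <- matrix(as.logical(EBImage::imageData(
      EBImage::erode(EBImage::Image(msub), brush))), nrow(sub), ncol(sub))
    if (!any(core)) core <- msub
  }

  k <- log_kernel(params$psf_sigma_px)
  resp <- matrix(EBImage::imageData(
    EBImage::filter2(EBImage::Image(sub), k, boundary = "replicate")),
    nrow(sub), ncol(sub))

  sigma_hat <- stats::mad(resp[core])
  # absolute floors guard against FFT ripple maxima on noise-free images
  thr <- max(params$n_mads * sigma_hat, 0.02 * max(resp[core]), 1e-9)
  cand <- which(local_maxima(resp) & core & resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_candidates_df())

  o <- order(-resp[cand], cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    dmin <- min(sqrt((prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2))
    keep[i] <- dmin >= params$min_sep_px
  }
  cand <- cand[keep, , drop = FALSE]

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rows[[i]] <- spot_from_peak(sub, msub, cand[i, 1], cand[i, 2], params,
                                resp[cand[i, 1], cand[i, 2]])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_candidates_df())
  out <- do.call(rbind, rows)
  # lift subwindow coordinates/indices back to the full image
  out$y_px <- out$y_px + ys[1] - 1
  out$x_px <- out$x_px + xs[1] - 1
  out$peak_y <- out$peak_y + ys[1] - 1
  out$peak_x <- out$peak_x + xs[1] - 1
  out$mask_px <- lapply(out$mask_px, function(ij)
    cbind(ij[, 1] + ys[1] - 1, ij[, 2] + xs[1] - 1))
  out$mask_px <- lapply(out$mask_px, function(ij)
    as.integer(ij[, 1] + (ij[, 2] - 1) * nrow(mip)))
  out$cell_id <- roi$cell_id
  out[order(out$y_px, out$x_px),
      c("cell_id", "y_px", "x_px", "peak_y", "peak_x", "peak", "area_px",
        "integrated", "log_response", "mask_px")]
}

empty_candidates_df <- function() {
  out <- data.frame(cell_id = integer(), y_px = numeric(), x_px = numeric(),
                    peak_y = integer(), peak_x = integer(),
                    peak = numeric(), area_px = integer(),
                    integrated = numeric(), log_response = numeric())
  out$mask_px <- list()
  out
}

# Build the spot record around a LoG peak: recentre on the raw maximum,
# threshold the local window at bg + rel * (peak - bg), keep the connected
# component containing the peak.
spot_from_peak <- function(sub, msub, py, px_, params, log_resp) {
  wr <- ceiling(3 * params$psf_sigma_px) + 1
  ys <- max(1, py - 1):min(nrow(sub), py + 1)
  xs <- max(1, px_ - 1):min(ncol(sub), px_ + 1)
  loc <- which(sub[ys, xs] == max(sub[ys, xs]), arr.ind = TRUE)[1, ]
  py <- ys[loc[1]]; px_ <- xs[loc[2]]

  ys <- max(1, py - wr):min(nrow(sub), py + wr)
  xs <- max(1, px_ - wr):min(ncol(sub), px_ + wr)
  w <- sub[ys, xs, drop = FALSE]
  ring <- c(w[1, ], w[nrow(w), ], w[, 1], w[, ncol(w)])
  bg <- stats::median(ring)
  peak <- sub[py, px_]
  if (peak <= bg) return(NULL)
  level <- bg + params$mask_rel_level * (peak - bg)
  bin <- w >= level
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(w), ncol(w))
  id <- lab[py - ys[1] + 1, px_ - xs[1] + 1]
  if (id == 0) return(NULL)
  sel <- which(lab == id, arr.ind = TRUE)
  vals <- w[lab == id]
  wts <- pmax(vals - bg, 0)
  cy <- sum((sel[, 1] + ys[1] - 1) * wts) / sum(wts)
  cx <- sum((sel[, 2] + xs[1] - 1) * wts) / sum(wts)
  out <- data.frame(cell_id = NA_integer_, y_px = cy, x_px = cx,
                    peak_y = py, peak_x = px_,
                    peak = max(vals), area_px = length(vals),
                    integrated = sum(vals - bg), log_response = log_resp)
  out$mask_px <- list(cbind(sel[, 1] + ys[1] - 1, sel[, 2] + xs[1] - 1))
  out
}

#' Nucleoplasmic background estimate
#'
#' Mean intensity of the nucleus region excluding all candidate spot masks
#' dilated by a safety margin — the reproducible surrogate for a manually
#' drawn nucleoplasmic ROI outside of spots. This is the SBR denominator
#' F_nucleus.
#'
#' @param mip 2D projected image.
#' @param roi A [nucleus_roi()].
#' @param spots Candidate data frame from [detect_candidates()] (its
#'   `mask_px` column is used); may be empty.
#' @param margin_px Dilation margin in pixels.
#' @return List with `cell_id`, `f_nucleus` and `n_pixels`.
#' @export
estimate_background <- function(mip, roi, spots = NULL, margin_px = 2) {
  stopifnot(is.matrix(mip), inherits(roi, "nucleus_roi"))
  excl <- matrix(FALSE, nrow(mip), ncol(mip))
  if (!is.null(spots) && nrow(spots) > 0)
    excl[unlist(spots$mask_px)] <- TRUE
  if (any(excl) && margin_px > 0) {
    brush <- EBImage::makeBrush(2 * margin_px + 1, "disc")
    excl <- matrix(as.logical(EBImage::imageData(
      EBImage::dilate(EBImage::Image(excl), brush))), nrow(mip), ncol(mip))
  }
  sel <- roi$mask & !excl
  if (!any(sel))
    stop("spot masks cover the entire nucleus; no background region left",
         call. = FALSE)
  list(cell_id = roi$cell_id, f_nucleus = mean(mip[sel]),
       n_pixels = sum(sel))
}

#' Signal-to-background ratio
#'
#' The spot statistic: maximum spot intensity divided by the mean
#' nucleoplasmic intensity outside spots. Unitless; invariant under a global
#' positive gain applied to the image.
#'
#' @param f_candidate Maximum spot intensity (scalar or vector).
#' @param f_nucleus Mean nucleoplasmic background (scalar, > 0), or a
#'   background estimate from [estimate_background()].
#' @return Numeric SBR value(s).
#' @export
compute_sbr <- function(f_candidate, f_nucleus) {
  if (is.list(f_nucleus)) f_nucleus <- f_nucleus$f_nucleus
  if (!is.numeric(f_nucleus) || length(f_nucleus) != 1 || f_nucleus <= 0)
    stop("background must be a single positive value", call. = FALSE)
  stopifnot(is.numeric(f_candidate))
  f_candidate / f_nucleus
}

#' Calibrate the SBR threshold on mock cells
#'
#' The empirical-null cutoff: the maximum SBR observed among candidate spots
#' pooled across mock (focus-free) control cells. If the mock set yields no
#' candidates at all, the threshold falls back to a configured floor and the
#' fallback is flagged.
#'
#' @param mock_scores Numeric vector of SBR values from mock-cell candidates
#'   (may be empty).
#' @param n_mock_cells Number of mock cells analysed (must be >= 1).
#' @param floor Fallback threshold when no mock candidate exists.
#' @return A list of class `threshold_calibration`: `threshold`, `source`
#'   (sorted mock SBRs), `n_mock_cells`, `fallback`.
#' @export
calibrate_threshold <- function(mock_scores, n_mock_cells, floor = 1.0) {
  if (missing(n_mock_cells) || !is.numeric(n_mock_cells) || n_mock_cells < 1)
    stop("at least one analysed mock cell is required", call. = FALSE)
  stopifnot(is.numeric(mock_scores))
  fallback <- length(mock_scores) == 0
  structure(list(
    threshold = if (fallback) floor else max(mock_scores),
    source = sort(mock_scores),
    n_mock_cells = as.integer(n_mock_cells),
    fallback = fallback), class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> SBR > %.4g (%d mock cells, %d candidates%s)\n",
              x$threshold, x$n_mock_cells, length(x$source),
              if (x$fallback) ", FALLBACK floor" else ""))
  invisible(x)
}

#' Call foci from scored candidates
#'
#' A candidate becomes a focus call when its SBR is strictly greater than the
#' calibrated threshold (the mock maximum itself defines the null extreme and
#' must not be called). Cells without surviving candidates get a zero count.
#'
#' @param scored Data frame of candidates with at least `cell_id` and `sbr`
#'   columns (see [score_scene()]).
#' @param calibration A [calibrate_threshold()] result, or a bare numeric
#'   threshold (e.g. a user override such as 1.60).
#' @param cell_ids Universe of cell ids (so focus-free cells appear with
#'   count 0); defaults to the ids present in `scored`.
#' @return List of class `foci_callsets`: per-cell list entries with
#'   `cell_id`, `calls` (data frame of passing candidates) and `count`, plus
#'   attribute `threshold`.
#' @export
call_foci <- function(scored, calibration, cell_ids = NULL) {
  thr <- if (inherits(calibration, "threshold_calibration"))
    calibration$threshold else as.numeric(calibration)
  stopifnot(is.numeric(thr), length(thr) == 1)
  if (is.null(cell_ids)) cell_ids <- sort(unique(scored$cell_id))
  sets <- lapply(cell_ids, function(id) {
    calls <- scored[scored$cell_id == id & scored$sbr > thr, , drop = FALSE]
    list(cell_id = id, calls = calls, count = nrow(calls))
  })
  structure(sets, class = "foci_callsets", threshold = thr)
}

#' Per-cell focus counts from callsets
#' @param callsets A `foci_callsets` object.
#' @return Data frame with `cell_id` and `n_foci`.
#' @export
foci_counts <- function(callsets) {
  data.frame(cell_id = vapply(callsets, `[[`, 0L, "cell_id"),
             n_foci = vapply(callsets, function(s) as.integer(s$count), 0L))
}

#' Summarize per-cell foci counts as mean +/- SEM
#'
#' The figure-legend convention: mean and standard error of the mean of
#' per-cell counts.
#'
#' @param counts Numeric vector of per-cell counts, a data frame with an
#'   `n_foci` column, or a `foci_callsets` object.
#' @return List with `mean`, `sem`, `n_cells` and the per-cell `table`.
#' @export
summarize_counts <- function(counts) {
  if (inherits(counts, "foci_callsets")) counts <- foci_counts(counts)
  if (is.data.frame(counts)) {
    tab <- counts
    counts <- counts$n_foci
  } else {
    stopifnot(is.numeric(counts))
    tab <- data.frame(cell_id = seq_along(counts), n_foci = counts)
  }
  if (length(counts) < 1) stop("no cells supplied", call. = FALSE)
  sem <- if (length(counts) == 1) 0 else
    stats::sd(counts) / sqrt(length(counts))
  list(mean = mean(counts), sem = sem, n_cells = length(counts), table = tab)
}

# --- scene-level drivers ----------------------------------------------------

#' Detect and score all candidates of a projected scene
#'
#' Runs [detect_candidates()], [estimate_background()] and [compute_sbr()]
#' for every labelled nucleus of a projected field.
#'
#' @param mip 2D projected image.
#' @param labels Integer nucleus label matrix.
#' @param params A [detect_params()].
#' @return Data frame of scored candidates (columns of
#'   [detect_candidates()] plus `f_nucleus` and `sbr`), with attribute
#'   `cell_ids` holding the full id universe.
#' @export
score_scene <- function(mip, labels, params = detect_params()) {
  rois <- rois_from_labels(labels)
  out <- lapply(rois, function(roi) {
    cand <- detect_candidates(mip, roi, params)
    if (nrow(cand) == 0) return(NULL)
    bg <- estimate_background(mip, roi, cand, margin_px = params$bg_margin_px)
    cand$f_nucleus <- bg$f_nucleus
    cand$sbr <- compute_sbr(cand$peak, bg)
    cand
  })
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else {
    e <- empty_candidates_df(); e$f_nucleus <- numeric(); e$sbr <- numeric(); e
  }
  attr(res, "cell_ids") <- as.integer(names(rois))
  res
}

#' Calibrate the SBR threshold on one or more mock scenes
#'
#' Projects each mock scene, scores its candidates, and pools the SBRs across
#' all mock cells into a single empirical-null maximum.
#'
#' @param mock_scenes An `fs_scene` or list of `fs_scene` objects generated
#'   with [generate_mock_cells()].
#' @param params A [detect_params()].
#' @param floor Fallback threshold if the mock set yields no candidate.
#' @return A `threshold_calibration`.
#' @export
calibrate_on_mock <- function(mock_scenes, params = detect_params(),
                              floor = 1.0) {
  if (inherits(mock_scenes, "fs_scene")) mock_scenes <- list(mock_scenes)
  sbrs <- numeric(); n_cells <- 0L
  for (sc in mock_scenes) {
    mip <- max_intensity_projection(sc$channels[[1]])
    scored <- score_scene(mip, sc$nucleus_labels, params)
    sbrs <- c(sbrs, scored$sbr)
    n_cells <- n_cells + nrow(sc$truth$cells)
  }
  calibrate_threshold(sbrs, n_mock_cells = n_cells, floor = floor)
}

#' Count foci per cell in a scene
#'
#' The full per-scene counting pipeline: project, score, threshold, count.
#'
#' @param scene An `fs_scene` (or any list with `channels` and
#'   `nucleus_labels`).
#' @param calibration A `threshold_calibration` or numeric threshold.
#' @param params A [detect_params()].
#' @param channel Channel index to analyse.
#' @return Data frame with `cell_id` and `n_foci` for every cell.
#' @export
count_scene_foci <- function(scene, calibration, params = detect_params(),
                             channel = 1L) {
  mip <- max_intensity_projection(scene$channels[[channel]])
  scored <- score_scene(mip, scene$nucleus_labels, params)
  sets <- call_foci(scored, calibration, cell_ids = attr(scored, "cell_ids"))
  foci_counts(sets)
}
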