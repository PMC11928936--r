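# Two-channel colocalization: pixel-level Pearson correlation on equal-sized
# nuclear crops, and object-level spot matching with a physical distance
# criterion.

#' Pearson correlation between two nuclear crops
#'
#' Standard sample Pearson correlation over all pixels of a pair of
#' equal-sized crops (no intensity thresholding; background pixels included).
#'
#' @param crop_a,crop_b Numeric matrices of identical shape with >= 2 pixels.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_coefficient <- function(crop_a, crop_b) {
  stopifnot(is.matrix(crop_a), is.matrix(crop_b))
  if (!all(dim(crop_a) == dim(crop_b)))
    stop("crops must be equal-sized", call. = FALSE)
  if (length(crop_a) < 2) stop("need at least two pixels", call. = FALSE)
  if (stats::sd(crop_a) == 0 || stats::sd(crop_b) == 0)
    stop("Pearson r undefined: zero variance in a channel", call. = FALSE)
  stats::cor(as.vector(crop_a), as.vector(crop_b))
}

#' Match spots across two channels of one cell
#'
#' One-to-one greedy matching by ascending centre-to-centre distance among
#' candidate pairs within `max_distance_um` (spots further apart than the
#' matching radius — by default 0.5 um, i.e. separated by more than 500 nm —
#' are never paired). Deterministic: distance ties are broken by the
#' symmetric lexicographic order of the pair centroids.
#'
#' @param spots_a,spots_b Data frames with `y_px`, `x_px` columns (e.g. calls
#'   from one cell's [call_foci()] entry).
#' @param pixel_size_um Lateral calibration shared by both channels.
#' @param max_distance_um Matching radius, centre-to-centre, um.
#' @return A list of class `coloc_result`: `matched` (data frame `idx_a`,
#'   `idx_b`, `dist_um`), `unmatched_a`, `unmatched_b` (row indices),
#'   `n_a`, `n_b`.
#' @export
match_spots <- function(spots_a, spots_b, pixel_size_um,
                        max_distance_um = 0.5) {
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  na <- nrow(spots_a); nb <- nrow(spots_b)
  pairs <- NULL
  if (na > 0 && nb > 0) {
    d <- outer(spots_a$y_px, spots_b$y_px, `-`)^2 +
      outer(spots_a$x_px, spots_b$x_px, `-`)^2
    d <- sqrt(d) * pixel_size_um
    idx <- which(d <= max_distance_um, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      dist <- d[idx]
      key_y <- pmin(spots_a$y_px[idx[, 1]], spots_b$y_px[idx[, 2]])
      key_x <- pmin(spots_a$x_px[idx[, 1]], spots_b$x_px[idx[, 2]])
      o <- order(dist, key_y + key_x, key_y)
      used_a <- logical(na); used_b <- logical(nb)
      keep <- integer(0)
      for (k in o) {
        ia <- idx[k, 1]; ib <- idx[k, 2]
        if (!used_a[ia] && !used_b[ib]) {
          used_a[ia] <- TRUE; used_b[ib] <- TRUE
          keep <- c(keep, k)
        }
      }
      pairs <- data.frame(idx_a = idx[keep, 1], idx_b = idx[keep, 2],
                          dist_um = dist[keep])
      pairs <- pairs[order(pairs$dist_um, pairs$idx_a), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(idx_a = integer(), idx_b = integer(),
                        dist_um = numeric())
  structure(list(matched = pairs,
                 unmatched_a = setdiff(seq_len(na), pairs$idx_a),
                 unmatched_b = setdiff(seq_len(nb), pairs$idx_b),
                 n_a = na, n_b = nb),
            class = "coloc_result")
}

#' Cohort summary: % cells with colocalized / uncolocalized spots
#'
#' Denominator: cells containing at least one spot in each channel. A cell
#' with >= 1 matched pair counts as colocalized; a cell with >= 1 unmatched
#' spot in either channel counts as uncolocalized; the two percentages need
#' not sum to 100.
#'
#' @param results List of [match_spots()] results (one per cell).
#' @return List with `pct_cells_colocalized`, `pct_cells_uncolocalized`, and
#'   `n_cells_with_both_signals`.
#' @export
percent_cells_colocalized <- function(results) {
  stopifnot(is.list(results))
  eligible <- vapply(results, function(r) r$n_a > 0 && r$n_b > 0, TRUE)
  results <- results[eligible]
  n <- length(results)
  if (n == 0)
    stop("no cells contain spots in both channels", call. = FALSE)
  has_match <- vapply(results, function(r) nrow(r$matched) > 0, TRUE)
  has_unmatched <- vapply(results, function(r)
    length(r$unmatched_a) + length(r$unmatched_b) > 0, TRUE)
  list(pct_cells_colocalized = 100 * sum(has_match) / n,
       pct_cells_uncolocalized = 100 * sum(has_unmatched) / n,
       n_cells_with_both_signals = n)
}

#' Per-cell colocalization analysis of a two-channel scene
#'
#' For every nucleus: equal-sized crops of the two channel MIPs
#' ([crop_paired_rois()]) give the pixel Pearson r; the per-channel focus
#' calls are matched at the physical radius to give object-level counts.
#'
#' @param scene A two-channel `fs_scene`.
#' @param calibration Threshold (calibration object or numeric) used to call
#'   foci in both channels.
#' @param params A [detect_params()].
#' @param max_distance_um Object matching radius, um.
#' @return List with `per_cell` (data frame: `cell_id`, `pearson_r`,
#'   `n_matched`, `n_unmatched_a`, `n_unmatched_b`), `results` (per-cell
#'   [match_spots()] objects), and `summary` ([percent_cells_colocalized()]
#'   over eligible cells, or NULL if none).
#' @export
coloc_scene <- function(scene, calibration, params = detect_params(),
                        max_distance_um = 0.5) {
  stopifnot(length(scene$channels) == 2)
  px <- scene$channels[[1]]$pixel_size_um
  mip_a <- max_intensity_projection(scene$channels[[1]])
  mip_b <- max_intensity_projection(scene$channels[[2]])
  rois <- rois_from_labels(scene$nucleus_labels)
  scored_a <- score_scene(mip_a, scene$nucleus_labels, params)
  scored_b <- score_scene(mip_b, scene$nucleus_labels, params)
  ids <- attr(scored_a, "cell_ids")
  calls_a <- call_foci(scored_a, calibration, cell_ids = ids)
  calls_b <- call_foci(scored_b, calibration, cell_ids = ids)

  results <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    roi <- rois[[as.character(ids[i])]]
    crops <- crop_paired_rois(mip_a, mip_b, roi)
    r <- tryCatch(pearson_coefficient(crops$crop_a, crops$crop_b),
                  error = function(e) NA_real_)
    m <- match_spots(calls_a[[i]]$calls, calls_b[[i]]$calls, px,
                     max_distance_um)
    results[[i]] <- m
    rows[[i]] <- data.frame(cell_id = ids[i], pearson_r = r,
                            n_matched = nrow(m$matched),
                            n_unmatched_a = length(m$unmatched_a),
                            n_unmatched_b = length(m$unmatched_b))
  }
  per_cell <- do.call(rbind, rows)
  summary <- tryCatch(percent_cells_colocalized(results),
                      error = function(e) NULL)
  list(per_cell = per_cell, results = results, summary = summary)
}
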