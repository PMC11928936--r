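# Synthetic-scene generator: nuclei with diffraction-limited foci rendered as
# anisotropic 3D Gaussians on a nucleoplasmic background, Poisson + Gaussian
# noise, with a fully specified ground-truth record for every cell.

DARK_LEVEL <- 2  # extracellular offset, photons

#' Generate a synthetic multi-channel 3D scene with ground truth
#'
#' Places non-overlapping nuclei (perturbed ellipses) in the field by
#' rejection sampling, draws per-cell focus counts from Poisson(lambda),
#' places foci inside each nucleus with a minimum mutual separation, renders
#' them as 3D Gaussian puncta on a flat nucleoplasmic background, and applies
#' Poisson shot noise plus Gaussian read noise. Identical configs (including
#' seed) give bit-identical output.
#'
#' @param config A [scene_config()].
#' @param truth_only If `TRUE`, skip rendering and return only the ground
#'   truth (fast path for statistical calibration studies).
#' @return A list of class `fs_scene` with elements `channels` (list of
#'   [image_stack()]), `nucleus_labels` (integer matrix), `truth` (list with
#'   `cells` and `foci` data frames), and `config`.
#' @export
generate_scene <- function(config, truth_only = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config, truth_only))
}

generate_scene_impl <- function(cfg, truth_only) {
  shp <- cfg$image_shape
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
  px <- cfg$pixel_size_um

  nuc <- place_nuclei(cfg)
  labels <- nuc$labels

  sig_lat <- cfg$psf_sigma_um[1] / px
  sig_ax <- cfg$psf_sigma_um[2] / cfg$z_step_um
  z_lo <- 1 + 2 * sig_ax
  z_hi <- nz - 2 * sig_ax
  if (z_hi < z_lo) { z_lo <- z_hi <- (1 + nz) / 2 }

  amp_floor <- 5 * sqrt(cfg$background_level)
  foci <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    k <- stats::rpois(1, cfg$foci_per_cell_mean)
    if (k == 0) { foci[[i]] <- NULL; next }
    pos <- place_foci_in_nucleus(nuc$allowed[[i]], k,
                                 cfg$min_focus_sep_um / px)
    amp <- pmax(stats::rnorm(k, cfg$focus_amplitude[1],
                             cfg$focus_amplitude[2]), amp_floor)
    z <- stats::runif(k, z_lo, z_hi)
    shared <- stats::runif(k) < cfg$coloc_fraction
    in_a <- in_b <- rep(TRUE, k)
    if (cfg$n_channels == 2L) {
      solo_b <- !shared & (stats::runif(k) < 0.5)
      in_a <- shared | !solo_b
      in_b <- shared | solo_b
    }
    jit <- cfg$coloc_jitter_um / sqrt(2) / px
    y_b <- ifelse(in_b, pos$y + stats::rnorm(k, 0, jit), NA_real_)
    x_b <- ifelse(in_b, pos$x + stats::rnorm(k, 0, jit), NA_real_)
    foci[[i]] <- data.frame(
      cell_id = i, focus_id = seq_len(k),
      y_px = pos$y, x_px = pos$x, z_plane = z, amplitude = amp,
      in_a = in_a, in_b = in_b, y_b_px = y_b, x_b_px = x_b)
  }
  foci <- if (all(vapply(foci, is.null, TRUE))) empty_foci_df() else
    do.call(rbind, foci)
  cells <- nuc$cells
  cells$n_foci <- as.integer(tabulate(foci$cell_id, nbins = cfg$n_cells))
  truth <- list(cells = cells, foci = foci)

  if (truth_only)
    return(structure(list(channels = NULL, nucleus_labels = labels,
                          truth = truth, config = cfg), class = "fs_scene"))

  base <- matrix(DARK_LEVEL, ny, nx)
  base[labels > 0] <- cfg$background_level
  channels <- vector("list", cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    arr <- array(rep(base, nz), dim = c(ny, nx, nz))
    sel <- if (ch == 1L) foci$in_a else foci$in_b
    if (any(sel)) {
      f <- foci[sel, , drop = FALSE]
      yy <- if (ch == 1L) f$y_px else f$y_b_px
      xx <- if (ch == 1L) f$x_px else f$x_b_px
      arr <- render_gaussians_3d(arr, yy, xx, f$z_plane, f$amplitude,
                                 sig_lat, sig_ax)
    }
    arr <- apply_noise(arr, cfg)
    channels[[ch]] <- image_stack(arr, px, z_step_um = cfg$z_step_um,
                                  kind = "z",
                                  channel = c("ch_a", "ch_b")[ch])
  }
  structure(list(channels = channels, nucleus_labels = labels,
                 truth = truth, config = cfg), class = "fs_scene")
}

empty_foci_df <- function() {
  data.frame(cell_id = integer(), focus_id = integer(), y_px = numeric(),
             x_px = numeric(), z_plane = numeric(), amplitude = numeric(),
             in_a = logical(), in_b = logical(), y_b_px = numeric(),
             x_b_px = numeric())
}

#' @export
print.fs_scene <- function(x, ...) {
  cat(sprintf("<fs_scene> %d cells, %d true foci, %d channel(s)%s\n",
              nrow(x$truth$cells), nrow(x$truth$foci),
              x$config$n_channels,
              if (is.null(x$channels)) " [truth only]" else ""))
  invisible(x)
}

# --- nucleus placement ------------------------------------------------------

place_nuclei <- function(cfg) {
  shp <- cfg$image_shape; ny <- shp[2]; nx <- shp[3]
  px <- cfg$pixel_size_um
  n <- cfg$n_cells
  margin_px <- 0.5 / px

  ry <- pmax(stats::rnorm(n, cfg$nucleus_radius_um[1], cfg$nucleus_radius_um[2]),
             0.4 * cfg$nucleus_radius_um[1]) / px
  rx <- pmax(stats::rnorm(n, cfg$nucleus_radius_um[1], cfg$nucleus_radius_um[2]),
             0.4 * cfg$nucleus_radius_um[1]) / px
  theta <- stats::runif(n, 0, pi)
  # low-order radial perturbation -> smoothed, non-circular boundary
  pert <- cbind(stats::rnorm(n, 0, 0.03), stats::runif(n, 0, 2 * pi),
                stats::rnorm(n, 0, 0.02), stats::runif(n, 0, 2 * pi))
  rmax <- pmax(ry, rx) * 1.12

  cy <- cx <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(600)) {
      y <- stats::runif(1, rmax[i] + 2, ny - rmax[i] - 1)
      x <- stats::runif(1, rmax[i] + 2, nx - rmax[i] - 1)
      if (i == 1L ||
          all(sqrt((cy[seq_len(i - 1)] - y)^2 + (cx[seq_len(i - 1)] - x)^2) >
              rmax[i] + rmax[seq_len(i - 1)] + margin_px)) {
        cy[i] <- y; cx[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("nucleus placement failed after bounded retries: ",
           "nuclei too large for the field; enlarge `image_shape` or ",
           "reduce `n_cells`/`nucleus_radius_um`", call. = FALSE)
  }

  labels <- matrix(0L, ny, nx)
  allowed <- vector("list", n)
  erode_px <- max(2 * cfg$psf_sigma_um[1], 0.5) / px
  for (i in seq_len(n)) {
    box_r <- ceiling(rmax[i]) + 2L
    ys <- max(1L, floor(cy[i]) - box_r):min(ny, ceiling(cy[i]) + box_r)
    xs <- max(1L, floor(cx[i]) - box_r):min(nx, ceiling(cx[i]) + box_r)
    dy <- ys - cy[i]
    dx <- xs - cx[i]
    g <- expand.grid(dy = dy, dx = dx)
    u <- cos(theta[i]) * g$dx + sin(theta[i]) * g$dy
    v <- -sin(theta[i]) * g$dx + cos(theta[i]) * g$dy
    phi <- atan2(v / ry[i], u / rx[i])
    rad <- 1 + pert[i, 1] * cos(2 * phi + pert[i, 2]) +
      pert[i, 3] * cos(3 * phi + pert[i, 4])
    rho <- sqrt((u / rx[i])^2 + (v / ry[i])^2)
    inside <- matrix(rho <= rad, length(ys), length(xs))
    labels[ys, xs][inside] <- i
    # interior pixels at least erode_px from the boundary: focus sites
    core <- matrix(rho <= pmax(rad - erode_px / min(rx[i], ry[i]), 0),
                   length(ys), length(xs))
    idx <- which(core, arr.ind = TRUE)
    allowed[[i]] <- cbind(y = ys[idx[, 1]], x = xs[idx[, 2]])
  }
  cells <- data.frame(cell_id = seq_len(n), cy_px = cy, cx_px = cx,
                      ry_um = ry * px, rx_um = rx * px, theta = theta)
  list(labels = labels, cells = cells, allowed = allowed)
}

# Uniform focus positions over the eroded nucleus interior with a minimum
# mutual separation; separation is relaxed only if placement is infeasible.
place_foci_in_nucleus <- function(allowed, k, min_sep_px) {
  if (nrow(allowed) == 0) stop("nucleus interior too small for foci")
  y <- x <- numeric(k)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(400)) {
      i <- sample.int(nrow(allowed), 1)
      yy <- allowed[i, 1] + stats::runif(1, -0.5, 0.5)
      xx <- allowed[i, 2] + stats::runif(1, -0.5, 0.5)
      if (j == 1L || all(sqrt((y[seq_len(j - 1)] - yy)^2 +
                              (x[seq_len(j - 1)] - xx)^2) >= min_sep_px)) {
        y[j] <- yy; x[j] <- xx; ok <- TRUE; break
      }
    }
    if (!ok) {  # dense cell: accept the draw, separation no longer feasible
      i <- sample.int(nrow(allowed), 1)
      y[j] <- allowed[i, 1] + stats::runif(1, -0.5, 0.5)
      x[j] <- allowed[i, 2] + stats::runif(1, -0.5, 0.5)
    }
  }
  list(y = y, x = x)
}

# --- rendering and noise ----------------------------------------------------

# Add 3D Gaussian puncta (peak amplitude `amp`) to `arr`, evaluated at voxel
# centres in a +/-5 sigma window.
render_gaussians_3d <- function(arr, y, x, z, amp, sig_lat, sig_ax) {
  d <- dim(arr)
  wl <- ceiling(5 * sig_lat); wa <- ceiling(4 * sig_ax)
  for (i in seq_along(y)) {
    ys <- max(1L, floor(y[i] - wl)):min(d[1], ceiling(y[i] + wl))
    xs <- max(1L, floor(x[i] - wl)):min(d[2], ceiling(x[i] + wl))
    zs <- max(1L, floor(z[i] - wa)):min(d[3], ceiling(z[i] + wa))
    gy <- exp(-(ys - y[i])^2 / (2 * sig_lat^2))
    gx <- exp(-(xs - x[i])^2 / (2 * sig_lat^2))
    gz <- exp(-(zs - z[i])^2 / (2 * sig_ax^2))
    blob <- (amp[i] * outer(gy, gx)) %o% gz
    arr[ys, xs, zs] <- arr[ys, xs, zs] + blob
  }
  arr
}

render_gaussians_2d <- function(img, y, x, amp, sig_lat) {
  d <- dim(img)
  wl <- ceiling(5 * sig_lat)
  for (i in seq_along(y)) {
    ys <- max(1L, floor(y[i] - wl)):min(d[1], ceiling(y[i] + wl))
    xs <- max(1L, floor(x[i] - wl)):min(d[2], ceiling(x[i] + wl))
    gy <- exp(-(ys - y[i])^2 / (2 * sig_lat^2))
    gx <- exp(-(xs - x[i])^2 / (2 * sig_lat^2))
    img[ys, xs] <- img[ys, xs] + amp[i] * outer(gy, gx)
  }
  img
}

apply_noise <- function(arr, cfg) {
  d <- dim(arr)
  out <- as.numeric(arr)
  if (cfg$shot_noise) out <- stats::rpois(length(out), out)
  if (cfg$read_noise_sd > 0)
    out <- out + stats::rnorm(length(out), 0, cfg$read_noise_sd)
  array(pmax(out, 0), dim = d)
}

# --- derived generators -----------------------------------------------------

#' Generate mock (focus-free) negative-control cells
#'
#' Same contract as [generate_scene()] with the focus rate forced to zero;
#' these cells carry only noise and are the empirical null used to calibrate
#' the SBR threshold.
#'
#' @inheritParams generate_scene
#' @return An `fs_scene` whose truth focus table is empty.
#' @export
generate_mock_cells <- function(config, truth_only = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  cfg$foci_per_cell_mean <- 0
  generate_scene(cfg, truth_only = truth_only)
}

#' Generate a treated/untreated condition pair
#'
#' Two scenes sharing all parameters except that the treated arm's focus rate
#' is scaled by `count_ratio` and its mean focus amplitude by
#' `intensity_ratio` (emulating, e.g., siRNA knockdown or aliphatic-diol
#' treatment of condensates). The arms use sub-seeds derived from the config
#' seed, so the pair is reproducible as a unit.
#'
#' @inheritParams generate_scene
#' @param count_ratio Multiplier in (0, 1] on the treated focus rate.
#' @param intensity_ratio Multiplier in (0, 1] on the treated amplitude mean.
#' @return List with elements `control` and `treated`, each an `fs_scene`.
#' @export
generate_condition_pair <- function(config, count_ratio = 1,
                                    intensity_ratio = 1,
                                    truth_only = FALSE) {
  stopifnot(inherits(config, "scene_config"),
            count_ratio > 0, count_ratio <= 1,
            intensity_ratio > 0, intensity_ratio <= 1)
  ctrl_cfg <- config
  ctrl_cfg$seed <- derive_seed(config$seed, 1L)
  trt_cfg <- config
  trt_cfg$seed <- derive_seed(config$seed, 2L)
  trt_cfg$foci_per_cell_mean <- config$foci_per_cell_mean * count_ratio
  trt_cfg$focus_amplitude[1] <- config$focus_amplitude[1] * intensity_ratio
  list(control = generate_scene(ctrl_cfg, truth_only = truth_only),
       treated = generate_scene(trt_cfg, truth_only = truth_only))
}

#' Generate a time-lapse fusion series with ground truth
#'
#' A single nucleus containing two foci that approach linearly (closing speed
#' `approach_speed_um_per_frame`) and coalesce into one spot, with the merged
#' amplitude equal to the sum of the partners (intensity conservation by
#' construction). Coalescence occurs at the first frame where the centre
#' distance falls below the configured contact distance
#' (`merge_distance_um`). Each frame is scaled by `exp(-bleach_rate * t)`
#' before noise (t = 0 for the first frame).
#'
#' @inheritParams generate_scene
#' @param n_frames Number of frames (>= 3).
#' @param approach_speed_um_per_frame Closing speed of the two foci, um/frame.
#' @param initial_separation_um Centre distance at frame 1, um.
#' @param amplitudes Length-2 peak amplitudes of the partners (photons);
#'   defaults to draws from the config amplitude law.
#' @return List with `series` (an [image_stack()] over t), `nucleus_mask`
#'   (logical matrix), and `truth` (per-frame spot table, `merge_frame` —
#'   1-based frame index or `NA` if no merge — and `bleach_rate`).
#' @export
generate_fusion_series <- function(config, n_frames = 25L,
                                   approach_speed_um_per_frame = 0.1,
                                   initial_separation_um = 2,
                                   amplitudes = NULL) {
  stopifnot(inherits(config, "scene_config"), n_frames >= 3)
  with_seed(config$seed, {
    cfg <- config
    px <- cfg$pixel_size_um
    r_px <- cfg$nucleus_radius_um[1] / px
    side <- as.integer(ceiling(2 * r_px * 1.3 + 12))
    cen <- (side + 1) / 2
    yy <- matrix(seq_len(side), side, side)
    xx <- t(yy)
    mask <- (yy - cen)^2 + (xx - cen)^2 <= r_px^2

    if (is.null(amplitudes))
      amplitudes <- pmax(stats::rnorm(2, cfg$focus_amplitude[1],
                                      cfg$focus_amplitude[2]),
                         5 * sqrt(cfg$background_level))
    stopifnot(length(amplitudes) == 2, all(amplitudes > 0))
    ang <- stats::runif(1, 0, pi)
    half <- initial_separation_um / 2 / px
    dirv <- c(sin(ang), cos(ang))
    p1 <- c(cen, cen) + half * dirv
    p2 <- c(cen, cen) - half * dirv
    sig_lat <- cfg$psf_sigma_um[1] / px
    merge_px <- cfg$merge_distance_um / px
    speed_px <- approach_speed_um_per_frame / px

    base <- matrix(DARK_LEVEL, side, side)
    base[mask] <- cfg$background_level

    frames <- array(0, dim = c(side, side, n_frames))
    rows <- list()
    merge_frame <- NA_integer_
    for (t in seq_len(n_frames)) {
      d <- sqrt(sum((p1 - p2)^2))
      merged <- !is.na(merge_frame)
      if (!merged && d < merge_px) {
        merge_frame <- t
        merged <- TRUE
        w <- amplitudes / sum(amplitudes)
        pm <- w[1] * p1 + w[2] * p2
        p1 <- p2 <- pm
      }
      img <- base
      if (merged) {
        img <- render_gaussians_2d(img, p1[1], p1[2], sum(amplitudes), sig_lat)
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, spot = 3L, y_px = p1[1], x_px = p1[2],
          amplitude = sum(amplitudes))
      } else {
        img <- render_gaussians_2d(img, c(p1[1], p2[1]), c(p1[2], p2[2]),
                                   amplitudes, sig_lat)
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, spot = 1:2, y_px = c(p1[1], p2[1]),
          x_px = c(p1[2], p2[2]), amplitude = amplitudes)
        # symmetric linear approach toward the midpoint
        step <- min(speed_px / 2, max(d - 1e-9, 0) / 2)
        p1 <- p1 - step * dirv
        p2 <- p2 + step * dirv
      }
      img <- img * exp(-cfg$bleach_rate * (t - 1))
      frames[, , t] <- apply_noise(img, cfg)
    }
    truth <- list(frames = do.call(rbind, rows), merge_frame = merge_frame,
                  bleach_rate = cfg$bleach_rate,
                  amplitudes = amplitudes, merge_distance_um = cfg$merge_distance_um)
    list(series = image_stack(frames, px, frame_interval = 1, kind = "t",
                              channel = "fusion"),
         nucleus_mask = mask, truth = truth)
  })
}
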