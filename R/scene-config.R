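#' Configuration for a synthetic microscopy scene
#'
#' Bundles every parameter of the ground-truth simulator: field geometry,
#' optics (anisotropic Gaussian PSF), photon budget (Poisson shot noise plus
#' additive Gaussian read noise), nucleus geometry, and the per-cell focus
#' model (Poisson focus counts, Gaussian focus amplitudes). Defaults emulate
#' FISH imaging of nuclear RNA foci on a 100x/EMCCD widefield system: bright
#' diffraction-limited puncta (amplitude well above the shot-noise floor) on
#' a dim nucleoplasmic background, z-sampled at 0.25 um.
#'
#' @param n_cells Number of nuclei per field.
#' @param foci_per_cell_mean Poisson mean of true foci per cell (lambda).
#' @param image_shape Integer `(n_z, n_y, n_x)` in voxels, or `NULL` to size
#'   the lateral field automatically from `n_cells` and the nucleus radius.
#' @param pixel_size_um Lateral sampling, um/pixel.
#' @param z_step_um Axial step, um (0.25 matches standard z-sampling here).
#' @param nucleus_radius_um Length-2 `(mean, sd)` of the nucleus radius, um.
#' @param focus_amplitude Length-2 `(mean, sd)` of focus peak amplitude in
#'   photons above background; draws are truncated below at
#'   `5 * sqrt(background_level)` so every rendered focus has SNR >= 5.
#' @param psf_sigma_um Length-2 `(lateral, axial)` Gaussian PSF sigma, um.
#' @param background_level Nucleoplasmic background, photons.
#' @param read_noise_sd Additive Gaussian read noise sd, photons.
#' @param coloc_fraction Proportion of foci present in both channels of a
#'   two-channel scene; the remainder are assigned to one channel at random.
#' @param coloc_jitter_um Localization jitter of the second channel's copy of
#'   a shared focus: sd of the total lateral displacement, um.
#' @param n_channels 1 or 2.
#' @param min_focus_sep_um Minimum centre separation enforced between foci of
#'   the same cell (condensates closer than this would have coalesced).
#' @param merge_distance_um Centre distance below which two approaching foci
#'   in a fusion series coalesce into one rendered spot. The default, 4
#'   lateral PSF sigma, is the contact distance of the two optical-size
#'   (~2 sigma radius) droplets, and keeps every rendered two-spot frame
#'   resolvable so that tracking and ground truth agree on the merge frame.
#' @param bleach_rate Per-frame multiplicative photobleaching decay rate for
#'   time series (frame t is scaled by `exp(-bleach_rate * t)`, t = 0, 1, ...).
#' @param shot_noise Apply Poisson shot noise? Disable (with
#'   `read_noise_sd = 0`) for noise-free conservation checks.
#' @param seed Integer seed; identical configs give bit-identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_cells = 25L,
                         foci_per_cell_mean = 15.8,
                         image_shape = NULL,
                         pixel_size_um = 0.13,
                         z_step_um = 0.25,
                         nucleus_radius_um = c(4.5, 0.4),
                         focus_amplitude = c(250, 50),
                         psf_sigma_um = c(0.2, 0.5),
                         background_level = 30,
                         read_noise_sd = 3,
                         coloc_fraction = 0,
                         coloc_jitter_um = 0.1,
                         n_channels = 1L,
                         min_focus_sep_um = 0.8,
                         merge_distance_um = 4 * psf_sigma_um[1],
                         bleach_rate = 0,
                         shot_noise = TRUE,
                         seed = 1L) {
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  stop_if_not_scalar_pos(z_step_um, "z_step_um")
  stopifnot(length(nucleus_radius_um) == 2, nucleus_radius_um[1] > 0,
            length(focus_amplitude) == 2, focus_amplitude[1] > 0,
            length(psf_sigma_um) == 2, all(psf_sigma_um > 0),
            n_cells >= 1, foci_per_cell_mean >= 0,
            background_level > 0, read_noise_sd >= 0,
            coloc_fraction >= 0, coloc_fraction <= 1,
            n_channels %in% 1:2, min_focus_sep_um >= 0,
            merge_distance_um > 0, bleach_rate >= 0)
  cfg <- list(
    n_cells = as.integer(n_cells),
    foci_per_cell_mean = foci_per_cell_mean,
    image_shape = image_shape,
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    nucleus_radius_um = nucleus_radius_um,
    focus_amplitude = focus_amplitude,
    psf_sigma_um = psf_sigma_um,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    coloc_fraction = coloc_fraction,
    coloc_jitter_um = coloc_jitter_um,
    n_channels = as.integer(n_channels),
    min_focus_sep_um = min_focus_sep_um,
    merge_distance_um = merge_distance_um,
    bleach_rate = bleach_rate,
    shot_noise = isTRUE(shot_noise),
    seed = as.integer(seed))
  cfg$image_shape <- resolve_image_shape(cfg)
  if (any(cfg$image_shape < 1)) stop("all image dimensions must be >= 1")
  class(cfg) <- "scene_config"
  cfg
}

# Field sized so that rejection placement of n_cells non-overlapping nuclei
# succeeds comfortably (~30% disc coverage).
resolve_image_shape <- function(cfg) {
  if (!is.null(cfg$image_shape)) {
    shp <- as.integer(cfg$image_shape)
    if (length(shp) != 3) stop("`image_shape` must be (n_z, n_y, n_x)")
    return(shp)
  }
  r_px <- (cfg$nucleus_radius_um[1] + 2 * cfg$nucleus_radius_um[2]) /
    cfg$pixel_size_um
  tile <- 2 * 1.15 * r_px + 1.5 / cfg$pixel_size_um
  side <- as.integer(ceiling(sqrt(cfg$n_cells) * tile * 1.25))
  c(13L, side, side)
}

#' Nominal focus signal-to-noise ratio of a scene configuration
#'
#' Reported as mean focus amplitude over the shot-noise standard deviation of
#' the nucleoplasmic background, `amplitude / sqrt(background)`.
#'
#' @param config A [scene_config()].
#' @return A single number.
#' @export
config_snr <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  config$focus_amplitude[1] / sqrt(config$background_level)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    paste0("<scene_config> %d cells, lambda = %.3g foci/cell, field %d x %d x %d",
           " vox @ %.3g um/px\n  amplitude %.4g +/- %.3g photons over bg %.3g",
           " (SNR %.3g), PSF sigma (%.3g, %.3g) um, seed %d\n"),
    x$n_cells, x$foci_per_cell_mean,
    x$image_shape[1], x$image_shape[2], x$image_shape[3], x$pixel_size_um,
    x$focus_amplitude[1], x$focus_amplitude[2], x$background_level,
    config_snr(x), x$psf_sigma_um[1], x$psf_sigma_um[2], x$seed))
  invisible(x)
}

# Serialize / restore a scene_config as a plain list (JSON-friendly).
config_to_list <- function(config) unclass(config)

config_from_list <- function(lst) {
  lst$image_shape <- if (is.null(lst$image_shape)) NULL else as.integer(lst$image_shape)
  do.call(scene_config, lst)
}
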