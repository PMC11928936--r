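# End-to-end orchestration: run the generate/load -> project -> detect ->
# calibrate -> call (-> colocalize / compare) pipeline and write a
# reproducible report bundle.

#' Write a scene to disk (TIFF channels, label TIFF, JSON truth/config)
#'
#' @param scene An `fs_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(scene$channels))
    write_stack_tiff(scene$channels[[i]],
                     file.path(dir, sprintf("channel_%d.tif", i)))
  write_labels_tiff(scene$nucleus_labels, file.path(dir, "nucleus_labels.tif"))
  jsonlite::write_json(scene$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(config_to_list(scene$config),
                       file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#' @param dir Scene directory.
#' @return An `fs_scene`.
#' @export
read_scene <- function(dir) {
  cfg <- config_from_list(jsonlite::read_json(file.path(dir, "config.json"),
                                              simplifyVector = TRUE))
  chans <- sort(list.files(dir, pattern = "^channel_\\d+\\.tif$",
                           full.names = TRUE))
  channels <- lapply(seq_along(chans), function(i)
    read_stack_tiff(chans[i], cfg$pixel_size_um, z_step_um = cfg$z_step_um,
                    channel = c("ch_a", "ch_b")[i]))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(channels = channels,
                 nucleus_labels = read_labels_tiff(
                   file.path(dir, "nucleus_labels.tif")),
                 truth = truth, config = cfg), class = "fs_scene")
}

#' Simulation presets for the reported experimental regimes
#'
#' Named regimes of the quantified experiments: `plasmid_like` (high focus
#' rate, 15.8 foci/cell), `cassette_like` (marginal rate, 0.09 foci/cell),
#' `mock` (focus-free control), `coloc_high` (two channels, every focus
#' co-labelled), `coloc_none` (two channels, independent foci at low
#' density), `fusion` (time-lapse with exactly one merge event), and
#' `condition_pair` (control plus treated arm with reduced count and
#' intensity).
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param n_cells Cells per scene (ignored by `fusion`).
#' @return For `fusion`: the [generate_fusion_series()] result. For
#'   `condition_pair`: the [generate_condition_pair()] result. Otherwise an
#'   `fs_scene`.
#' @export
simulate_preset <- function(preset = c("plasmid_like", "cassette_like",
                                       "mock", "coloc_high", "coloc_none",
                                       "fusion", "condition_pair"),
                            seed = 1L, n_cells = 25L) {
  preset <- match.arg(preset)
  switch(preset,
    plasmid_like = generate_scene(
      scene_config(n_cells = n_cells, foci_per_cell_mean = 15.8, seed = seed)),
    cassette_like = generate_scene(
      scene_config(n_cells = n_cells, foci_per_cell_mean = 0.09, seed = seed)),
    mock = generate_mock_cells(
      scene_config(n_cells = n_cells, seed = seed)),
    coloc_high = generate_scene(
      scene_config(n_cells = n_cells, foci_per_cell_mean = 15,
                   n_channels = 2L, coloc_fraction = 1, seed = seed)),
    coloc_none = generate_scene(
      scene_config(n_cells = n_cells, foci_per_cell_mean = 15,
                   n_channels = 2L, coloc_fraction = 0, seed = seed)),
    fusion = generate_fusion_series(
      scene_config(n_cells = 1L, shot_noise = TRUE, seed = seed)),
    condition_pair = generate_condition_pair(
      scene_config(n_cells = n_cells, foci_per_cell_mean = 15.8, seed = seed),
      count_ratio = 0.3, intensity_ratio = 0.7))
}

#' Materialize a preset as an on-disk fixture set
#'
#' @inheritParams simulate_preset
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(preset, seed, dir, n_cells = 25L) {
  obj <- simulate_preset(preset, seed = seed, n_cells = n_cells)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "fusion") {
    write_stack_tiff(obj$series, file.path(dir, "series.tif"))
    write_labels_tiff(matrix(as.integer(obj$nucleus_mask),
                             nrow(obj$nucleus_mask)),
                      file.path(dir, "nucleus_labels.tif"))
    jsonlite::write_json(obj$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  } else if (preset == "condition_pair") {
    write_scene(obj$control, file.path(dir, "control"))
    write_scene(obj$treated, file.path(dir, "treated"))
  } else {
    write_scene(obj, dir)
  }
  invisible(dir)
}

#' Pipeline configuration
#'
#' @param out_dir Report output directory.
#' @param preset Simulation preset name (scenes are generated), or `NULL`
#'   with `scene_dir`/`mock_dir` pointing at on-disk fixtures.
#' @param scene_dir,mock_dir Directories of a written scene / mock set.
#' @param n_cells,n_mock_cells Cells per simulated scene / mock scene.
#' @param threshold_override Numeric SBR threshold to use instead of mock
#'   calibration (e.g. 1.60); recorded with provenance `"user"`.
#' @param matching_radius_um Object colocalization radius.
#' @param seed Integer seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, preset = "plasmid_like",
                            scene_dir = NULL, mock_dir = NULL,
                            n_cells = 25L, n_mock_cells = 25L,
                            threshold_override = NULL,
                            matching_radius_um = 0.5, seed = 1L) {
  if (is.null(preset) && is.null(scene_dir))
    stop("config error: need a preset or a scene_dir", call. = FALSE)
  for (d in c(scene_dir, mock_dir))
    if (!is.null(d) && !dir.exists(d))
      stop("config error: path not resolvable: ", d, call. = FALSE)
  if (!is.null(threshold_override))
    stopifnot(is.numeric(threshold_override), threshold_override > 0)
  structure(list(out_dir = out_dir, preset = preset, scene_dir = scene_dir,
                 mock_dir = mock_dir, n_cells = as.integer(n_cells),
                 n_mock_cells = as.integer(n_mock_cells),
                 threshold_override = threshold_override,
                 matching_radius_um = matching_radius_um,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full quantification pipeline
#'
#' Generate-or-load, project, detect, calibrate (or apply a user threshold
#' override), call foci, and — for two-channel scenes — colocalize. Writes a
#' report bundle: `counts.csv` (per cell), `calibration.json`, for
#' two-channel scenes `coloc.csv` + `coloc_summary.json`, and `run_log.txt`
#' with the package version, seed, config hash and all effective parameters.
#' Identical config + seed give identical report bodies.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `counts`, `calibration`, `coloc` (or NULL)
#'   and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  scene <- tryCatch({
    if (!is.null(config$scene_dir)) read_scene(config$scene_dir)
    else simulate_preset(config$preset, seed = derive_seed(config$seed, 1L),
                         n_cells = config$n_cells)
  }, error = function(e)
    stop("data error [stage load/generate]: ", conditionMessage(e),
         call. = FALSE))
  if (!inherits(scene, "fs_scene"))
    stop("config error: preset does not produce a single scene", call. = FALSE)
  params <- detect_params_for(scene$config)

  if (!is.null(config$threshold_override)) {
    calib <- list(threshold = config$threshold_override, source = numeric(),
                  n_mock_cells = 0L, fallback = FALSE, provenance = "user")
  } else {
    mock <- tryCatch({
      if (!is.null(config$mock_dir)) read_scene(config$mock_dir)
      else generate_mock_cells(
        scene_config(n_cells = config$n_mock_cells,
                     seed = derive_seed(config$seed, 2L)))
    }, error = function(e)
      stop("data error [stage mock]: ", conditionMessage(e), call. = FALSE))
    calib <- calibrate_on_mock(mock, params)
    calib$provenance <- "mock"
  }

  counts <- tryCatch(
    count_scene_foci(scene, calib$threshold, params),
    error = function(e)
      stop("data error [stage count]: ", conditionMessage(e), call. = FALSE))

  coloc <- NULL
  if (length(scene$channels) == 2) {
    coloc <- coloc_scene(scene, calib$threshold, params,
                         max_distance_um = config$matching_radius_um)
  }

  paths <- list(counts = file.path(config$out_dir, "counts.csv"),
                calibration = file.path(config$out_dir, "calibration.json"),
                log = file.path(config$out_dir, "run_log.txt"))
  utils::write.csv(format_floats(counts), paths$counts, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(threshold = calib$threshold, n_mock_cells = calib$n_mock_cells,
         n_mock_candidates = length(calib$source),
         fallback = isTRUE(calib$fallback), provenance = calib$provenance),
    paths$calibration, auto_unbox = TRUE, digits = NA)
  if (!is.null(coloc)) {
    paths$coloc <- file.path(config$out_dir, "coloc.csv")
    paths$coloc_summary <- file.path(config$out_dir, "coloc_summary.json")
    utils::write.csv(format_floats(coloc$per_cell), paths$coloc,
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(coloc$summary, paths$coloc_summary,
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(c(
    sprintf("fociscope %s", as.character(utils::packageVersion("fociscope"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", config_hash(unclass(config))),
    sprintf("threshold: %.6g (%s)", calib$threshold, calib$provenance),
    sprintf("n_cells: %d", nrow(counts)),
    utils::capture.output(utils::str(unclass(config)))),
    paths$log)
  invisible(list(counts = counts, calibration = calib, coloc = coloc,
                 paths = paths))
}

# CSV floats at 6 significant digits (stable report bodies).
format_floats <- function(df) {
  for (nm in names(df)) if (is.double(df[[nm]]))
    df[[nm]] <- signif(df[[nm]], 6)
  df
}
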