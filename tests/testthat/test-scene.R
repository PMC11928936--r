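# Ground-truth simulator: determinism, calibration of the focus-count law,
# containment, channel labelling, fusion-series conservation.

test_that("lambda = 0 gives focus-free cells and coloc_fraction = 1 labels every focus in both channels", {
  mock <- generate_mock_cells(scene_config(n_cells = 5, seed = 2),
                              truth_only = TRUE)
  expect_equal(nrow(mock$truth$foci), 0)
  expect_true(all(mock$truth$cells$n_foci == 0))

  sc <- generate_scene(scene_config(n_cells = 5, foci_per_cell_mean = 6,
                                    n_channels = 2, coloc_fraction = 1,
                                    seed = 3), truth_only = TRUE)
  expect_gt(nrow(sc$truth$foci), 0)
  expect_true(all(sc$truth$foci$in_a & sc$truth$foci$in_b))

  sc0 <- generate_scene(scene_config(n_cells = 5, foci_per_cell_mean = 6,
                                     n_channels = 2, coloc_fraction = 0,
                                     seed = 3), truth_only = TRUE)
  expect_false(any(sc0$truth$foci$in_a & sc0$truth$foci$in_b))
})

test_that("empirical per-cell focus count matches Poisson(lambda) within the CLT bound", {
  sc <- generate_scene(scene_config(n_cells = 200, foci_per_cell_mean = 5,
                                    seed = 4), truth_only = TRUE)
  expect_lt(abs(mean(sc$truth$cells$n_foci) - 5), 3 * sqrt(5 / 200))
})

test_that("identical config and seed give bit-identical scenes", {
  a <- generate_scene(scene_config(n_cells = 3, seed = 9))
  b <- generate_scene(scene_config(n_cells = 3, seed = 9))
  expect_identical(a$channels[[1]]$data, b$channels[[1]]$data)
  expect_identical(a$nucleus_labels, b$nucleus_labels)
  expect_identical(a$truth, b$truth)
})

test_that("every focus peak voxel lies inside its nucleus mask", {
  sc <- small_scene()
  f <- sc$truth$foci
  owner <- sc$nucleus_labels[cbind(round(f$y_px), round(f$x_px))]
  expect_true(all(owner == f$cell_id))
})

test_that("nucleus placement failure raises an explicit error", {
  expect_error(
    generate_scene(scene_config(n_cells = 8, image_shape = c(5L, 90L, 90L),
                                seed = 1), truth_only = TRUE),
    "placement failed")
})

test_that("condition pair scales the treated count rate and amplitude law", {
  pr <- generate_condition_pair(
    scene_config(n_cells = 500, foci_per_cell_mean = 10, seed = 6),
    count_ratio = 0.5, intensity_ratio = 1, truth_only = TRUE)
  m <- mean(pr$treated$truth$cells$n_foci)
  expect_lt(abs(m - 5), 3 * sqrt(5 / 500))
  expect_lt(abs(mean(pr$control$truth$cells$n_foci) - 10),
            3 * sqrt(10 / 500))

  pr2 <- generate_condition_pair(
    scene_config(n_cells = 300, foci_per_cell_mean = 10, seed = 7),
    count_ratio = 1, intensity_ratio = 0.5, truth_only = TRUE)
  ratio <- mean(pr2$treated$truth$foci$amplitude) /
    mean(pr2$control$truth$foci$amplitude)
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("noise-free fusion series conserves integrated intensity exactly and obeys the bleach closed form", {
  cfg <- scene_config(shot_noise = FALSE, read_noise_sd = 0, seed = 7)
  fs <- generate_fusion_series(cfg, n_frames = 20,
                               approach_speed_um_per_frame = 0.1)
  expect_false(is.na(fs$truth$merge_frame))
  # spot flux = frame total minus the flat background, which is constant
  totals <- apply(fs$series$data, 3, sum)
  expect_lt(diff(range(totals)) / mean(totals), 1e-4)

  cfgb <- scene_config(shot_noise = FALSE, read_noise_sd = 0,
                       bleach_rate = 0.1, seed = 8)
  fsb <- generate_fusion_series(cfgb, n_frames = 10,
                                approach_speed_um_per_frame = 0)
  expect_true(is.na(fsb$truth$merge_frame))  # speed 0, disjoint foci
  tot <- apply(fsb$series$data, 3, sum)
  expect_equal(tot / tot[1], exp(-0.1 * (0:9)), tolerance = 1e-10)
})

test_that("truth merge frame equals the first frame where partner distance drops below the contact distance", {
  cfg <- scene_config(seed = 42)
  fs <- generate_fusion_series(cfg, n_frames = 25,
                               approach_speed_um_per_frame = 0.1)
  fr <- fs$truth$frames
  px <- cfg$pixel_size_um
  pre <- fr[fr$spot %in% 1:2, ]
  d_um <- sapply(split(pre, pre$frame), function(g)
    sqrt(diff(g$y_px)^2 + diff(g$x_px)^2) * px)
  # brute force: first frame at which the rendered configuration is merged
  first_merged <- min(fr$frame[fr$spot == 3])
  expect_true(all(d_um >= cfg$merge_distance_um))
  expect_equal(fs$truth$merge_frame, first_merged)
  expect_equal(max(pre$frame) + 1L, first_merged)
})
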