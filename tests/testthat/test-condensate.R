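# Shape, fusion tracking, condition statistics.

test_that("circularity separates discs from bars and is scale-invariant", {
  disc <- outer(-15:15, -15:15, function(y, x) y^2 + x^2 <= 100)
  expect_gte(circularity(disc), 0.9)

  bar <- matrix(FALSE, 30, 30); bar[15:16, 5:25] <- TRUE
  expect_lt(circularity(bar), 0.5)

  big <- outer(-35:35, -35:35, function(y, x) y^2 + x^2 <= 400)
  expect_lt(abs(circularity(big) - circularity(disc)), 0.05)

  expect_error(circularity(matrix(c(TRUE, rep(FALSE, 24)), 5, 5)),
               "degenerate")
})

test_that("called foci in default simulations are round; injected elongated structures are not", {
  sc <- small_scene()
  p <- detect_params_for(sc$config)
  mip <- max_intensity_projection(sc$channels[[1]])
  scored <- score_scene(mip, sc$nucleus_labels, p)
  sets <- call_foci(scored, small_calib())
  circ <- unlist(lapply(sets, function(s) {
    if (s$count == 0) return(NULL)
    vapply(s$calls$mask_px, function(idx) {
      m <- matrix(FALSE, nrow(mip), ncol(mip)); m[idx] <- TRUE
      if (sum(m) < 4) return(NA_real_)
      circularity(m)
    }, 0)
  }))
  expect_gte(median(circ, na.rm = TRUE), 0.85)
  bar <- matrix(FALSE, 40, 40); bar[19:21, 8:32] <- TRUE
  expect_lt(circularity(bar), median(circ, na.rm = TRUE))
})

test_that("fusion tracking recovers the truth merge frame and conserves combined intensity", {
  cfg <- scene_config(shot_noise = FALSE, read_noise_sd = 0, seed = 7)
  fs <- generate_fusion_series(cfg, n_frames = 25,
                               approach_speed_um_per_frame = 0.1)
  tr <- track_fusion(fs$series, fs$nucleus_mask, detect_params_for(cfg))
  mf <- fs$truth$merge_frame
  expect_equal(tr$merge_frame, mf)
  ci <- tr$intensity$combined
  expect_lte(abs(ci[mf + 1] - ci[mf - 1]) / ci[mf - 1], 0.05)

  # static, well-separated spots never merge
  fs0 <- generate_fusion_series(cfg, n_frames = 6,
                                approach_speed_um_per_frame = 0)
  tr0 <- track_fusion(fs0$series, fs0$nucleus_mask, detect_params_for(cfg))
  expect_true(is.na(tr0$merge_frame))
  expect_true(is.na(fs0$truth$merge_frame))
})

test_that("noisy bleach-corrected fusion series conserves combined intensity within 5%", {
  cfg <- scene_config(bleach_rate = 0.05, seed = 42)
  fs <- generate_fusion_series(cfg, n_frames = 25,
                               approach_speed_um_per_frame = 0.1)
  bc <- correct_photobleaching(fs$series, fs$nucleus_mask)
  tr <- track_fusion(bc$corrected, fs$nucleus_mask, detect_params_for(cfg))
  mf <- fs$truth$merge_frame
  expect_equal(tr$merge_frame, mf)
  ci <- tr$intensity$combined
  expect_lte(abs(ci[mf + 1] - ci[mf - 1]) / ci[mf - 1], 0.05)
})

test_that("two-arm comparison reduces to the Welch t-test closed form", {
  a <- c(4, 6, 5, 7, 9, 3, 6, 5)
  b <- c(2, 3, 4, 2, 5, 1, 3, 2)
  cs <- compare_conditions(list(control = list(counts = a),
                                treated = list(counts = b)))
  # hand-computed Welch statistic and Satterthwaite df
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  t_hand <- (mean(b) - mean(a)) / sqrt(se2a + se2b)
  df_hand <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  row <- cs$tests[cs$tests$metric == "counts", ]
  expect_equal(row$statistic, t_hand, tolerance = 1e-12)
  expect_equal(row$df, df_hand, tolerance = 1e-12)
  expect_equal(row$p_raw, p_hand, tolerance = 1e-12)
  expect_error(compare_conditions(list(only = list(counts = a))), "2")
})

test_that("knockdown-like count reduction is detected with high power; matched arms are not", {
  pr <- generate_condition_pair(
    scene_config(n_cells = 60, foci_per_cell_mean = 15, seed = 77),
    count_ratio = 0.3, intensity_ratio = 1, truth_only = TRUE)
  cs <- compare_conditions(list(
    control = list(counts = pr$control$truth$cells$n_foci),
    treated = list(counts = pr$treated$truth$cells$n_foci)))
  expect_gt(cs$arms$count_mean[1], cs$arms$count_mean[2])
  expect_lt(cs$tests$p_adj[cs$tests$metric == "counts"], 0.01)
})

test_that("intensity-only treatment separates the intensity metric but not the count metric", {
  pr <- generate_condition_pair(
    scene_config(n_cells = 80, foci_per_cell_mean = 12, seed = 90),
    count_ratio = 1, intensity_ratio = 0.5, truth_only = TRUE)
  cs <- compare_conditions(list(
    control = list(counts = pr$control$truth$cells$n_foci,
                   intensities = pr$control$truth$foci$amplitude),
    treated = list(counts = pr$treated$truth$cells$n_foci,
                   intensities = pr$treated$truth$foci$amplitude)))
  expect_lt(cs$tests$p_adj[cs$tests$metric == "intensities"], 0.001)
  expect_gt(cs$tests$p_adj[cs$tests$metric == "counts"], 0.05)
})

test_that("three arms trigger ANOVA plus corrected pairwise comparisons against the control", {
  set.seed(12)
  arms <- list(ctrl = list(counts = rpois(30, 15)),
               t1 = list(counts = rpois(30, 15)),
               t2 = list(counts = rpois(30, 5)))
  cs <- compare_conditions(arms, control = "ctrl")
  expect_false(is.null(cs$anova_p))
  tc <- cs$tests[cs$tests$metric == "counts", ]
  expect_equal(nrow(tc), 2)
  expect_true(all(tc$p_adj >= tc$p_raw))
  expect_lt(tc$p_adj[tc$comparison == "t2 vs ctrl"], 0.001)
  expect_gt(tc$p_adj[tc$comparison == "t1 vs ctrl"], 0.05)
})
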