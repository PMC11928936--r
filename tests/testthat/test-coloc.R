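# Pixel Pearson correlation and object-level spot matching.

test_that("Pearson correlation hits its closed-form anchors and a hand-computed 3x3 oracle", {
  set.seed(3)
  a <- matrix(runif(64, 10, 50), 8, 8)
  expect_equal(pearson_coefficient(a, a), 1)
  expect_equal(pearson_coefficient(a, -a + 100), -1)

  x <- matrix(c(1, 4, 2, 8, 5, 7, 3, 6, 9), 3, 3)
  y <- matrix(c(2, 3, 1, 9, 6, 8, 2, 7, 8), 3, 3)
  mx <- mean(x); my <- mean(y)
  oracle <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(pearson_coefficient(x, y), oracle)

  expect_error(pearson_coefficient(matrix(1, 3, 3), y), "zero variance")
  expect_error(pearson_coefficient(x, y[1:2, 1:2, drop = FALSE]), "equal-sized")
})

test_that("Pearson is symmetric and invariant under positive affine maps", {
  set.seed(4)
  a <- matrix(rpois(400, 40), 20, 20)
  b <- matrix(rpois(400, 40) + 0.3 * a, 20, 20)
  expect_equal(pearson_coefficient(a, b), pearson_coefficient(b, a))
  expect_equal(pearson_coefficient(2.5 * a + 7, b),
               pearson_coefficient(a, b), tolerance = 1e-12)
})

test_that("spot matching obeys the distance radius and its trivial anchors", {
  px <- 0.13
  s <- data.frame(y_px = c(10, 30, 50), x_px = c(12, 28, 44))
  m <- match_spots(s, s, px)
  expect_equal(nrow(m$matched), 3)
  expect_true(all(m$matched$dist_um == 0))
  expect_length(m$unmatched_a, 0)
  expect_length(m$unmatched_b, 0)

  # single pair 0.8 um apart with 0.5 um radius: farther than 500 nm, no pair
  a <- data.frame(y_px = 10, x_px = 10)
  b <- data.frame(y_px = 10, x_px = 10 + 0.8 / px)
  m2 <- match_spots(a, b, px)
  expect_equal(nrow(m2$matched), 0)
  expect_equal(m2$unmatched_a, 1L)
  expect_equal(m2$unmatched_b, 1L)
})

test_that("greedy matching equals the optimal assignment on jittered instances and is swap-stable", {
  px <- 0.13
  for (seed in 1:5) {
    set.seed(seed)
    a <- data.frame(y_px = runif(5, 10, 90), x_px = runif(5, 10, 90))
    # separated spots jittered by sigma = 0.1 um
    b <- data.frame(y_px = a$y_px + rnorm(5, 0, 0.1 / px / sqrt(2)),
                    x_px = a$x_px + rnorm(5, 0, 0.1 / px / sqrt(2)))
    m <- match_spots(a, b, px)
    oracle <- brute_force_matching(a, b, px, 0.5)
    expect_equal(nrow(m$matched), oracle$n)
    got <- m$matched[order(m$matched$idx_a), c("idx_a", "idx_b")]
    want <- oracle$pairs[order(oracle$pairs[, "a"]), , drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(want))

    sw <- match_spots(b, a, px)
    swapped <- sw$matched[order(sw$matched$idx_b), c("idx_b", "idx_a")]
    expect_equal(unname(as.matrix(swapped)), unname(as.matrix(got)))
  }
})

test_that("cohort percentages follow their definitions and the simulator truth tally", {
  all_matched <- list(
    list(matched = data.frame(idx_a = 1), unmatched_a = integer(),
         unmatched_b = integer(), n_a = 1, n_b = 1),
    list(matched = data.frame(idx_a = 1), unmatched_a = integer(),
         unmatched_b = integer(), n_a = 1, n_b = 1))
  s <- percent_cells_colocalized(all_matched)
  expect_equal(s$pct_cells_colocalized, 100)
  expect_equal(s$pct_cells_uncolocalized, 0)

  none <- list(list(matched = data.frame(), unmatched_a = 1L,
                    unmatched_b = 1L, n_a = 1, n_b = 1))
  s0 <- percent_cells_colocalized(none)
  expect_equal(s0$pct_cells_colocalized, 0)
  expect_equal(s0$pct_cells_uncolocalized, 100)

  # half-colocalized truth: match truth spot lists and compare to the tally
  cfg <- scene_config(n_cells = 10, foci_per_cell_mean = 6, n_channels = 2,
                      coloc_fraction = 0.5, seed = 17)
  sc <- generate_scene(cfg, truth_only = TRUE)
  f <- sc$truth$foci
  results <- lapply(1:10, function(id) {
    fc <- f[f$cell_id == id, ]
    match_spots(
      data.frame(y_px = fc$y_px[fc$in_a], x_px = fc$x_px[fc$in_a]),
      data.frame(y_px = fc$y_b_px[fc$in_b], x_px = fc$x_b_px[fc$in_b]),
      cfg$pixel_size_um)
  })
  got <- percent_cells_colocalized(results)
  eligible <- vapply(1:10, function(id) {
    fc <- f[f$cell_id == id, ]
    sum(fc$in_a) > 0 && sum(fc$in_b) > 0
  }, TRUE)
  truth_coloc <- vapply(1:10, function(id) {
    fc <- f[f$cell_id == id, ]
    any(fc$in_a & fc$in_b)
  }, TRUE)
  expect_equal(got$n_cells_with_both_signals, sum(eligible))
  expect_equal(got$pct_cells_colocalized,
               100 * sum(truth_coloc[eligible]) / sum(eligible))
})

test_that("fully co-labelled scenes give near-unity colocalization and separated scenes a low Pearson floor", {
  cfg1 <- scene_config(n_cells = 10, foci_per_cell_mean = 15,
                       n_channels = 2, coloc_fraction = 1, seed = 21)
  sc1 <- generate_scene(cfg1)
  res1 <- coloc_scene(sc1, small_calib(), detect_params_for(cfg1))
  expect_gte(median(res1$per_cell$pearson_r), 0.9)
  expect_equal(res1$summary$pct_cells_colocalized, 100)

  cfg0 <- scene_config(n_cells = 10, foci_per_cell_mean = 15,
                       n_channels = 2, coloc_fraction = 0, seed = 22)
  sc0 <- generate_scene(cfg0)
  res0 <- coloc_scene(sc0, small_calib(), detect_params_for(cfg0))
  expect_lte(median(res0$per_cell$pearson_r), 0.3)
})
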