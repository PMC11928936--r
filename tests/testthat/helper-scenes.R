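# Shared fixtures, generated once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_scene <- function() fixture("small_scene",
  generate_scene(scene_config(n_cells = 8, foci_per_cell_mean = 15.8,
                              seed = 11)))

small_mock <- function() fixture("small_mock",
  generate_mock_cells(scene_config(n_cells = 10, seed = 12)))

small_calib <- function() fixture("small_calib", {
  sc <- small_scene()
  calibrate_on_mock(small_mock(), detect_params_for(sc$config))
})

default_params <- function() detect_params_for(scene_config())

# Count foci over several simulated fields with a shared calibration.
count_over_fields <- function(lambda, n_fields, cells_per_field, calib,
                              params, seed0) {
  counts <- integer(0)
  for (i in seq_len(n_fields)) {
    sc <- generate_scene(scene_config(
      n_cells = cells_per_field, foci_per_cell_mean = lambda,
      seed = derive_seed(seed0, i)))
    counts <- c(counts, count_scene_foci(sc, calib, params)$n_foci)
  }
  counts
}

# Exhaustive minimum-total-distance one-to-one assignment among pairs within
# the radius, maximising the number of matched pairs first (exact oracle for
# small instances).
brute_force_matching <- function(spots_a, spots_b, pixel_size_um,
                                 max_distance_um) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  d <- sqrt(outer(spots_a$y_px, spots_b$y_px, `-`)^2 +
            outer(spots_a$x_px, spots_b$x_px, `-`)^2) * pixel_size_um
  best <- list(n = -1L, total = Inf, pairs = NULL)
  if (na == 0 || nb == 0) return(list(n = 0L, total = 0, pairs = NULL))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  idx_b <- seq_len(nb)
  for (sz in min(na, nb):0) {
    if (sz < best$n) break
    combs_a <- utils::combn(na, sz, simplify = FALSE)
    combs_b <- utils::combn(nb, sz, simplify = FALSE)
    for (ca in combs_a) for (cb in combs_b) for (pb in perms(cb)) {
      dist <- d[cbind(ca, pb)]
      if (all(dist <= max_distance_um)) {
        tot <- sum(dist)
        if (sz > best$n || (sz == best$n && tot < best$total))
          best <- list(n = sz, total = tot,
                       pairs = cbind(a = ca, b = pb))
      }
    }
    if (best$n == sz && best$n >= 0) break
  }
  best
}
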