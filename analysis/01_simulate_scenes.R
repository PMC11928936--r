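#!/usr/bin/env Rscript
# Generate the simulated imaging conditions analysed by the rest of the
# workflow: a mock (focus-free) calibration set, a plasmid-regime cohort
# (15.8 foci/cell), an excised-cassette cohort (0.09 foci/cell), and a fully
# co-labelled two-channel cohort. Scenes are written under results/scenes/.

library(fociscope)

seed <- 1L
out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("mock calibration set (2 fields x 25 cells)")
for (i in 1:2)
  write_scene(generate_mock_cells(
    scene_config(n_cells = 25L, seed = derive_seed(seed, 100 + i))),
    file.path(out, sprintf("mock_%02d", i)))

message("plasmid-regime cohort (4 fields x 25 cells, lambda = 15.8)")
for (i in 1:4)
  write_scene(generate_scene(
    scene_config(n_cells = 25L, foci_per_cell_mean = 15.8,
                 seed = derive_seed(seed, 110 + i))),
    file.path(out, sprintf("plasmid_%02d", i)))

message("cassette-regime cohort (4 fields x 25 cells, lambda = 0.09)")
for (i in 1:4)
  write_scene(generate_scene(
    scene_config(n_cells = 25L, foci_per_cell_mean = 0.09,
                 seed = derive_seed(seed, 120 + i))),
    file.path(out, sprintf("cassette_%02d", i)))

message("co-labelled two-channel cohort (30 cells, coloc_fraction = 1)")
write_scene(generate_scene(
  scene_config(n_cells = 30L, foci_per_cell_mean = 15, n_channels = 2L,
               coloc_fraction = 1, seed = derive_seed(seed, 300))),
  file.path(out, "coloc_high"))

message("done; scenes under ", out)
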