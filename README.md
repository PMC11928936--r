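# fociscope

Quantification of false-positive nuclear RNA foci in fluorescence
microscopy.

CRISPR imaging systems that read out fluorescently tagged sgRNAs — and, more
generally, FISH-type experiments on transiently transfected cells — can show
bright nuclear puncta that are not genomic loci but condensates of spurious
(cryptic) plasmid transcripts. Deciding whether a punctum is real, counting
foci per cell against a negative-control baseline, measuring two-channel
colocalization, and characterizing the liquid-droplet behaviour of the foci
are quantification problems. This package implements those procedures as a
tested R pipeline for microscopists and image analysts, driven end-to-end by
a synthetic-microscopy generator with known ground truth.

## The core statistic

Each candidate punctum on the maximum-intensity projection of a 3D stack is
scored by its signal-to-background ratio

```
SBR = F_candidate_spot / F_nucleus
```

with `F_candidate_spot` the maximum spot intensity and `F_nucleus` the mean
nucleoplasmic intensity outside spots. The calling threshold is an
*empirical null*: the maximum SBR found among candidates in mock
(focus-free) control cells. Calls are strictly greater-than, so
re-applying a calibration to its own mock set calls exactly zero foci, and
the statistic is invariant to global intensity gain.

Around that core the package provides Laplacian-of-Gaussian candidate
detection, per-cell counting with mean ± SEM summaries, pixel Pearson
correlation on equal-sized nuclear crops plus object-level spot matching at
a 0.5 µm radius (two-channel colocalization), photobleaching correction,
fusion-event tracking with deblended aperture photometry, circularity, and
Welch/ANOVA + Dunnett-T3-style condition comparisons.

## Worked example

```r
library(fociscope)

params <- detect_params_for(scene_config())

# empirical-null threshold from 50 simulated mock cells
mock  <- lapply(1:2, function(i)
  generate_mock_cells(scene_config(n_cells = 25, seed = derive_seed(1, 100 + i))))
calib <- calibrate_on_mock(mock, params)
calib
#> <threshold_calibration> SBR > 1.472 (50 mock cells, 36 candidates)

# count foci in a high-rate cohort (true rate 15.8 foci/cell)
sc <- generate_scene(scene_config(n_cells = 25, foci_per_cell_mean = 15.8,
                                  seed = 11))
s  <- summarize_counts(count_scene_foci(sc, calib, params))
c(mean = s$mean, sem = s$sem)
#>      mean       sem
#> 16.080000  0.780854
```

The mock-derived SBR cutoff lands near 1.5 (the same regime as thresholds
reported for real mock-nucleofected cells, ~1.6), and the detected mean
(16.08 ± 0.78 foci/cell) recovers the generating rate within sampling error.
Re-applying `calib` to the mock scenes yields zero calls in every cell.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study on simulated
data, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_scenes.R` | generates mock, high-rate (15.8 foci/cell), marginal-rate (0.09 foci/cell) and co-labelled two-channel cohorts |
| `02_calibrate_and_count.R` | calibrates the SBR threshold on the mock set; per-cell counts and cohort summaries |
| `03_colocalization.R` | per-cell Pearson r on nuclear crops + object matching; cohort percentages |
| `04_fusion_dynamics.R` | bleach-corrects a fusion time series, tracks the two spots, locates the merge, checks intensity conservation |
| `05_condition_comparisons.R` | control vs count-knockdown vs intensity-reduced arms; Welch/ANOVA + Dunnett-T3-style tests |

Run them in order with `Rscript analysis/01_simulate_scenes.R` etc.

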