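#!/usr/bin/env Rscript
# Track a simulated condensate fusion event: bleach-correct the time series,
# link the two spots across frames, locate the merge, and verify that the
# combined background-subtracted intensity is conserved across it.
# Writes results/fusion_track.csv.

library(fociscope)

cfg <- scene_config(bleach_rate = 0.05, seed = 42L)
fs <- generate_fusion_series(cfg, n_frames = 25,
                             approach_speed_um_per_frame = 0.1)
bc <- correct_photobleaching(fs$series, fs$nucleus_mask)
track <- track_fusion(bc$corrected, fs$nucleus_mask, detect_params_for(cfg))

mf <- fs$truth$merge_frame
ci <- track$intensity$combined
message(sprintf("truth merge frame %d, detected %d", mf, track$merge_frame))
message(sprintf("combined intensity change across the merge: %.1f%%",
                100 * abs(ci[mf + 1] - ci[mf - 1]) / ci[mf - 1]))

dir.create("results", showWarnings = FALSE)
out <- track$intensity
out$gain <- bc$gains
write.csv(out, "results/fusion_track.csv", row.names = FALSE)
message("wrote results/fusion_track.csv")
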