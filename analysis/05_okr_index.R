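#!/usr/bin/env Rscript
# Saccade detection and the OKR index on the simulated eye trace: count
# saccades in the stimulus-expected direction minus the opposite direction
# within the optogenetic-stimulation window, averaged over both eyes.
# Expects 01_simulate_data.R.

library(visdevstats)

tr <- read_eye_trace("results/data/okr_trace.csv", expected_direction = 1)
ev <- detect_saccades(tr, velocity_threshold = 100, refractory = 0.5)
message(nrow(ev), " saccades detected")

opto <- range(tr$time[tr$phase == "opto"])
idx <- okr_index(ev, expected_direction = 1, window = opto)
message(sprintf("OKR index: left %g, right %g, combined %g (window %g-%g s)",
                idx$index_left, idx$index_right, idx$combined,
                opto[1], opto[2]))
dir.create("results/okr", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(idx, "results/okr/okr_index.json", auto_unbox = TRUE,
                     digits = NA)
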