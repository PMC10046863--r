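#!/usr/bin/env Rscript
# Step 1 -- simulate a synthetic gambling-task session.
#
# The study conditions this emulates: 64-channel EEG at 250 Hz, TR = 2 s,
# 560 volumes (80 trials of 14 s = 18 min 40 s), 90 AAL ROIs. This driver
# runs a half-size session (40 trials -> 280 volumes, 16 channels, 30 ROIs)
# so the whole analysis finishes in minutes on one CPU; every generator
# takes the full-scale values if you have the patience.

library(cmtfusion)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_trials <- 40; TR <- 2; fs <- 250
R_true <- 2; K <- 2; Q <- 1
If <- 58; Ic <- 16; Iv <- 30
snr_db <- 20; seed <- 1L

stim <- generate_stimulus_timecourse(n_trials, TR = TR, condition = "both",
                                     seed = seed)
message(sprintf("paradigm: %d trials, %d volumes, %d feedback volumes",
                n_trials, length(stim$values), sum(stim$values)))

gt <- generate_ground_truth(R_true, K, Q,
                            dims = c(length(stim$values), If, Ic, Iv),
                            stimulus = stim, seed = seed)
message(sprintf("ground truth: %d sources; stimulus component %d correlates %.2f with the paradigm",
                R_true, gt$stim_component_index,
                cor(gt$S[, gt$stim_component_index], stim$values)))

basis <- build_hrf_basis(K = K, TR = TR, duration = 32)
raw <- synthesize_raw_eeg(gt, fs = fs, TR = TR, snr_db = snr_db, seed = seed + 1L)
Y <- assemble_fmri_matrix(gt, basis, snr_db = snr_db, seed = seed + 2L)

saveRDS(gt, file.path(out, "ground_truth.rds"))
saveRDS(raw, file.path(out, "raw_eeg.rds"))
write_roi_tsv(Y, file.path(out, "Y.tsv"))
write_events_tsv(stim, file.path(out, "events.tsv"))
write.table(hrf_basis_table(basis), file.path(out, "hrf_basis.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("raw EEG: %d samples x %d channels; ROI matrix: %d x %d",
                nrow(raw), ncol(raw), nrow(Y$data), ncol(Y$data)))
message("wrote ground_truth.rds, raw_eeg.rds, Y.tsv, events.tsv, hrf_basis.tsv")
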