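#!/usr/bin/env Rscript
# Step 2 -- tensorize the raw EEG: segment per fMRI volume, multitaper
# spectrum per segment and channel, average squared Fourier amplitudes into
# 0.5 Hz bins on [1, 30) Hz.

library(cmtfusion)

out <- "results/analysis"
raw <- readRDS(file.path(out, "raw_eeg.rds"))
gt <- readRDS(file.path(out, "ground_truth.rds"))
fs <- attr(raw, "fs"); TR <- attr(raw, "TR")
n_volumes <- nrow(raw) / (fs * TR)

X <- build_eeg_tensor(raw, fs = fs, TR = TR, n_volumes = n_volumes,
                      edges = default_freq_edges(), NW = 2, n_tapers = 3)
message(sprintf("EEG tensor: %d segments x %d bins x %d channels, all nonnegative: %s",
                dim(X$data)[1], dim(X$data)[2], dim(X$data)[3],
                all(X$data >= 0)))

# sanity: the frequency marginal should peak where the planted spectral
# signatures put their bumps
marg <- apply(X$data, 2, sum)
centers <- (X$freq_bin_edges[-1] + X$freq_bin_edges[-length(X$freq_bin_edges)]) / 2
planted <- centers[apply(gt$F, 2, which.max)]
message(sprintf("frequency marginal peaks at %.1f Hz; planted bumps at %s Hz",
                centers[which.max(marg)],
                paste(sprintf("%.1f", planted), collapse = ", ")))

saveRDS(X, file.path(out, "X.rds"))
message("wrote X.rds")
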