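#!/usr/bin/env Rscript
# Step 4 -- model selection with the four indicators: CORCONDIA of the EEG
# factors, reproducibility under graph-structured clustering (retain
# clusters present in more than min_cardinality runs), similarity of the
# temporal signature to the stimulus timecourse, and SnPM significance of
# the spatial signature at FWE alpha = 0.05.

library(cmtfusion)

out <- "results/analysis"
X <- readRDS(file.path(out, "X.rds"))
Y <- read_roi_tsv(file.path(out, "Y.tsv"), TR = 2)
ensembles <- readRDS(file.path(out, "ensembles.rds"))
events <- read_events_tsv(file.path(out, "events.tsv"))
stim <- events_to_timecourse(events, nrow(Y$data), TR = 2, condition = "both")

# retention bound scaled with the ensemble size (study rule: > 10 of 50)
n_runs <- length(ensembles[[1]])
min_card <- ceiling(n_runs * 10 / 50)

reports <- lapply(ensembles, function(ens) {
  evaluate_candidate(X, Y, ens, stim, threshold = 0.9,
                     min_cardinality = min_card,
                     alpha = 0.05, n_perm = 499, seed = 7L)
})
sel <- select_best_model(reports, corcondia_min = 80)
print(sel)

snpm <- sel$chosen_report$snpm
message(sprintf("chosen R = %d; stimulus component similarity %.3f; %d ROI(s) significant at FWE 0.05",
                sel$chosen_R, sel$chosen_report$best$similarity,
                length(snpm$significant)))

gt <- readRDS(file.path(out, "ground_truth.rds"))
planted <- which(gt$V[, gt$stim_component_index] != 0)
message(sprintf("planted active ROIs: %s", paste(planted, collapse = ", ")))
message(sprintf("detected ROIs:       %s", paste(snpm$significant, collapse = ", ")))

saveRDS(sel, file.path(out, "selection.rds"))
write.table(sel$trace, file.path(out, "indicators.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote selection.rds, indicators.tsv")
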