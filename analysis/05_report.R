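#!/usr/bin/env Rscript
# Step 5 -- export the selected model: per-component signature tables
# (temporal, spectral, channel, ROI), the indicator table, and the
# significant-ROI list.

library(cmtfusion)

out <- "results/analysis"
sel <- readRDS(file.path(out, "selection.rds"))
Y <- read_roi_tsv(file.path(out, "Y.tsv"), TR = 2)

write_report(sel, sel$chosen_report$model, out, roi_labels = Y$roi_labels)
tsvs <- list.files(out, pattern = "^component.*tsv$")
message(sprintf("wrote %d signature tables, indicators.tsv and significant_rois.tsv under %s",
                length(tsvs), out))

sig <- read.delim(file.path(out, "significant_rois.tsv"))
if (nrow(sig) > 0) {
  message("significant ROIs (FWE alpha = 0.05):")
  print(sig, row.names = FALSE)
} else {
  message("no ROI exceeded the FWE threshold")
}
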