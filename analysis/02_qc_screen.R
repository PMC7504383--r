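#!/usr/bin/env Rscript
# Step 2: quality-control the model spectra and screen outliers before any
# modeling. Reads the bundle written by 01_simulate.R, flags spectra with
# elevated visible reflectance, detector-splice jumps, or an inverted red
# edge, plus residual/trait-extreme outliers, and writes the QC report and
# the outlier list under results/qc/.

suppressMessages(library(fluospec))

metadata <- read.csv("results/data/metadata.csv", stringsAsFactors = FALSE)
spectra <- read_spectra_csv("results/data/spectra.csv", metadata)
traits <- read.csv("results/data/traits.csv", stringsAsFactors = FALSE)

set <- subset_range(spectra, 400, 2400)
qc <- qc_report(set)
screen <- screen_outliers(set, traits$PhiPSII, n_components = 8)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.csv(qc, "results/qc/qc_report.csv", row.names = FALSE)
write.csv(screen, "results/qc/outliers.csv", row.names = FALSE)

cat("QC:", sum(!qc$pass), "of", nrow(qc), "spectra flagged\n")
print(table(flags = qc$flags[!qc$pass]))
cat("\nOutlier screen (union of reasons):",
    length(unique(screen$sample_id)), "samples\n")
print(table(reason = screen$reason))
planted <- metadata$sample_id[metadata$defect != ""]
flagged <- unique(screen$sample_id[screen$reason == "QC_SPECTRAL"])
cat(sprintf("\nPlanted-defect recall: %d/%d; clean spectra flagged: %d\n",
            sum(planted %in% flagged), length(planted),
            length(setdiff(flagged, planted))))
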