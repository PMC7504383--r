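#!/usr/bin/env Rscript
# Step 4: hyperspectral phenotyping of the ozone treatments from the full
# 400-2400 nm spectral signatures of the 24 phenotyping plants: PERMANOVA
# (Euclidean, 10,000 permutations), PCoA, and a PLS-DA grid search over
# calibration:validation ratios {50:50, 70:30, 80:20} and component counts
# scored by validation Cohen's kappa. Writes results under
# results/phenotyping/.

suppressMessages(library(fluospec))

meta <- read.csv("results/data/pheno_metadata.csv", stringsAsFactors = FALSE)
spectra <- read_spectra_csv("results/data/pheno_spectra.csv", meta)
set <- subset_range(spectra, 400, 2400)
groups <- meta$treatment

pm <- permanova(set, groups, n_permutations = 10000, seed = 3)
pc <- pcoa(set)
grid <- plsda_grid(set, groups, component_grid = 1:8, n_iter = 500, seed = 4)

dir.create("results/phenotyping", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(unclass(pm)[c("pseudo_f", "p_value", "ss_total",
                                   "ss_among", "ss_within",
                                   "n_permutations")],
                     "results/phenotyping/permanova.json",
                     auto_unbox = TRUE, digits = NA)
scores <- data.frame(sample_id = meta$sample_id, treatment = groups,
                     pc$scores[, 1:min(4, ncol(pc$scores))])
write.csv(scores, "results/phenotyping/pcoa_scores.csv", row.names = FALSE)
write.csv(grid$grid, "results/phenotyping/plsda_grid.csv", row.names = FALSE)
write.csv(as.data.frame.matrix(grid$best_confusion),
          "results/phenotyping/confusion_best.csv")

print(pm)
cat(sprintf("\nPCoA: axis 1 carries %.1f%%, axis 2 %.1f%% of the variance\n",
            100 * pc$proportion[1], 100 * pc$proportion[2]))
print(grid)
cat("\nBest-cell confusion (rows = reference, summed over validation splits):\n")
print(grid$best_confusion)
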