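#!/usr/bin/env Rscript
# Step 5: univariate treatment-effect testing on the spectra-derived
# traits and vegetation indices of the phenotyping plants: Shapiro-Wilk
# normality check, one-way ANOVA, Tukey letters. Writes
# results/stats/anova.csv and results/stats/tukey.csv.

suppressMessages(library(fluospec))

meta <- read.csv("results/data/pheno_metadata.csv", stringsAsFactors = FALSE)
predicted <- read.csv("results/models/predicted_traits.csv",
                      stringsAsFactors = FALSE)
spectra <- read_spectra_csv("results/data/pheno_spectra.csv", meta)
stopifnot(identical(predicted$sample_id, meta$sample_id))

indices <- compute_indices(spectra)
traits <- cbind(predicted[setdiff(names(predicted), "sample_id")],
                indices[setdiff(names(indices), "sample_id")])
tests <- trait_treatment_tests(traits, meta$treatment)

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)
write.csv(tests$anova, "results/stats/anova.csv", row.names = FALSE)
write.csv(tests$tukey, "results/stats/tukey.csv", row.names = FALSE)

cat("One-way ANOVA per spectra-derived trait/index:\n")
print(tests$anova, digits = 3, row.names = FALSE)
cat("\nTukey letters (groups sharing a letter do not differ at alpha = 0.05):\n")
print(tests$tukey, digits = 3, row.names = FALSE)

sig <- tests$anova$trait[tests$anova$p_value < 0.05]
cat("\nTraits with a significant ozone effect:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
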