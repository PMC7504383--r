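#!/usr/bin/env Rscript
# Step 1: generate the synthetic ozone-FACE study that the rest of the
# workflow analyses: 102 paired PAM + reflectance samples for model
# building (10% with planted acquisition defects) and 8 plants x 3 ozone
# treatments measured for reflectance only. Writes the CSV bundle under
# results/data/.

suppressMessages(library(fluospec))

cfg <- synthetic_config(seed = 1)
study <- generate_study(cfg)
write_study(study, "results/data")

cat("Simulated study (seed", cfg$seed, "):\n")
print(study)
tr <- study$truth_traits
by_trt <- function(v) tapply(v, study$metadata$treatment, mean)
cat("\nMean PhiPSII by treatment (truth):\n")
print(round(by_trt(tr$PhiPSII), 3))
cat("Mean qN by treatment (truth):\n")
print(round(by_trt(tr$qN), 3))
cat("\nPlanted defects:", sum(study$artifact_flags$defect != ""), "of",
    nrow(study$pam), "model spectra\n")
cat("Bundle written to results/data/\n")
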