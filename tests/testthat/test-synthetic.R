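test_that("generated yields satisfy the physical ordering constraints", {
  cfg <- synthetic_config(seed = 40, n_model_samples = 10000L)
  pam <- generate_pam_readings(cfg)
  expect_true(all(pam$F0 > 0))
  expect_true(all(pam$F0 < pam$Fm))
  expect_true(all(pam$F0_prime > 0))
  expect_true(all(pam$F0_prime <= pam$Fs))
  expect_true(all(pam$Fs < pam$Fm_prime))
  expect_true(all(pam$Fm_prime <= pam$Fm))
})

test_that("configured treatment effects are recovered at large n", {
  cfg <- synthetic_config(seed = 41, n_model_samples = 6000L)
  pam <- generate_pam_readings(cfg)
  tr <- derive_chlf(pam[, c("F0", "Fm", "Fs", "Fm_prime", "F0_prime", "ppfd")])
  tr$treatment <- pam$treatment
  phi_ratio <- mean(tr$PhiPSII[tr$treatment == "EO"]) /
    mean(tr$PhiPSII[tr$treatment == "AA"])
  qn_ratio <- mean(tr$qN[tr$treatment == "EO"]) /
    mean(tr$qN[tr$treatment == "AA"])
  expect_equal(phi_ratio, 0.70, tolerance = 0.02 / 0.70)
  expect_equal(qn_ratio, 1.21, tolerance = 0.02)
  # the moderate treatment and Fv/Fm are untouched
  mo_ratio <- mean(tr$PhiPSII[tr$treatment == "MO"]) /
    mean(tr$PhiPSII[tr$treatment == "AA"])
  expect_equal(mo_ratio, 1, tolerance = 0.03)
  fvfm_ratio <- mean(tr$FvFm[tr$treatment == "EO"]) /
    mean(tr$FvFm[tr$treatment == "AA"])
  expect_equal(fvfm_ratio, 1, tolerance = 0.01)
})

test_that("identical seeds give identical studies, different seeds differ", {
  a <- generate_study(synthetic_config(seed = 42, n_model_samples = 12))
  b <- generate_study(synthetic_config(seed = 42, n_model_samples = 12))
  d <- generate_study(synthetic_config(seed = 43, n_model_samples = 12))
  expect_identical(a$pam, b$pam)
  expect_identical(a$spectra$reflectance, b$spectra$reflectance)
  expect_false(identical(a$spectra$reflectance, d$spectra$reflectance))
  expect_identical(dim(a$spectra$reflectance), dim(d$spectra$reflectance))
})

test_that("spectra are deterministic functions of traits when noise is zero", {
  cfg <- synthetic_config(seed = 44, spectral_noise_sd = 0, trait_noise_sd = 0)
  traits <- data.frame(PhiPSII = c(0.5, 0.5, 0.6), qN = 0.35, FvFm = 0.78,
                       Fm = 0.45)
  meta <- data.frame(sample_id = c("a", "b", "c"))
  set <- generate_spectra(traits, meta, cfg, seed = 45)
  # rows 1 and 2 share identical traits: identical spectra at zero noise
  expect_identical(set$reflectance[1, ], set$reflectance[2, ])
  # a larger PhiPSII deepens the 685 nm chlorophyll feature
  i685 <- match(685L, set$wavelengths)
  i800 <- match(800L, set$wavelengths)
  depth_row <- function(i) set$reflectance[i, i800] - set$reflectance[i, i685]
  expect_gt(depth_row(3), depth_row(1))
})

test_that("artifact injection hits exactly the configured fraction", {
  study <- generate_study(synthetic_config(seed = 47, n_model_samples = 100))
  expect_equal(sum(study$artifact_flags$defect != ""), 10L)
  # fraction zero is a no-op
  cfg0 <- synthetic_config(seed = 47, artifact_fraction = 0)
  clean <- generate_spectra(study$truth_traits, study$metadata, cfg0, seed = 1)
  out <- inject_artifacts(clean, cfg0, seed = 1)
  expect_identical(out$spectra$reflectance, clean$reflectance)
  expect_true(all(out$flags$defect == ""))
})

test_that("a study has the expected sample counts and aligned ids", {
  study <- generate_study(synthetic_config(seed = 48))
  expect_equal(nrow(study$pam), 102L)
  expect_equal(nrow(study$pheno_metadata), 24L)
  expect_identical(study$pam$sample_id, study$truth_traits$sample_id)
  expect_identical(study$pam$sample_id, study$spectra$sample_ids)
  expect_identical(study$pheno_metadata$sample_id,
                   study$pheno_spectra$sample_ids)
  expect_true(all(table(study$pheno_metadata$treatment) == 8L))
  # reflectance bounded before QC
  expect_true(all(study$spectra$reflectance >= 0 &
                  study$spectra$reflectance <= 1.2))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_model_samples = 2), ">= 3")
  expect_error(synthetic_config(artifact_fraction = 0.6), "artifact_fraction")
  expect_error(synthetic_config(spectral_noise_sd = -1), "spectral_noise_sd")
  expect_error(synthetic_config(effect_phi_psii = -1.2), "effect")
})

test_that("the CSV bundle round-trips spectra and metadata", {
  study <- generate_study(synthetic_config(seed = 49, n_model_samples = 6))
  dir <- tempfile("study")
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "spectra.csv", "pam.csv", "traits.csv", "metadata.csv",
    "pheno_spectra.csv", "pheno_metadata.csv", "config.json")))))
  back <- read_spectra_csv(file.path(dir, "spectra.csv"))
  expect_equal(back$reflectance, study$spectra$reflectance,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$sample_ids, study$spectra$sample_ids)
  unlink(dir, recursive = TRUE)
})
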