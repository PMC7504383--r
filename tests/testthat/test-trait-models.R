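test_that("fit statistics match hand computation", {
  obs <- c(0, 1, 2)
  fs <- fit_stats(obs, c(0, 0, 0))
  expect_equal(fs$rmse, sqrt(5 / 3), tolerance = 1e-10)
  expect_equal(fs$pct_rmse, 100 * sqrt(5 / 3) / 2, tolerance = 1e-10)
  perfect <- fit_stats(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$bias, 0)
  shifted <- fit_stats(obs, obs + 0.1)
  expect_equal(shifted$bias, 0.1)
  expect_equal(shifted$r2, 1)
  expect_error(fit_stats(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("pct_rmse is invariant under affine rescaling of the trait", {
  set.seed(20)
  obs <- rnorm(30)
  pred <- obs + rnorm(30, 0, 0.3)
  a <- fit_stats(obs, pred)
  b <- fit_stats(10 * obs + 5, 10 * pred + 5)
  expect_equal(a$pct_rmse, b$pct_rmse, tolerance = 1e-10)
})

test_that("split ensembles separate signal from null and are reproducible", {
  study <- generate_study(synthetic_config(seed = 21, artifact_fraction = 0))
  sub <- subset_range(study$spectra, 600, 900)
  X <- sub$reflectance
  # noiseless linear response: the leading principal component of X
  y_lin <- as.numeric(prcomp(X, center = TRUE)$x[, 1])
  ens_lin <- permutation_ensemble(X, y_lin, 4, n_iter = 50, seed = 1)
  expect_gte(ensemble_stat(ens_lin, "val_r2"), 0.99)
  # permuted-label null
  y_null <- sample(study$truth_traits$PhiPSII)
  ens_null <- permutation_ensemble(X, y_null, 4, n_iter = 50, seed = 1)
  expect_lte(ensemble_stat(ens_null, "val_r2"), 0.1)
  # determinism under seed
  again <- permutation_ensemble(X, y_lin, 4, n_iter = 50, seed = 1)
  expect_identical(ens_lin$summary, again$summary)
  # percentile bands bracket the mean profile almost everywhere
  pr <- ens_lin$profiles
  inside <- mean(pr$coef_mean >= pr$coef_p5 & pr$coef_mean <= pr$coef_p95)
  expect_gte(inside, 0.5)
})

test_that("across-seed variability of the ensemble summary shrinks with more splits", {
  study <- generate_study(synthetic_config(seed = 22, artifact_fraction = 0))
  sub <- subset_range(study$spectra, 600, 900)
  X <- sub$reflectance[, seq(1, 301, by = 10)]
  y <- study$truth_traits$PhiPSII
  means_50 <- vapply(1:6, function(s)
    ensemble_stat(permutation_ensemble(X, y, 6, n_iter = 50, seed = s),
                  "val_r2"), numeric(1))
  means_400 <- vapply(1:6, function(s)
    ensemble_stat(permutation_ensemble(X, y, 6, n_iter = 400, seed = s),
                  "val_r2"), numeric(1))
  expect_lt(sd(means_400), sd(means_50))
})

test_that("outlier screen catches planted defects and extreme responses", {
  study <- generate_study(synthetic_config(seed = 23, n_model_samples = 100))
  set <- subset_range(study$spectra, 400, 2400)
  y <- study$truth_traits$PhiPSII
  rep_out <- screen_outliers(set, y, n_components = 8)
  qc_ids <- unique(rep_out$sample_id[rep_out$reason == "QC_SPECTRAL"])
  planted <- study$artifact_flags$sample_id[study$artifact_flags$defect != ""]
  expect_true(all(planted %in% qc_ids))
  expect_lte(length(setdiff(qc_ids, planted)), 2L)
  # a planted 10x-range response outlier is flagged by the residual screen
  y2 <- y
  y2[7] <- max(y) + 10 * diff(range(y))
  rep2 <- screen_outliers(set, y2, n_components = 8)
  flagged7 <- rep2$reason[rep2$sample_id == set$sample_ids[7]]
  expect_true("RESIDUAL" %in% flagged7 || "TRAIT_EXTREME" %in% flagged7)
})

test_that("external validation is consistent and guards against leakage", {
  study <- generate_study(synthetic_config(seed = 24, artifact_fraction = 0))
  sub <- subset_range(study$spectra, 600, 900)
  y <- study$truth_traits$PhiPSII
  n <- length(y)
  ext <- 83:102
  take <- function(idx) spectra_set(sub$reflectance[idx, , drop = FALSE],
                                    sub$wavelengths, sub$sample_ids[idx])
  ens <- permutation_ensemble(take(1:82), y[1:82], 8, n_iter = 100, seed = 2)
  ev <- external_validate(ens, take(ext), y[ext])
  internal <- ensemble_stat(ens, "val_r2")
  expect_lt(abs(ev$r2 - internal), 0.15)
  expect_error(external_validate(ens, take(1:20), y[1:20]), "overlap")
  expect_error(external_validate(ens, take(ext[1]), y[ext[1]]), "at least 2")
})

test_that("trait prediction is gated by external-validation r2", {
  study <- generate_study(synthetic_config(seed = 25, artifact_fraction = 0))
  pipe <- run_trait_pipeline(study, traits = c("PhiPSII", "qN", "FvFm"),
                             n_iter = 30, seed = 3)
  # gate wide open: every modeled trait is predicted
  all_tr <- suppressMessages(
    predict_traits(pipe$bundle, splice_correct(
      subset_range(study$pheno_spectra, 400, 2400)), r2_threshold = 0))
  expect_setequal(setdiff(names(all_tr), "sample_id"),
                  c("PhiPSII", "qN", "FvFm"))
  # impossible gate: nothing is predicted
  none <- suppressMessages(
    predict_traits(pipe$bundle, splice_correct(
      subset_range(study$pheno_spectra, 400, 2400)), r2_threshold = 1.01))
  expect_equal(names(none), "sample_id")
  expect_length(attr(none, "skipped"), 3L)
})
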