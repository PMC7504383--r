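test_that("splice correction removes planted steps and is a no-op otherwise", {
  s <- smooth_spectrum()
  stepped <- add_step(s, 1000, 0.05)
  fixed <- splice_correct(stepped)
  i <- match(1000:1001, fixed$wavelengths)
  jump <- abs(diff(fixed$reflectance[i]))
  base_jump <- abs(diff(s$reflectance[i]))
  expect_lt(jump - base_jump, 1e-6)
  # continuous spectrum passes through unchanged up to the continuity anchor
  corrected <- splice_correct(s)
  expect_lt(max(abs(corrected$reflectance[s$wavelengths <= 1000] -
                    s$reflectance[s$wavelengths <= 1000])), 1e-9)
})

test_that("stacked steps at both splices are removed, VNIR anchored", {
  s <- smooth_spectrum()
  stepped <- add_step(add_step(s, 1000, 0.05), 1800, -0.03)
  fixed <- splice_correct(stepped)
  vnir <- s$wavelengths <= 1000
  expect_equal(fixed$reflectance[vnir], s$reflectance[vnir])
  # SWIR values recovered up to the rigid-shift continuity convention:
  # the correction makes r(1001) = r(1000), removing both the planted step
  # and the original curve's own 1-nm increment
  shift1 <- s$reflectance[match(1001, s$wavelengths)] -
    s$reflectance[match(1000, s$wavelengths)]
  swir1 <- s$wavelengths > 1000 & s$wavelengths <= 1800
  expect_lt(max(abs(fixed$reflectance[swir1] -
                    (s$reflectance[swir1] - shift1))), 1e-9)
})

test_that("splice correction is idempotent", {
  s <- add_step(smooth_spectrum(), 1000, 0.05)
  once <- splice_correct(s)
  twice <- splice_correct(once)
  expect_equal(twice$reflectance, once$reflectance, tolerance = 1e-12)
})

test_that("linear resampling: identity on 1-nm input, midpoint mean on 2-nm", {
  s <- smooth_spectrum(400, 900)
  expect_equal(resample_to_grid(s, 400, 900)$reflectance, s$reflectance)
  coarse <- spectrum(seq(400, 900, by = 2), s$reflectance[seq(1, 501, by = 2)])
  fine <- resample_to_grid(coarse, 400, 900)
  expect_equal(fine$reflectance[match(401, fine$wavelengths)],
               mean(s$reflectance[match(c(400, 402), s$wavelengths)]))
  # monotone input stays monotone
  mono <- spectrum(seq(400, 500, by = 5), seq(0.1, 0.6, length.out = 21))
  expect_true(all(diff(resample_to_grid(mono, 400, 500)$reflectance) >= 0))
  expect_error(resample_to_grid(s, 350, 900), "extrapolation")
})

test_that("replicate averaging takes per-wavelength means and records counts", {
  s <- smooth_spectrum(400, 500)
  r <- rbind(s$reflectance, s$reflectance + 0.02, s$reflectance,
             s$reflectance + 0.02)
  set <- spectra_set(r, s$wavelengths, c("a", "a", "b", "b"),
                     allow_replicates = TRUE)
  avg <- average_replicates(set)
  expect_equal(avg$sample_ids, c("a", "b"))
  expect_equal(avg$reflectance[1, ], s$reflectance + 0.01,
               ignore_attr = TRUE)
  expect_equal(avg$metadata$n_replicates, c(2L, 2L))
  # four identical replicates reproduce the spectrum; singles pass through
  same <- average_replicates(spectra_set(rbind(r[1, ], r[1, ], r[1, ], r[1, ]),
                                         s$wavelengths, rep("x", 4),
                                         allow_replicates = TRUE))
  expect_equal(same$reflectance[1, ], r[1, ], ignore_attr = TRUE)
})

test_that("replicate averaging commutes with range subsetting", {
  s <- smooth_spectrum(400, 900)
  set.seed(1)
  r <- matrix(rep(s$reflectance, 6), nrow = 6, byrow = TRUE) +
    matrix(rnorm(6 * length(s$wavelengths), 0, 0.01), nrow = 6)
  set <- spectra_set(r, s$wavelengths, rep(c("a", "b"), each = 3),
                     allow_replicates = TRUE)
  a <- subset_range(average_replicates(set), 600, 800)
  b <- average_replicates(subset_range(set, 600, 800))
  expect_equal(a$reflectance, b$reflectance)
})

test_that("range subsetting is inclusive and validates its bounds", {
  s <- smooth_spectrum()
  set <- spectra_set(matrix(s$reflectance, 1), s$wavelengths, "x")
  expect_equal(ncol(subset_range(set, 400, 2400)$reflectance), 2001L)
  expect_equal(ncol(subset_range(set, 600, 900)$reflectance), 301L)
  expect_error(subset_range(set, 900, 600), "lo_nm > hi_nm")
})

test_that("qc flags fire on constructed defects and stay silent on clean spectra", {
  cfg <- synthetic_config(seed = 5, artifact_fraction = 0)
  study <- generate_study(cfg)
  set <- subset_range(study$spectra, 400, 2400)
  qc <- qc_report(set)
  expect_true(all(qc$pass))

  s <- get_spectrum(set, 1)
  vis <- s
  sel <- vis$wavelengths <= 700
  vis$reflectance[sel] <- vis$reflectance[sel] + 0.15
  expect_true("VIS_ELEVATED" %in% qc_flags(vis)$flags)

  stepped <- add_step(s, 1000, 0.05)
  expect_true("SPLICE_JUMP" %in% qc_flags(stepped)$flags)
})

test_that("qc separates planted artifacts from clean spectra perfectly", {
  study <- generate_study(synthetic_config(seed = 3, n_model_samples = 100))
  qc <- qc_report(subset_range(study$spectra, 400, 2400))
  planted <- study$artifact_flags$defect != ""
  expect_true(all(!qc$pass[planted]))   # 100% recall
  expect_true(all(qc$pass[!planted]))   # no false positives
})
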