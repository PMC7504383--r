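#' Configuration for the synthetic ozone-FACE study generator
#'
#' The defaults emulate the study design the pipeline is built for: ~102
#' paired spectra + PAM samples for spectra-trait model building, 8 plants
#' per ozone treatment (ambient air AA, moderate MO, elevated EO) for
#' hyperspectral phenotyping, an elevated-ozone treatment that lowers mean
#' PSII operating efficiency by 30% and raises mean non-photochemical
#' quenching qN by 21% relative to ambient air (MO is left at the ambient
#' distribution), and a 10% rate of defective spectra.
#'
#' @param n_model_samples Paired samples for model building (default 102).
#' @param n_pheno_plants_per_treatment Plants per treatment for phenotyping
#'   (default 8).
#' @param treatments Treatment labels (default AA, MO, EO; the last label is
#'   the "elevated" treatment that receives the effects).
#' @param effect_phi_psii Fractional change of mean PhiPSII under the
#'   elevated treatment (default -0.30).
#' @param effect_qn Fractional change of mean qN under the elevated
#'   treatment (default +0.21).
#' @param spectral_noise_sd Per-band i.i.d. reflectance noise SD (default
#'   0.005).
#' @param trait_noise_sd Noise on the trait-to-absorption-depth mapping, as
#'   a fraction of the trait's realized range (default 0.05).
#' @param ppfd Actinic photon flux density, umol m-2 s-1 (default 270).
#' @param artifact_fraction Fraction of model spectra receiving one planted
#'   acquisition defect (default 0.10; must be <= 0.5).
#' @param seed Integer RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_model_samples = 102L,
                             n_pheno_plants_per_treatment = 8L,
                             treatments = c("AA", "MO", "EO"),
                             effect_phi_psii = -0.30,
                             effect_qn = 0.21,
                             spectral_noise_sd = 0.005,
                             trait_noise_sd = 0.05,
                             ppfd = 270,
                             artifact_fraction = 0.10,
                             seed = 1L) {
  cfg <- list(n_model_samples = as.integer(n_model_samples),
              n_pheno_plants_per_treatment = as.integer(n_pheno_plants_per_treatment),
              treatments = as.character(treatments),
              effect_phi_psii = effect_phi_psii,
              effect_qn = effect_qn,
              spectral_noise_sd = spectral_noise_sd,
              trait_noise_sd = trait_noise_sd,
              ppfd = ppfd,
              artifact_fraction = artifact_fraction,
              seed = as.integer(seed))
  if (cfg$n_model_samples < 3L) stop("n_model_samples must be >= 3")
  if (cfg$n_pheno_plants_per_treatment < 3L) {
    stop("n_pheno_plants_per_treatment must be >= 3")
  }
  if (length(cfg$treatments) < 2L || anyDuplicated(cfg$treatments)) {
    stop("treatments must be >= 2 distinct labels")
  }
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction > 0.5) {
    stop("artifact_fraction must be in [0, 0.5]")
  }
  if (cfg$trait_noise_sd < 0 || cfg$trait_noise_sd > 1) {
    stop("trait_noise_sd must be in [0, 1]")
  }
  if (cfg$spectral_noise_sd < 0) stop("spectral_noise_sd must be >= 0")
  if (cfg$ppfd < 0) stop("ppfd must be >= 0")
  if (1 + cfg$effect_phi_psii <= 0 || 1 + cfg$effect_qn <= 0) {
    stop("effects must keep trait means positive (effect > -1)")
  }
  structure(cfg, class = "synthetic_config")
}

# The elevated treatment is the last label by convention.
elevated_label <- function(config) config$treatments[length(config$treatments)]

#' Generate synthetic PAM fluorescence readings with treatment labels
#'
#' Yields are drawn via a generative model that guarantees internal
#' consistency of all downstream parameters: dark-adapted Fv/Fm ~ truncated
#' Normal(0.78, 0.04) on (0.5, 0.87) and Fm ~ truncated Normal(0.45, 0.05)
#' give F0 = Fm (1 - Fv/Fm); light-adapted latents qP, qN and Fv'/Fm' are
#' sampled and the quenching formulas inverted to recover Fm', F0' and Fs,
#' so the ordering constraints 0 < F0 < Fm and 0 < F0' <= Fs < Fm' <= Fm
#' hold for every sample by construction. Under the elevated treatment the
#' qP latent is multiplied by `1 + effect_phi_psii` (which scales mean
#' PhiPSII by exactly that factor) and the qN latent by `1 + effect_qn`.
#'
#' @param config A [synthetic_config()].
#' @param n Number of samples (default `config$n_model_samples`).
#' @param seed RNG seed (default `config$seed`); `NULL` uses the current
#'   stream.
#' @param id_prefix Prefix for sample ids.
#' @return Data frame with metadata (`sample_id`, `treatment`, `plot`,
#'   `plant`, `date`) and raw yields (`F0`, `Fm`, `Fs`, `Fm_prime`,
#'   `F0_prime`, `ppfd`).
#' @export
generate_pam_readings <- function(config, n = config$n_model_samples,
                                  seed = config$seed, id_prefix = "S") {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    trt <- sample(rep_len(config$treatments, n))
    elev <- trt == elevated_label(config)

    FvFm <- rtrunc_norm(n, 0.78, 0.04, 0.5, 0.87)
    Fm <- rtrunc_norm(n, 0.45, 0.05, 0.2, 0.8)
    F0 <- Fm * (1 - FvFm)
    FvpFmp <- rtrunc_norm(n, 0.75, 0.05, 0.4, 0.95)
    qP <- rtrunc_norm(n, 0.65, 0.05, 0.05, 0.98)
    qN <- rtrunc_norm(n, 0.35, 0.035, 0.05, 0.60)
    qP[elev] <- qP[elev] * (1 + config$effect_phi_psii)
    qN[elev] <- qN[elev] * (1 + config$effect_qn)
    qP <- pmin(qP, 0.995)
    qN <- pmin(qN, 0.9)

    Fmp <- Fm * (1 - qN) / (1 - qN * (1 - FvpFmp))
    F0p <- Fmp * (1 - FvpFmp)
    Fs <- Fmp * (1 - qP * FvpFmp)

    data.frame(
      sample_id = sprintf("%s%03d", id_prefix, seq_len(n)),
      treatment = trt,
      plot = paste0(trt, "-", (seq_len(n) %% 3L) + 1L),
      plant = sprintf("plant%03d", seq_len(n)),
      date = rep_len(c("2019-07-30", "2019-07-31", "2019-08-01", "2019-08-02"), n),
      F0 = F0, Fm = Fm, Fs = Fs, Fm_prime = Fmp, F0_prime = F0p,
      ppfd = config$ppfd,
      stringsAsFactors = FALSE)
  })
}

# Smooth leaf-like reflectance continuum on an integer grid. `nir_amp`
# controls the height of the near-infrared plateau; `wfac` and `pfac` scale
# the water (1450/1930 nm) and protein (1700 nm) absorption depths.
leaf_continuum <- function(wl, nir_amp = 0.38, wfac = 1, pfac = 1) {
  gauss <- function(center, sd) exp(-0.5 * ((wl - center) / sd)^2)
  r <- 0.07 + nir_amp * stats::plogis((wl - 715) / 7) +
    0.035 * gauss(550, 25) -
    0.08 * stats::plogis((wl - 1350) / 100) -
    0.12 * wfac * gauss(1450, 40) -
    0.04 * pfac * gauss(1700, 35) -
    0.22 * wfac * gauss(1930, 55) -
    0.05 * gauss(2300, 60)
  r
}

#' Generate reflectance spectra coupled to chlorophyll fluorescence traits
#'
#' Each spectrum is a smooth leaf-like continuum (visible floor ~0.07,
#' logistic red edge to a near-infrared plateau ~0.45, short-wave-infrared
#' water/protein shoulders) minus Gaussian absorption features whose depths
#' are affine functions of latent trait values plus trait-mapping noise:
#' the 685 nm chlorophyll feature follows PhiPSII, the 650 nm feature
#' follows qN, the 710 nm red-edge feature follows Fv/Fm, the plateau height
#' follows Fm, and the 1450/1930 nm water and 1700 nm protein depths follow
#' a latent partially coupled to PhiPSII (hence to ETR and P). I.i.d.
#' Gaussian noise of SD `spectral_noise_sd` is added per band and the result
#' clipped to [0, 1].
#'
#' @param truth_traits Data frame with at least `PhiPSII`, `qN`, `FvFm`,
#'   `Fm` columns (e.g., from [derive_chlf()]).
#' @param metadata Data frame with `sample_id` (and treatment etc.), aligned
#'   row-for-row with `truth_traits`.
#' @param config A [synthetic_config()].
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A `spectra_set` on the 350-2500 nm 1-nm grid.
#' @export
generate_spectra <- function(truth_traits, metadata, config,
                             seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(truth_traits)
  if (!is.null(metadata) && nrow(metadata) != n) {
    stop("truth_traits and metadata are misaligned (row counts differ)")
  }
  need <- c("PhiPSII", "qN", "FvFm", "Fm")
  if (!all(need %in% names(truth_traits))) {
    stop("truth_traits must contain ", paste(need, collapse = ", "))
  }
  wl <- 350:2500
  gauss <- function(center, sd) exp(-0.5 * ((wl - center) / sd)^2)
  g685 <- gauss(685, 10); g650 <- gauss(650, 15); g710 <- gauss(710, 16)

  with_seed(seed, {
    tn <- function(x) {
      rng <- diff(range(x))
      x + stats::rnorm(n, 0, config$trait_noise_sd * max(rng, 1e-8))
    }
    phi_n <- tn(truth_traits$PhiPSII)
    qn_n <- tn(truth_traits$qN)
    fvfm_n <- tn(truth_traits$FvFm)
    d685 <- pmin(pmax(0.035 + 0.10 * (phi_n - 0.49), 0.001), 0.068)
    d650 <- pmin(pmax(0.022 + 0.10 * (qn_n - 0.35), 0.001), 0.060)
    d710 <- pmin(pmax(0.025 + 0.12 * (fvfm_n - 0.78), 0.002), 0.060)
    nir_amp <- 0.38 + 0.3 * (truth_traits$Fm - 0.45)
    z_phi <- (phi_n - 0.49) / 0.06
    # the trait-independent part of the water/protein latents scales with
    # trait_noise_sd so that noise-free configurations are fully
    # deterministic functions of the traits
    ind <- config$trait_noise_sd / 0.05
    wfac <- 1 + 0.5 * (0.6 * z_phi + 0.8 * ind * stats::rnorm(n))
    wfac <- pmin(pmax(wfac, 0.3), 1.7)
    pfac <- 1 + 0.4 * (0.5 * z_phi + 0.87 * ind * stats::rnorm(n))
    pfac <- pmin(pmax(pfac, 0.3), 1.7)

    r <- matrix(0, n, length(wl))
    for (i in seq_len(n)) {
      r[i, ] <- leaf_continuum(wl, nir_amp[i], wfac[i], pfac[i]) -
        d685[i] * g685 - d650[i] * g650 - d710[i] * g710
    }
    if (config$spectral_noise_sd > 0) {
      r <- r + matrix(stats::rnorm(length(r), 0, config$spectral_noise_sd),
                      nrow = n)
    }
    r <- pmin(pmax(r, 0), 1)
    ids <- if (!is.null(metadata)) metadata$sample_id else
      sprintf("S%03d", seq_len(n))
    spectra_set(r, wl, ids, metadata)
  })
}

#' Plant acquisition defects into a fraction of spectra
#'
#' Exactly `round(artifact_fraction * n)` spectra receive one defect each,
#' drawn uniformly from the three acquisition-error types the QC screen
#' targets: a +0.15 additive offset over 400-700 nm (`VIS_ELEVATED`), a
#' +0.05 step for all wavelengths >= 1001 nm (`SPLICE_JUMP`), and a local
#' inversion (vertical flip) of the 700-750 nm red edge
#' (`REDEDGE_CONCAVE`).
#'
#' @param spectra A `spectra_set` covering 400-1001 nm at least.
#' @param config A [synthetic_config()] (uses `artifact_fraction`).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return List with `spectra` (defects applied) and `flags`, a data frame
#'   `sample_id`, `defect` ("" for clean spectra).
#' @export
inject_artifacts <- function(spectra, config, seed = config$seed) {
  stopifnot(inherits(spectra, "spectra_set"),
            inherits(config, "synthetic_config"))
  n <- nrow(spectra$reflectance)
  n_bad <- round(config$artifact_fraction * n)
  flags <- data.frame(sample_id = spectra$sample_ids,
                      defect = rep("", n), stringsAsFactors = FALSE)
  if (n_bad == 0L) return(list(spectra = spectra, flags = flags))
  wl <- spectra$wavelengths
  r <- spectra$reflectance
  with_seed(seed, {
    victims <- sample.int(n, n_bad)
    types <- sample(c("VIS_ELEVATED", "SPLICE_JUMP", "REDEDGE_CONCAVE"),
                    n_bad, replace = TRUE)
    for (k in seq_len(n_bad)) {
      i <- victims[k]
      if (types[k] == "VIS_ELEVATED") {
        vis <- wl >= 400L & wl <= 700L
        r[i, vis] <- r[i, vis] + 0.15
      } else if (types[k] == "SPLICE_JUMP") {
        r[i, wl >= 1001L] <- r[i, wl >= 1001L] + 0.05
      } else {
        re <- wl >= 700L & wl <= 750L
        lo <- r[i, match(700L, wl)]; hi <- r[i, match(750L, wl)]
        r[i, re] <- lo + hi - r[i, re]
      }
    }
    flags$defect[victims] <- types
    list(spectra = spectra_set(r, wl, spectra$sample_ids, spectra$metadata,
                               allow_replicates = TRUE),
         flags = flags)
  })
}

#' Generate a full synthetic study
#'
#' Composes the PAM, spectra, and artifact generators into one
#' reproducible study object: a model-building set of paired PAM readings +
#' spectra (with planted defects at `artifact_fraction`), and a clean
#' phenotyping set of `n_pheno_plants_per_treatment` plants per treatment
#' measured for reflectance only (their ground-truth traits are retained
#' for checking).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study`: `config`, `pam`,
#'   `truth_traits`, `spectra` (model set, defects included),
#'   `artifact_flags`, `metadata`, `pheno_spectra`, `pheno_truth_traits`,
#'   `pheno_metadata`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    pam <- generate_pam_readings(config, seed = NULL)
    meta_cols <- c("sample_id", "treatment", "plot", "plant", "date")
    metadata <- pam[, meta_cols]
    traits <- derive_chlf(pam[, c("F0", "Fm", "Fs", "Fm_prime", "F0_prime",
                                  "ppfd")], ppfd = config$ppfd)
    traits <- cbind(sample_id = pam$sample_id, traits)
    spectra <- generate_spectra(traits, metadata, config, seed = NULL)
    art <- inject_artifacts(spectra, config, seed = NULL)

    n_ph <- config$n_pheno_plants_per_treatment * length(config$treatments)
    ph_pam <- generate_pam_readings(config, n = n_ph, seed = NULL,
                                    id_prefix = "PH")
    # phenotyping plants are measured in treatment blocks, one plant each
    ph_pam$treatment <- rep(config$treatments,
                            each = config$n_pheno_plants_per_treatment)
    ph_elev <- ph_pam$treatment == elevated_label(config)
    # reassign yields so the block labels carry the configured effects
    ph_pam2 <- regenerate_for_labels(ph_pam, config, ph_elev)
    ph_meta <- ph_pam2[, meta_cols]
    ph_traits <- derive_chlf(ph_pam2[, c("F0", "Fm", "Fs", "Fm_prime",
                                         "F0_prime", "ppfd")],
                             ppfd = config$ppfd)
    ph_traits <- cbind(sample_id = ph_pam2$sample_id, ph_traits)
    ph_spectra <- generate_spectra(ph_traits, ph_meta, config, seed = NULL)

    structure(list(config = config, pam = pam, truth_traits = traits,
                   spectra = art$spectra, artifact_flags = art$flags,
                   metadata = metadata,
                   pheno_spectra = ph_spectra,
                   pheno_truth_traits = ph_traits,
                   pheno_metadata = ph_meta),
              class = "synthetic_study")
  })
}

# Redraw the treatment-affected latents so that a caller-imposed label
# vector (rather than the shuffled labels of generate_pam_readings) carries
# the configured elevated-treatment effects.
regenerate_for_labels <- function(pam, config, elevated) {
  n <- nrow(pam)
  FvFm <- rtrunc_norm(n, 0.78, 0.04, 0.5, 0.87)
  Fm <- rtrunc_norm(n, 0.45, 0.05, 0.2, 0.8)
  FvpFmp <- rtrunc_norm(n, 0.75, 0.05, 0.4, 0.95)
  qP <- rtrunc_norm(n, 0.65, 0.05, 0.05, 0.98)
  qN <- rtrunc_norm(n, 0.35, 0.035, 0.05, 0.60)
  qP[elevated] <- pmin(qP[elevated] * (1 + config$effect_phi_psii), 0.995)
  qN[elevated] <- pmin(qN[elevated] * (1 + config$effect_qn), 0.9)
  Fmp <- Fm * (1 - qN) / (1 - qN * (1 - FvpFmp))
  pam$F0 <- Fm * (1 - FvFm)
  pam$Fm <- Fm
  pam$Fm_prime <- Fmp
  pam$F0_prime <- Fmp * (1 - FvpFmp)
  pam$Fs <- Fmp * (1 - qP * FvpFmp)
  pam
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d model samples (%d defective), %d phenotyping samples>\n",
              nrow(x$pam), sum(x$artifact_flags$defect != ""),
              nrow(x$pheno_metadata)))
  invisible(x)
}

#' Write a synthetic study to a CSV bundle
#'
#' Writes `spectra.csv`, `pam.csv`, `traits.csv`, `metadata.csv`,
#' `pheno_spectra.csv`, `pheno_metadata.csv`, and `config.json` under `dir`.
#' The generating seed is recorded as a `#` comment line in each spectra
#' file.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed_note <- sprintf("seed=%d", study$config$seed)
  write_spectra_csv(study$spectra, file.path(dir, "spectra.csv"), seed_note)
  write_spectra_csv(study$pheno_spectra, file.path(dir, "pheno_spectra.csv"),
                    seed_note)
  utils::write.csv(study$pam, file.path(dir, "pam.csv"), row.names = FALSE)
  utils::write.csv(study$truth_traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(study$metadata,
                         defect = study$artifact_flags$defect),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(study$pheno_metadata, file.path(dir, "pheno_metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(study$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Single-informative-band spectra for diagnostics
#'
#' Generates leaf-like spectra in which only one Gaussian absorption
#' feature carries signal about the response: depth at `center` is affine
#' in `y` while everything else is a fixed continuum plus noise. Used to
#' check that VIP localizes the informative wavelengths.
#'
#' @param n Number of samples.
#' @param center,sd_nm Center and width of the informative feature.
#' @param gain Depth change per unit response.
#' @param noise_sd Per-band noise SD.
#' @param seed RNG seed.
#' @return List with `spectra` (`spectra_set`, 350-2500 nm) and `y`.
#' @export
simulate_band_signal <- function(n = 80L, center = 685, sd_nm = 10,
                                 gain = 0.05, noise_sd = 0.005, seed = NULL) {
  wl <- 350:2500
  with_seed(seed, {
    y <- stats::rnorm(n)
    g <- exp(-0.5 * ((wl - center) / sd_nm)^2)
    base <- leaf_continuum(wl)
    r <- matrix(rep(base, each = n), nrow = n)
    r <- r - (0.03 + gain * 0.2 * outer(y, g))
    r <- r + matrix(stats::rnorm(length(r), 0, noise_sd), nrow = n)
    list(spectra = spectra_set(pmin(pmax(r, 0), 1), wl,
                               sprintf("B%03d", seq_len(n))),
         y = y)
  })
}

#' Well-separated labeled spectra for classification diagnostics
#'
#' Each class of leaf-like spectra deepens its own signature absorption
#' band (chlorophyll 685 nm, water 1450 nm, protein 1700 nm, cycling for
#' more classes) by `separation` times a fixed step, large relative to the
#' noise. Placing the class signatures along different spectral directions
#' keeps every class indicator linear in the spectrum, so the classes are
#' linearly separable at `separation = 1`. With `separation = 0` the
#' classes are identical.
#'
#' @param n_per_class Samples per class.
#' @param classes Class labels.
#' @param separation Scale of the between-class feature steps.
#' @param noise_sd Per-band noise SD.
#' @param seed RNG seed.
#' @return List with `spectra` (`spectra_set`) and `labels`.
#' @export
simulate_labeled_spectra <- function(n_per_class = 8L,
                                     classes = c("AA", "MO", "EO"),
                                     separation = 1, noise_sd = 0.005,
                                     seed = NULL) {
  wl <- 350:2500
  k <- length(classes)
  n <- n_per_class * k
  labels <- rep(classes, each = n_per_class)
  signatures <- list(
    exp(-0.5 * ((wl - 685) / 10)^2),
    exp(-0.5 * ((wl - 1450) / 40)^2),
    exp(-0.5 * ((wl - 1700) / 35)^2))
  with_seed(seed, {
    base <- leaf_continuum(wl)
    r <- matrix(rep(base, each = n), nrow = n)
    cls <- rep(seq_len(k), each = n_per_class)
    for (j in seq_len(k)) {
      sig <- signatures[[(j - 1L) %% length(signatures) + 1L]]
      depth <- separation * 0.04 * (1 + (j - 1L) %/% length(signatures))
      r[cls == j, ] <- r[cls == j, ] - rep(depth * sig, each = sum(cls == j))
    }
    r <- r + matrix(stats::rnorm(length(r), 0, noise_sd), nrow = n)
    list(spectra = spectra_set(pmin(pmax(r, 0), 1), wl,
                               sprintf("C%03d", seq_len(n)),
                               data.frame(sample_id = sprintf("C%03d", seq_len(n)),
                                          treatment = labels)),
         labels = labels)
  })
}
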