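#' Fit statistics for observed vs predicted values
#'
#' `r2` is the squared Pearson correlation between observed and predicted
#' (the convention of observed-vs-predicted regression plots in the
#' spectra-trait literature); `rmse = sqrt(mean((pred - obs)^2))`;
#' `bias = mean(pred - obs)`; `pct_rmse = 100 * rmse / range(obs)` (percent
#' RMSE of the data range).
#'
#' @param observed,predicted Numeric vectors of equal length >= 2;
#'   `observed` must not be constant.
#' @return A list of class `fit_stats`: `r2`, `rmse`, `bias`, `pct_rmse`,
#'   `n`.
#' @export
fit_stats <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  n <- length(observed)
  if (length(predicted) != n) stop("observed and predicted lengths differ")
  if (n < 2L) stop("need at least 2 observations")
  rng <- diff(range(observed))
  if (rng == 0) stop("constant observed values: data range undefined")
  rmse <- sqrt(mean((predicted - observed)^2))
  r <- suppressWarnings(stats::cor(observed, predicted))
  structure(list(r2 = if (is.na(r)) 0 else r^2,
                 rmse = rmse,
                 bias = mean(predicted - observed),
                 pct_rmse = 100 * rmse / rng,
                 n = n),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("r2 = %.3f, RMSE = %.4g, bias = %.4g, %%RMSE = %.1f (n = %d)\n",
              x$r2, x$rmse, x$bias, x$pct_rmse, x$n))
  invisible(x)
}

#' Random-split permutation ensemble for a PLSR spectra-trait model
#'
#' Repeats `n_iter` times: draw a uniform random calibration/validation
#' split (no stratification), fit a PLS model with `n_components` on the
#' calibration part, and record fit statistics on both parts along with the
#' standardized-coefficient and VIP profiles. The distribution of
#' validation statistics measures model stability; the per-wavelength mean
#' and 5th/95th percentile profiles summarize which wavelengths drive the
#' model.
#'
#' @param X Samples x wavelengths matrix or `spectra_set`.
#' @param y Trait vector.
#' @param n_components PLS components per fit.
#' @param n_iter Number of random splits (default 500).
#' @param cal_fraction Calibration fraction, in (0.5, 0.95).
#' @param seed Optional RNG seed (local).
#' @param scale Autoscale predictors (passed to [fit_pls()]).
#' @return A list of class `ensemble_result`: `iterations` (data frame of
#'   per-iteration cal/val statistics), `summary` (mean and sd per
#'   statistic), `profiles` (data frame: wavelength/predictor, coefficient
#'   and VIP mean, 5th, 95th percentiles), `mean_coefficients_raw`,
#'   `mean_intercept_raw`, `n_components`, `sample_ids`.
#' @export
permutation_ensemble <- function(X, y, n_components, n_iter = 500L,
                                 cal_fraction = 0.8, seed = NULL,
                                 scale = TRUE) {
  sample_ids <- NULL
  predictor_names <- NULL
  if (inherits(X, "spectra_set")) {
    sample_ids <- X$sample_ids
    X <- X$reflectance
  }
  X <- as.matrix(X)
  predictor_names <- colnames(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 samples for a split ensemble")
  if (cal_fraction <= 0.5 || cal_fraction >= 0.95) {
    stop("cal_fraction must be in (0.5, 0.95)")
  }
  n_cal <- round(cal_fraction * n)
  if (n_components >= n_cal) stop("n_components must be < calibration size")

  with_seed(seed, {
    stats_rows <- vector("list", n_iter)
    coefs <- matrix(NA_real_, n_iter, ncol(X))
    vips <- matrix(NA_real_, n_iter, ncol(X))
    raw_coefs <- matrix(NA_real_, n_iter, ncol(X))
    raw_int <- numeric(n_iter)
    for (b in seq_len(n_iter)) {
      cal <- sample.int(n, n_cal)
      val <- setdiff(seq_len(n), cal)
      fit <- suppressWarnings(
        fit_pls(X[cal, , drop = FALSE], y[cal], n_components, scale = scale))
      cs <- fit_stats(y[cal], predict(fit, X[cal, , drop = FALSE]))
      vs <- fit_stats(y[val], predict(fit, X[val, , drop = FALSE]))
      stats_rows[[b]] <- data.frame(
        iteration = b,
        cal_r2 = cs$r2, cal_rmse = cs$rmse, cal_bias = cs$bias,
        cal_pct_rmse = cs$pct_rmse,
        val_r2 = vs$r2, val_rmse = vs$rmse, val_bias = vs$bias,
        val_pct_rmse = vs$pct_rmse)
      coefs[b, ] <- standardized_coefficients(fit)
      vips[b, ] <- as.numeric(vip(fit))
      raw_coefs[b, ] <- fit$coefficients_raw
      raw_int[b] <- fit$intercept_raw
    }
    iterations <- do.call(rbind, stats_rows)
    cols <- setdiff(names(iterations), "iteration")
    summary <- data.frame(
      statistic = cols,
      mean = vapply(iterations[cols], mean, numeric(1)),
      sd = vapply(iterations[cols], stats::sd, numeric(1)),
      row.names = NULL)
    q <- function(m, pr) apply(m, 2, stats::quantile, probs = pr, names = FALSE)
    profiles <- data.frame(
      predictor = predictor_names %||% paste0("x", seq_len(ncol(X))),
      coef_mean = colMeans(coefs), coef_p5 = q(coefs, 0.05),
      coef_p95 = q(coefs, 0.95),
      vip_mean = colMeans(vips), vip_p5 = q(vips, 0.05),
      vip_p95 = q(vips, 0.95),
      stringsAsFactors = FALSE)
    structure(list(iterations = iterations, summary = summary,
                   profiles = profiles,
                   mean_coefficients_raw = colMeans(raw_coefs),
                   mean_intercept_raw = mean(raw_int),
                   n_components = as.integer(n_components),
                   n_iter = as.integer(n_iter),
                   cal_fraction = cal_fraction,
                   sample_ids = sample_ids,
                   predictor_names = predictor_names,
                   r2_definition = "squared Pearson correlation"),
              class = "ensemble_result")
  })
}

#' @export
print.ensemble_result <- function(x, ...) {
  s <- x$summary
  vr <- s[s$statistic == "val_r2", ]
  cat(sprintf("<ensemble_result: %d splits (cal %.0f%%), %d component(s); validation r2 = %.3f +/- %.3f>\n",
              x$n_iter, 100 * x$cal_fraction, x$n_components, vr$mean, vr$sd))
  invisible(x)
}

#' Extract one summary statistic from an ensemble result
#'
#' @param ens An `ensemble_result`.
#' @param statistic Statistic name, e.g. `"val_r2"`, `"cal_rmse"`.
#' @return The ensemble mean of that statistic.
#' @export
ensemble_stat <- function(ens, statistic) {
  s <- ens$summary
  s$mean[s$statistic == statistic]
}

# Leave-one-out residuals at a fixed component count.
loo_residuals <- function(X, y, n_components, scale = TRUE) {
  n <- nrow(X)
  res <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      fit_pls(X[-i, , drop = FALSE], y[-i],
              min(n_components, n - 2L), scale = scale))
    res[i] <- y[i] - predict(fit, X[i, , drop = FALSE])
  }
  res
}

#' Screen samples for outliers before final spectra-trait modeling
#'
#' Union of three screens, each with its own reason code:
#' \describe{
#'   \item{RESIDUAL}{absolute leave-one-out prediction residual beyond
#'     `residual_k` standard deviations of the residual distribution;}
#'   \item{QC_SPECTRAL}{spectrum fails [qc_flags()] (bad white reference,
#'     splice jump, inverted red edge);}
#'   \item{TRAIT_EXTREME}{trait value beyond `iqr_k` interquartile ranges
#'     from the median.}
#' }
#' Callers remove the flagged samples before the final ensemble.
#'
#' @param spectra A `spectra_set` covering 400-2400 nm at 1 nm.
#' @param y Trait values aligned with the spectra.
#' @param n_components Components for the preliminary residual model.
#' @param residual_k Residual threshold in SD units (default 2.5).
#' @param iqr_k Trait-extreme threshold in IQR units (default 3).
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @return Data frame with columns `sample_id`, `reason`, `metric` (one row
#'   per sample-reason pair; zero rows if nothing is flagged).
#' @export
screen_outliers <- function(spectra, y, n_components, residual_k = 2.5,
                            iqr_k = 3, thresholds = qc_thresholds()) {
  stopifnot(inherits(spectra, "spectra_set"))
  y <- as.numeric(y)
  n <- length(spectra$sample_ids)
  if (length(y) != n) stop("y must align with the spectra")
  out <- list()

  qc <- qc_report(spectra, thresholds)
  bad_qc <- which(!qc$pass)
  if (length(bad_qc) > 0L) {
    out$qc <- data.frame(sample_id = qc$sample_id[bad_qc],
                         reason = "QC_SPECTRAL",
                         metric = qc$flags[bad_qc], stringsAsFactors = FALSE)
  }

  res <- loo_residuals(spectra$reflectance, y, n_components)
  s <- stats::sd(res)
  bad_res <- which(abs(res) > residual_k * s)
  if (length(bad_res) > 0L) {
    out$res <- data.frame(sample_id = spectra$sample_ids[bad_res],
                          reason = "RESIDUAL",
                          metric = sprintf("%.3g sd", res[bad_res] / s),
                          stringsAsFactors = FALSE)
  }

  med <- stats::median(y)
  iqr <- stats::IQR(y)
  bad_y <- which(abs(y - med) > iqr_k * iqr)
  if (length(bad_y) > 0L) {
    out$y <- data.frame(sample_id = spectra$sample_ids[bad_y],
                        reason = "TRAIT_EXTREME",
                        metric = sprintf("%.3g IQR", (y[bad_y] - med) / iqr),
                        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(0), reason = character(0),
                      metric = character(0), stringsAsFactors = FALSE))
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' External validation of an ensemble on an independent sample set
#'
#' Applies the ensemble-mean regression coefficients (element-wise mean of
#' the per-iteration coefficient vectors, in original units) to an external
#' dataset that shares no samples with the modeling set, and returns the
#' fit statistics.
#'
#' @param ensemble An `ensemble_result`.
#' @param X_ext External spectra matrix or `spectra_set`.
#' @param y_ext External observed trait values.
#' @param ids_ext Sample ids of the external set (taken from the
#'   `spectra_set` when available); checked for overlap with the ensemble's
#'   modeling ids when both are known.
#' @return A `fit_stats` object.
#' @export
external_validate <- function(ensemble, X_ext, y_ext, ids_ext = NULL) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  if (inherits(X_ext, "spectra_set")) {
    ids_ext <- ids_ext %||% X_ext$sample_ids
    X_ext <- X_ext$reflectance
  }
  X_ext <- as.matrix(X_ext)
  y_ext <- as.numeric(y_ext)
  if (nrow(X_ext) < 2L) stop("external validation needs at least 2 samples")
  if (!is.null(ids_ext) && !is.null(ensemble$sample_ids) &&
      length(intersect(ids_ext, ensemble$sample_ids)) > 0L) {
    stop("external samples overlap the modeling set: ",
         paste(utils::head(intersect(ids_ext, ensemble$sample_ids), 5),
               collapse = ", "))
  }
  if (ncol(X_ext) != length(ensemble$mean_coefficients_raw)) {
    stop("external spectra do not match the model's wavelength range")
  }
  pred <- ensemble$mean_intercept_raw +
    as.numeric(X_ext %*% ensemble$mean_coefficients_raw)
  fit_stats(y_ext, pred)
}

#' Spectral range and component count per fluorescence parameter
#'
#' The per-trait wavelength ranges and component counts used by the final
#' spectra-trait models (600-900 nm with 6-11 components for most
#' parameters; 400-1200 nm for Fs and Fm'; the full 400-2400 nm range with
#' 12 components for ETR and P). Taken as fixed configuration defaults.
#'
#' @return Data frame with columns `trait`, `lo_nm`, `hi_nm`, `ncomp`.
#' @export
chlf_model_config <- function() {
  data.frame(
    trait = c("F0", "Fm", "FvFm", "Fs", "Fm_prime", "F0_prime", "PhiPSII",
              "FvpFmp", "ETR", "qP", "qN", "NPQ", "qL", "P", "D"),
    lo_nm = c(600, 600, 600, 400, 400, 600, 600, 600, 400, 600, 600, 600,
              600, 400, 600),
    hi_nm = c(900, 900, 900, 1200, 1200, 900, 900, 900, 2400, 900, 900, 900,
              900, 2400, 900),
    ncomp = c(8, 7, 8, 4, 8, 7, 10, 7, 12, 11, 7, 6, 8, 12, 7),
    stringsAsFactors = FALSE)
}

#' Predict traits for new spectra from a bundle of trait models
#'
#' Applies each trait's ensemble-mean coefficients to the matching
#' wavelength range of the new spectra. Only traits whose external
#' validation reached `r2 >= r2_threshold` are predicted; the others are
#' omitted with a message. A trait whose wavelength range is missing from
#' the spectra produces a per-trait warning while the rest are still
#' computed.
#'
#' @param bundle Named list (one element per trait) with elements
#'   `ensemble` (an `ensemble_result`), `external` (a `fit_stats`), `lo_nm`,
#'   `hi_nm` - as produced by [run_trait_pipeline()].
#' @param spectra A `spectra_set` covering the needed ranges.
#' @param r2_threshold Minimum external-validation r2 (default 0.55).
#' @return Data frame with `sample_id` and one column per passing trait;
#'   skipped traits and reasons in `attr(, "skipped")`.
#' @export
predict_traits <- function(bundle, spectra, r2_threshold = 0.55) {
  stopifnot(inherits(spectra, "spectra_set"))
  out <- data.frame(sample_id = spectra$sample_ids, stringsAsFactors = FALSE)
  skipped <- character(0)
  for (trait in names(bundle)) {
    entry <- bundle[[trait]]
    r2_ext <- entry$external$r2
    if (is.null(r2_ext) || r2_ext < r2_threshold) {
      skipped[trait] <- sprintf("external r2 %.2f < %.2f",
                                r2_ext %||% NA_real_, r2_threshold)
      message(sprintf("skipping %s: %s", trait, skipped[trait]))
      next
    }
    sub <- tryCatch(subset_range(spectra, entry$lo_nm, entry$hi_nm),
                    error = function(e) e)
    if (inherits(sub, "error") ||
        ncol(sub$reflectance) != length(entry$ensemble$mean_coefficients_raw)) {
      warning(sprintf("%s: spectra lack the %d-%d nm range; trait skipped",
                      trait, entry$lo_nm, entry$hi_nm))
      skipped[trait] <- "wavelength range unavailable"
      next
    }
    out[[trait]] <- entry$ensemble$mean_intercept_raw +
      as.numeric(sub$reflectance %*% entry$ensemble$mean_coefficients_raw)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Run the full spectra-trait analysis chain on a synthetic study
#'
#' The end-to-end pipeline: (1) trim spectra to 400-2400 nm and
#' splice-correct; (2) screen the model set for outliers (spectral QC +
#' per-trait residual/extreme screens on a reference trait) and drop them;
#' (3) hold out an external set (ca. `external_fraction` of the remaining
#' samples, split once by seed); (4) per trait, fit a random-split PLSR
#' ensemble on that trait's wavelength range with its configured component
#' count, then validate externally; (5) predict traits and vegetation
#' indices for the phenotyping spectra (only traits passing the external-r2
#' gate); (6) test treatment effects trait-by-trait with ANOVA + Tukey
#' letters.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param traits Traits to model (default all 15).
#' @param n_iter Ensemble iterations per trait (default 500).
#' @param r2_threshold External-validation gate for prediction (default
#'   0.55).
#' @param external_fraction Fraction held out for external validation.
#' @param seed RNG seed for the external split and ensembles (local).
#' @param alpha Significance level for the treatment tests.
#' @return A list of class `trait_pipeline`: `screen` (outlier report),
#'   `removed_ids`, `external_ids`, `bundle` (per-trait ensembles +
#'   external stats + ranges), `summary` (one row per trait; the
#'   ensemble-summary schema), `predicted` (phenotyping trait table),
#'   `indices` (phenotyping vegetation indices), `tests` (ANOVA/Tukey
#'   tables over predicted traits and indices).
#' @export
run_trait_pipeline <- function(study, traits = chlf_model_config()$trait,
                               n_iter = 500L, r2_threshold = 0.55,
                               external_fraction = 0.2, seed = 1L,
                               alpha = 0.05) {
  stopifnot(inherits(study, "synthetic_study"))
  cfgs <- chlf_model_config()
  cfgs <- cfgs[cfgs$trait %in% traits, , drop = FALSE]

  spectra <- subset_range(study$spectra, 400, 2400)
  pheno <- splice_correct(subset_range(study$pheno_spectra, 400, 2400))
  trait_tab <- study$truth_traits

  # screening runs on uncorrected spectra (splice correction would mask the
  # very jumps the QC screen looks for); residual/extreme screens use a
  # well-coupled reference trait (PhiPSII)
  screen <- screen_outliers(spectra, trait_tab$PhiPSII,
                            n_components = 8L)
  removed <- unique(screen$sample_id)
  keep <- !(spectra$sample_ids %in% removed)
  spectra <- splice_correct(
    spectra_set(spectra$reflectance[keep, , drop = FALSE],
                spectra$wavelengths, spectra$sample_ids[keep],
                study$metadata[keep, , drop = FALSE]))
  trait_tab <- trait_tab[keep, , drop = FALSE]

  with_seed(seed, {
    n <- nrow(spectra$reflectance)
    ext_idx <- sort(sample.int(n, round(external_fraction * n)))
    mod_idx <- setdiff(seq_len(n), ext_idx)
    take <- function(set, idx) {
      spectra_set(set$reflectance[idx, , drop = FALSE], set$wavelengths,
                  set$sample_ids[idx],
                  if (!is.null(set$metadata)) set$metadata[idx, , drop = FALSE])
    }
    bundle <- list()
    summary_rows <- list()
    for (k in seq_len(nrow(cfgs))) {
      trait <- cfgs$trait[k]
      y <- trait_tab[[trait]]
      rng_set <- subset_range(spectra, cfgs$lo_nm[k], cfgs$hi_nm[k])
      Xm <- take(rng_set, mod_idx)
      ens <- permutation_ensemble(Xm, y[mod_idx], cfgs$ncomp[k],
                                  n_iter = n_iter, seed = NULL)
      ext <- external_validate(ens, take(rng_set, ext_idx), y[ext_idx])
      bundle[[trait]] <- list(ensemble = ens, external = ext,
                              lo_nm = cfgs$lo_nm[k], hi_nm = cfgs$hi_nm[k])
      s <- ens$summary
      pick <- function(stat, col) s[[col]][s$statistic == stat]
      summary_rows[[trait]] <- data.frame(
        trait = trait, lo_nm = cfgs$lo_nm[k], hi_nm = cfgs$hi_nm[k],
        ncomp = cfgs$ncomp[k],
        cal_r2_mean = pick("cal_r2", "mean"), cal_r2_sd = pick("cal_r2", "sd"),
        cal_rmse_mean = pick("cal_rmse", "mean"),
        cal_pct_rmse_mean = pick("cal_pct_rmse", "mean"),
        val_r2_mean = pick("val_r2", "mean"), val_r2_sd = pick("val_r2", "sd"),
        val_rmse_mean = pick("val_rmse", "mean"),
        val_pct_rmse_mean = pick("val_pct_rmse", "mean"),
        ext_r2 = ext$r2, ext_rmse = ext$rmse, ext_bias = ext$bias,
        stringsAsFactors = FALSE)
    }
    predicted <- suppressMessages(
      predict_traits(bundle, pheno, r2_threshold = r2_threshold))
    idx_tab <- compute_indices(study$pheno_spectra)
    groups <- study$pheno_metadata$treatment
    tests <- trait_treatment_tests(
      cbind(predicted[setdiff(names(predicted), "sample_id")],
            idx_tab[setdiff(names(idx_tab), "sample_id")]),
      groups, alpha = alpha)
    structure(list(screen = screen, removed_ids = removed,
                   external_ids = spectra$sample_ids[ext_idx],
                   bundle = bundle,
                   summary = do.call(rbind, c(summary_rows,
                                              list(make.row.names = FALSE))),
                   predicted = predicted, indices = idx_tab,
                   tests = tests),
              class = "trait_pipeline")
  })
}

#' @export
print.trait_pipeline <- function(x, ...) {
  cat(sprintf("<trait_pipeline: %d trait model(s), %d sample(s) screened out, %d predicted column(s)>\n",
              length(x$bundle), length(x$removed_ids),
              ncol(x$predicted) - 1L))
  invisible(x)
}
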