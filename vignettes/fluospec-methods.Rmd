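---
title: "Methods: spectra-trait PLSR and hyperspectral phenotyping in fluospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra-trait PLSR and hyperspectral phenotyping in fluospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`fluospec` implements a complete leaf-level analysis chain linking
pulse-amplitude-modulation (PAM) chlorophyll fluorescence to hyperspectral
reflectance:

1. **Fluorescence algebra** (`derive_chlf`): the 15 standard
   quenching-analysis parameters from the five raw yields.
2. **Spectral handling** (`splice_correct`, `resample_to_grid`,
   `average_replicates`, `subset_range`, `qc_flags`): preprocessing and
   quality control of 350-2500 nm reflectance.
3. **Spectra-trait regression** (`fit_pls`, `loo_press`, `vip`,
   `permutation_ensemble`, `external_validate`): from-scratch NIPALS partial
   least squares with ensemble validation and wavelength diagnostics.
4. **Hyperspectral phenotyping** (`permanova`, `pcoa`, `plsda_grid`):
   treatment detection and classification from whole spectral signatures.
5. **Univariate treatment statistics** (`one_way_anova`, `tukey_hsd`).
6. A **synthetic-data generator** (`generate_study`) that emulates the
   coupled spectra/fluorescence/ozone-treatment structure so the whole chain
   is testable end to end without any field data.

# Fluorescence parameters

From dark-adapted yields `F0 < Fm` and light-adapted yields
`F0' <= Fs < Fm' <= Fm`:

- Fv/Fm = (Fm - F0)/Fm, the maximum quantum efficiency of PSII
- PhiPSII = (Fm' - Fs)/Fm', the PSII operating efficiency in the light
- Fv'/Fm' = (Fm' - F0')/Fm'
- ETR = PhiPSII x PPFD x 0.5 x 0.84 (µmol m⁻² s⁻¹); 0.5 is the PSII/PSI
  partitioning of absorbed quanta and 0.84 the leaf absorptance, both kept
  as named constants
- qP = (Fm' - Fs)/(Fm' - F0'), qN = (Fm - Fm')/(Fm - F0'),
  NPQ = (Fm - Fm')/Fm', qL = qP (F0'/Fs)
- P = (Fv'/Fm') qP and D = 1 - Fv'/Fm', the fractions of absorbed light used
  photochemically and dissipated thermally

P equals PhiPSII algebraically ((Fm'-F0')/Fm' x (Fm'-Fs)/(Fm'-F0')
telescopes); the package keeps both because they are reported side by side
in practice, and the test suite asserts the identity to 1e-12 as a
correctness check of the implementation. A reading violating the ordering
constraints (e.g. Fm' > Fm) raises a validation error naming the violated
inequality; the degenerate qP denominator Fm' = F0' is unreachable given
`F0' <= Fs < Fm'`. PPFD defaults to the actinic level 270 µmol m⁻² s⁻¹ when
not supplied per sample.

# PLS regression

`fit_pls` is PLS1 by NIPALS: predictors and response are centered and (by
default) autoscaled; each component takes the weight vector
`w = X'y / ||X'y||`, scores `t = Xw`, loadings `p = X't/t't`,
`q = y't/t't`, then deflates `X <- X - t p'`. Scores of successive
components are mutually orthogonal by construction, and at `A = p` on a
full-rank matrix the coefficients coincide with ordinary least squares (a
property the tests check against a normal-equations solve). The y-deflation
variant is exposed (`deflate_y`) but off by default - for a univariate
response it yields the identical model. Convergence tolerance is 1e-10 with
at most 500 inner iterations per component; for PLS1 the inner loop
converges in one pass.

Autoscaling is the default because the two wavelength diagnostics are
defined on autoscaled data: **standardized coefficients** (invariant under
affine rescaling of any input band) and **VIP**,

VIP_j = sqrt( p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a ),
SSY_a = q_a^2 t_a't_a,

whose squared profile averages to 1 (`sum(VIP^2) = p`). Predictions are
mapped back to original units through stored centering/scaling constants, so
`coefficients_raw` plus `intercept_raw` reproduce the model as a plain
affine predictor.

**Component selection.** `loo_press` computes the leave-one-out predicted
residual sum of squares for each candidate component count (each held-out
refit is done once at the largest count and truncated, which is exact for
NIPALS). `select_ncomp` offers `"min"` (argmin) and the default
`"onesigma"`: the smallest count whose PRESS is within 5% (relative) of the
minimum, the parsimonious guard against overfitting. Ties break to fewer
components. For the 15 fluorescence parameters the package also ships fixed
per-trait ranges and component counts (`chlf_model_config`): 600-900 nm
with 6-11 components for most parameters, 400-1200 nm for Fs and Fm', and
the full 400-2400 nm with 12 components for ETR and P. These are treated as
configuration defaults, not re-derived.

**Ensembles.** `permutation_ensemble` repeats (default) 500 random
calibration/validation splits (80:20, uniform draws without stratification),
refits the model each time, and records R², RMSE, bias and %RMSE (RMSE as a
percentage of the observed range) on both parts, plus the per-split
standardized-coefficient and VIP profiles summarized as mean and 5th/95th
percentiles. R² is the squared Pearson correlation of observed and
predicted, the convention of observed-vs-predicted regression in the
spectra-trait literature. Note the summary SD measures the across-split
spread of a statistic; it does not shrink with more splits - what shrinks is
the run-to-run variability of the summary mean, which is what the test
suite asserts.

**External validation** applies the element-wise mean of the per-split
coefficient vectors (an affine predictor in original units) to a hold-out
set split off once, by seed, before any modeling (default 20%), with a hard
error if any sample id overlaps the modeling set. Traits are only carried
into downstream phenotype analysis when their external R² reaches the gate
(default 0.55).

# Spectral quality control and preprocessing

Three acquisition-error signatures are screened (`qc_flags`), with
configurable thresholds:

- `VIS_ELEVATED`: mean 400-700 nm reflectance above 0.15 (a healthy leaf
  reflects little visible light; a bad white-reference measurement lifts
  the whole visible region).
- `SPLICE_JUMP`: the detector boundaries at 1000/1001 and 1800/1801 nm. The
  step is estimated by a local regression of reflectance on wavelength plus
  a step indicator over 25 bands per side. This estimator is unbiased under
  a locally linear continuum and has noise SD ≈ 0.57 x per-band noise, so
  at the default band noise (0.005) and threshold (0.01) false alarms are
  negligible while a 0.05 step is detected with certainty. A plain
  difference of adjacent bands would alias both the band noise and the
  local continuum slope into the step estimate.
- `REDEDGE_CONCAVE`: an inverted red edge. The mean second difference over
  700-750 nm is estimated as the curvature of a quadratic fit, and the end
  slope as a linear fit over 735-750 nm; the flag requires positive
  curvature together with a negative end slope. Least-squares estimates are
  used instead of raw finite differences because a second difference of
  noisy reflectance has ~sqrt(6) x the band noise, which would make the
  sign test a coin flip on clean spectra.

`splice_correct` removes detector steps by rigid additive shifts, anchoring
the visible/near-infrared segment and shifting SWIR1 then SWIR2 so the
spectrum is continuous at each boundary. It is idempotent, and must run
*after* QC screening - correcting first would erase the very jumps the
screen looks for (the pipeline orders the steps accordingly).
`resample_to_grid` uses linear interpolation (the simplest method
consistent with plain "data interpolation"; never extrapolates) and
`average_replicates` takes per-wavelength arithmetic means, recording the
replicate count. All modeling uses 400-2400 nm; the noisy grid edges below
400 and above 2400 nm are discarded.

`screen_outliers` unions three screens - leave-one-out residuals beyond 2.5
SD, spectra failing QC, and trait values beyond 3 IQR from the median -
mirroring the practice of examining prediction residuals, the spectra of
the offending samples, and the distribution of the reference measurements
before final modeling.

# Phenotyping

`permanova` partitions the total squared Euclidean distance:
`SS_total = (1/n) sum_{i<j} d²`, `SS_within = sum_g (1/n_g) sum_{i<j in g}
d²`, pseudo-F = (SS_among/(g-1))/(SS_within/(n-g)), with an unrestricted
permutation p-value using the +1 correction (never exactly zero; default
10,000 permutations). On univariate data the pseudo-F is exactly the
classical one-way ANOVA F, which the tests exploit as an oracle alongside an
independent implementation.

`pcoa` double-centers the squared distance matrix (Gower) and
eigendecomposes; scores are eigenvectors scaled by sqrt(eigenvalue), so on
Euclidean distances they reproduce centered-data PCA scores up to per-axis
sign.

`plsda_grid` runs one-hot PLS2 (NIPALS, centered data, argmax decoding with
lexicographic tie-break) over all combinations of calibration ratio
{50:50, 70:30, 80:20} and component count, with (default) 500 stratified
random splits per cell; the best cell maximizes mean validation kappa, ties
going to fewer components and then the larger calibration fraction. Splits
are stratified by class - with 8 plants per treatment, unstratified 50:50
splits frequently lose a class entirely. Component counts are capped at
calibration size minus 2 (a 13-component model is not estimable from ~19
calibration spectra); capped-out cells are skipped with a warning.

Two statistical subtleties worth recording:

- **Split-resampling on one fixed small dataset is not an unbiased null.**
  With 24 fixed samples, chance structure (e.g., the association between
  permuted labels and any real clusters in the spectra) is shared between
  calibration and validation halves, so mean validation kappa can sit well
  above zero even when labels were assigned independently of the
  generating process. The package's null checks therefore generate spectra
  with *no class-linked structure* and shuffle labels - under that null the
  grid's mean kappa is ~0 - rather than permuting the labels of strongly
  clustered data once.
- The same mechanism inflates 1-component cells slightly even on
  structure-free data; the grid mean is the stable summary.

Univariate treatment tests are a plain between-subjects one-way ANOVA (each
plant is measured once, so a repeated-measures structure has nothing to
model) with Tukey-Kramer post-hoc comparisons from the studentized range
distribution. The compact letter display assigns one letter per maximal
clique of the non-significance graph (exact by subset enumeration, fine for
a handful of groups).

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised: 102 paired PAM + spectra samples for model building, 8 plants
per ozone treatment (AA ambient, MO moderate, EO elevated) for
phenotyping, elevated ozone shifting mean PhiPSII by -30% and mean qN by
+21% (MO left at the ambient distribution, as is Fv/Fm), and 10% of model
spectra carrying one planted acquisition defect each.

**Yields.** Raw fluorescence yields are never published with an absolute
scale; the scale here is a modeling decision. Dark-adapted Fv/Fm ~
truncated Normal(0.78, 0.04) on (0.5, 0.87) and Fm ~ truncated
Normal(0.45, 0.05) give F0 = Fm (1 - Fv/Fm); the light-adapted latents
qP ~ tN(0.65, 0.05), qN ~ tN(0.35, 0.035) and Fv'/Fm' ~ tN(0.75, 0.05) are
sampled and the quenching formulas inverted
(Fm' = Fm (1-qN)/(1 - qN (1-Fv'/Fm')), F0' = Fm'(1-Fv'/Fm'),
Fs = Fm'(1 - qP Fv'/Fm')), so every ordering constraint holds by
construction and all 15 derived parameters are internally consistent.
Treatment effects multiply the qP and qN latents, which scales the mean of
PhiPSII = qP x Fv'/Fm' (independence) by exactly the configured factor. The
chosen between-plant coefficients of variation (5-10%) are typical of
uniform, well-watered seedlings measured under controlled actinic light.

**Spectra.** Each spectrum is a smooth leaf-like continuum - visible floor
0.07, green bump at 550 nm, logistic red edge (center 715 nm, scale 7 nm)
to a near-infrared plateau ~0.45, and short-wave-infrared water (1450,
1930 nm) and protein (1700 nm) shoulders - minus Gaussian absorption
features whose depths are affine in latent trait values: 685 nm follows
PhiPSII, 650 nm follows qN, 710 nm follows Fv/Fm, the plateau height
follows Fm, and the water/protein depths follow a latent partially coupled
to PhiPSII (hence to ETR and P, which use the full range). Depth mappings
receive Gaussian noise of SD `trait_noise_sd` x trait range (default 5%),
per-band i.i.d. noise (SD 0.005) is added, and reflectance is clipped to
[0, 1]. Feature centers sit where chlorophyll and water/protein absorption
is known to matter (650, 680-690, 700-750, 1400, 1700, 1900-1950 nm), so
VIP profiles peak in the right neighborhoods.

**Planted defects** are exactly the three QC signatures: +0.15 over
400-700 nm, a +0.05 step at >= 1001 nm, and a vertical inversion of the
700-750 nm red edge; their magnitudes sit far above the QC noise floors so
a correct screen separates them perfectly.

**What the generator does not emulate** - and hence what passing tests do
not show about real data: no radiative-transfer physics (no PROSPECT-style
leaf model), no radiance/white-reference division, no instrument drift or
wavelength miscalibration, no plot-level spatial correlation, no
measurement-day effects, Gaussian rather than heavy-tailed noise, and
absorption features that are cleaner and more orthogonal than real leaf
biochemistry. Validation R² values on synthetic data (0.8-0.9 for the
well-coupled parameters) are accordingly an upper bound on what field data
yields; the pipeline's claims verified here are correctness and calibration
of the machinery, not field-level predictive skill.

# Problem sizes and numerical choices

The test suite and the analysis scripts run at desk scale, chosen so the
full suite completes in minutes on one CPU: ensembles of 500 splits where
the ensemble itself is under test, 60-100 splits inside the 15-trait
end-to-end pipeline; 200-permutation PERMANOVA inside the 1000-run type-I
simulation (10,000 permutations for single analyses); PLS-DA grids with
100-500 iterations per cell. NIPALS tolerance 1e-10, max 500 iterations;
rank collapse during fitting truncates the component count with a warning;
zero-variance predictors get unit scale and a zero coefficient with a
warning; eigenvalues below 1e-9 x the spectral radius are treated as zero
in PCoA; degenerate Cohen's kappa (chance agreement 1) is defined as 0
with a warning.

# Known limitations

- PLS1/PLS2 by NIPALS only; no SIMPLS, kernel, sparse or penalized
  variants.
- The ensemble's external-validation predictor is the mean coefficient
  vector; a single refit on all modeling data is a reasonable alternative
  the API exposes via the stored per-iteration coefficients.
- The compact letter display enumerates subsets and is limited to 15
  groups.
- `permanova` is one-way with unrestricted permutations; no nested or
  restricted designs, dispersion tests, or non-Euclidean dissimilarities.
- The QC red-edge test is tuned to 1-nm grids over 400-2400 nm; other
  grids need `resample_to_grid` first.
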