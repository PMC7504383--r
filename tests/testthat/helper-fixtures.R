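# Shared fixtures, built in code.

# Random valid PAM readings: latents are sampled and the quenching formulas
# inverted, so ordering constraints hold by construction (independent of the
# package's own generator parameters).
random_readings <- function(n, seed = NULL) {
  build <- function() {
    FvFm <- runif(n, 0.55, 0.86)
    Fm <- runif(n, 0.25, 0.7)
    FvpFmp <- runif(n, 0.45, 0.9)
    qP <- runif(n, 0.1, 0.95)
    qN <- runif(n, 0.05, 0.8)
    Fmp <- Fm * (1 - qN) / (1 - qN * (1 - FvpFmp))
    data.frame(F0 = Fm * (1 - FvFm), Fm = Fm,
               Fs = Fmp * (1 - qP * FvpFmp),
               Fm_prime = Fmp, F0_prime = Fmp * (1 - FvpFmp),
               ppfd = 270)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# A smooth analytic spectrum on a 1-nm grid (logistic red edge over a
# gentle slope), for splice/resampling tests.
smooth_spectrum <- function(lo = 350, hi = 2500, id = "smooth") {
  wl <- lo:hi
  r <- 0.1 + 0.3 * plogis((wl - 715) / 7) - 0.00002 * (wl - 1200)
  spectrum(wl, r, id)
}

# Add a step of `size` to all wavelengths > s.
add_step <- function(s_obj, s, size) {
  r <- s_obj$reflectance
  r[s_obj$wavelengths > s] <- r[s_obj$wavelengths > s] + size
  spectrum(s_obj$wavelengths, r, s_obj$sample_id)
}
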