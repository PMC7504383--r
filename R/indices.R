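#' Narrow-band vegetation indices
#'
#' Computes the three reflectance indices used alongside the spectra-trait
#' models, reading single 1-nm band values `R_x`:
#' \describe{
#'   \item{PRI}{(R531 - R570)/(R531 + R570), photochemical reflectance index
#'     (xanthophyll-cycle / photochemistry proxy); sPRI = (PRI + 1)/2 rescales
#'     it to avoid negative values.}
#'   \item{PSRI}{(R678 - R500)/R750, plant senescence reflectance index;
#'     sPSRI = (PSRI + 1)/2.}
#'   \item{CI}{(R750 - R705)/(R750 + R705), red-edge chlorophyll index.}
#' }
#'
#' @param x A `spectrum` or `spectra_set` covering 500-750 nm on a 1-nm grid.
#' @return For a `spectrum`, a one-row data frame with columns `pri`, `spri`,
#'   `psri`, `spsri`, `ci`; for a `spectra_set`, one row per sample with a
#'   leading `sample_id` column.
#' @export
compute_indices <- function(x) {
  if (inherits(x, "spectrum")) {
    x <- spectra_set(matrix(x$reflectance, nrow = 1), x$wavelengths,
                     x$sample_id)
    single <- TRUE
  } else {
    single <- FALSE
  }
  stopifnot(inherits(x, "spectra_set"))
  wl <- x$wavelengths
  band <- function(w) x$reflectance[, wl_index(wl, w)]
  r500 <- band(500); r531 <- band(531); r570 <- band(570)
  r678 <- band(678); r705 <- band(705); r750 <- band(750)
  if (any(r531 + r570 == 0)) stop("zero denominator in PRI (R531 + R570 = 0)")
  if (any(r750 == 0)) stop("zero denominator in PSRI (R750 = 0)")
  if (any(r750 + r705 == 0)) stop("zero denominator in CI (R750 + R705 = 0)")
  pri <- (r531 - r570) / (r531 + r570)
  psri <- (r678 - r500) / r750
  out <- data.frame(sample_id = x$sample_ids,
                    pri = pri, spri = (pri + 1) / 2,
                    psri = psri, spsri = (psri + 1) / 2,
                    ci = (r750 - r705) / (r750 + r705),
                    stringsAsFactors = FALSE)
  if (single) out$sample_id <- NULL
  out
}
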