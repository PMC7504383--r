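#' Constants used in the electron transport rate calculation
#'
#' `ETR_PARTITION` (0.5) is the assumed partitioning of absorbed quanta between
#' photosystem II and photosystem I; `ETR_ABSORPTANCE` (0.84) is the absorption
#' coefficient of an average leaf. ETR = PhiPSII x PPFD x 0.5 x 0.84.
#'
#' @name etr-constants
#' @export
ETR_PARTITION <- 0.5

#' @rdname etr-constants
#' @export
ETR_ABSORPTANCE <- 0.84

#' Validate a PAM fluorescence reading
#'
#' Checks the physical ordering constraints on the five raw fluorescence
#' yields of a saturating-pulse quenching protocol: all yields positive,
#' `F0 < Fm` (dark-adapted), `F0_prime <= Fs < Fm_prime <= Fm`
#' (light-adapted), and `ppfd >= 0`.
#'
#' @param reading A list or one-row data frame with numeric elements `F0`,
#'   `Fm`, `Fs`, `Fm_prime`, `F0_prime` and optionally `ppfd`.
#' @return A character vector of violated constraints; empty if the reading
#'   is valid.
#' @export
validate_reading <- function(reading) {
  need <- c("F0", "Fm", "Fs", "Fm_prime", "F0_prime")
  missing <- setdiff(need, names(reading))
  if (length(missing) > 0L) {
    return(paste0("missing field: ", missing))
  }
  v <- character(0)
  for (f in need) {
    x <- reading[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      v <- c(v, paste0(f, " <= 0 or non-finite"))
    }
  }
  if (length(v) > 0L) return(v)
  if (reading$F0 >= reading$Fm) v <- c(v, "F0 >= Fm")
  if (reading$F0_prime > reading$Fs) v <- c(v, "F0_prime > Fs")
  if (reading$Fs >= reading$Fm_prime) v <- c(v, "Fs >= Fm_prime")
  if (reading$Fm_prime > reading$Fm) v <- c(v, "Fm_prime > Fm")
  ppfd <- reading$ppfd
  if (!is.null(ppfd) && (!is.finite(ppfd) || ppfd < 0)) v <- c(v, "ppfd < 0")
  v
}

#' Derive chlorophyll fluorescence parameters from raw PAM yields
#'
#' Computes the 15 standard quenching-analysis parameters from the five raw
#' fluorescence yields of a dark/light-adapted saturating-pulse protocol:
#' \describe{
#'   \item{FvFm}{(Fm - F0)/Fm, maximum quantum efficiency of PSII photochemistry}
#'   \item{PhiPSII}{(Fm' - Fs)/Fm', PSII operating efficiency in the light}
#'   \item{FvpFmp}{(Fm' - F0')/Fm', maximum PSII efficiency in the light}
#'   \item{ETR}{PhiPSII x PPFD x 0.5 x 0.84, electron transport rate
#'     (umol m-2 s-1)}
#'   \item{qP}{(Fm' - Fs)/(Fm' - F0'), photochemical quenching}
#'   \item{qN}{(Fm - Fm')/(Fm - F0'), non-photochemical quenching}
#'   \item{NPQ}{(Fm - Fm')/Fm', non-photochemical quenching (Stern-Volmer form)}
#'   \item{qL}{qP x (F0'/Fs), fraction of open PSII centers}
#'   \item{P}{(Fv'/Fm') x qP, fraction of absorbed light used in PSII
#'     photochemistry (algebraically identical to PhiPSII)}
#'   \item{D}{1 - Fv'/Fm', fraction of absorbed light dissipated thermally}
#' }
#' The five raw yields are passed through, giving 15 columns in total.
#'
#' @param pam A data frame with columns `F0`, `Fm`, `Fs`, `Fm_prime`,
#'   `F0_prime` and optionally `ppfd`, one row per sample; or a single
#'   reading as a named list.
#' @param ppfd Default photosynthetic photon flux density (umol m-2 s-1) used
#'   for rows lacking a `ppfd` value; defaults to the actinic level 270.
#' @return A data frame with the 15 parameter columns (plus any `sample_id`
#'   column of the input, passed through).
#' @export
derive_chlf <- function(pam, ppfd = 270) {
  if (!is.data.frame(pam)) pam <- as.data.frame(pam[!vapply(pam, is.null, TRUE)])
  n <- nrow(pam)
  if (n == 0L) stop("no readings supplied")
  if (is.null(pam$ppfd)) pam$ppfd <- ppfd
  pam$ppfd[is.na(pam$ppfd)] <- ppfd
  for (i in seq_len(n)) {
    v <- validate_reading(as.list(pam[i, , drop = FALSE]))
    if (length(v) > 0L) {
      stop(sprintf("invalid PAM reading in row %d: %s", i,
                   paste(v, collapse = "; ")))
    }
  }
  F0 <- pam$F0; Fm <- pam$Fm; Fs <- pam$Fs
  Fmp <- pam$Fm_prime; F0p <- pam$F0_prime
  out <- data.frame(
    F0 = F0, Fm = Fm, Fs = Fs, Fm_prime = Fmp, F0_prime = F0p,
    FvFm = (Fm - F0) / Fm,
    PhiPSII = (Fmp - Fs) / Fmp,
    FvpFmp = (Fmp - F0p) / Fmp,
    ETR = (Fmp - Fs) / Fmp * pam$ppfd * ETR_PARTITION * ETR_ABSORPTANCE,
    qP = (Fmp - Fs) / (Fmp - F0p),
    qN = (Fm - Fmp) / (Fm - F0p),
    NPQ = (Fm - Fmp) / Fmp,
    qL = (Fmp - Fs) / (Fmp - F0p) * (F0p / Fs),
    stringsAsFactors = FALSE
  )
  out$P <- out$FvpFmp * out$qP
  out$D <- 1 - out$FvpFmp
  if (!is.null(pam$sample_id)) out <- cbind(sample_id = pam$sample_id, out)
  out
}

#' Names of the 15 chlorophyll fluorescence parameters
#' @return Character vector in canonical order.
#' @export
chlf_trait_names <- function() {
  c("F0", "Fm", "FvFm", "Fs", "Fm_prime", "F0_prime", "PhiPSII", "FvpFmp",
    "ETR", "qP", "qN", "NPQ", "qL", "P", "D")
}

#' Read or write PAM readings as CSV
#'
#' Plain CSV with columns `sample_id, F0, Fm, Fs, Fm_prime, F0_prime, ppfd`.
#'
#' @param path File path.
#' @param pam Data frame of readings.
#' @return `read_pam_csv` returns the data frame; `write_pam_csv` returns
#'   `path` invisibly.
#' @export
read_pam_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_pam_csv
#' @export
write_pam_csv <- function(pam, path) {
  utils::write.csv(pam, path, row.names = FALSE)
  invisible(path)
}
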