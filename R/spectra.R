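#' Construct a single reflectance spectrum
#'
#' @param wavelengths Strictly increasing integer wavelengths (nm) within
#'   350-2500.
#' @param reflectance Numeric vector of the same length, finite.
#' @param sample_id Sample identifier.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, reflectance, sample_id = "s1") {
  wavelengths <- as.integer(round(wavelengths))
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance lengths differ")
  }
  if (any(diff(wavelengths) <= 0L)) stop("wavelengths must be strictly increasing")
  if (min(wavelengths) < 350L || max(wavelengths) > 2500L) {
    stop("wavelengths must lie within 350-2500 nm")
  }
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  structure(list(wavelengths = wavelengths,
                 reflectance = as.numeric(reflectance),
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

#' Construct a set of spectra on a common wavelength grid
#'
#' @param reflectance Samples x wavelengths numeric matrix.
#' @param wavelengths Integer wavelengths (nm), one per column.
#' @param sample_ids Sample identifiers (unique unless `allow_replicates`).
#' @param metadata Optional data frame with a `sample_id` column (treatment,
#'   plot, plant, date, ...), matched to `sample_ids` by position or id.
#' @param allow_replicates Allow duplicated sample ids (pre-averaging input).
#' @return An object of class `spectra_set` with elements `reflectance`,
#'   `wavelengths`, `sample_ids`, `metadata`.
#' @export
spectra_set <- function(reflectance, wavelengths, sample_ids = NULL,
                        metadata = NULL, allow_replicates = FALSE) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.integer(round(wavelengths))
  if (ncol(reflectance) != length(wavelengths)) {
    stop("number of columns must equal number of wavelengths")
  }
  if (any(diff(wavelengths) <= 0L)) stop("wavelengths must be strictly increasing")
  if (min(wavelengths) < 350L || max(wavelengths) > 2500L) {
    stop("wavelengths must lie within 350-2500 nm")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(reflectance) %||% paste0("s", seq_len(nrow(reflectance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) stop("one sample_id per row required")
  if (!allow_replicates && anyDuplicated(sample_ids)) {
    stop("duplicated sample_id; use allow_replicates = TRUE for replicate stacks")
  }
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  rownames(reflectance) <- NULL
  colnames(reflectance) <- paste0("w", wavelengths)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) stop("metadata needs a sample_id column")
  }
  structure(list(reflectance = reflectance, wavelengths = wavelengths,
                 sample_ids = sample_ids, metadata = metadata),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set: %d spectra, %d-%d nm (%d bands)>\n",
              nrow(x$reflectance), min(x$wavelengths), max(x$wavelengths),
              length(x$wavelengths)))
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s: %d-%d nm (%d bands)>\n", x$sample_id,
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)))
  invisible(x)
}

# Extract one row of a set as a `spectrum`.
#' Extract a single spectrum from a set
#' @param set A `spectra_set`.
#' @param i Row index or sample id.
#' @return A `spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.character(i)) i <- match(i, set$sample_ids)
  if (is.na(i) || i < 1L || i > nrow(set$reflectance)) stop("sample not found")
  spectrum(set$wavelengths, set$reflectance[i, ], set$sample_ids[i])
}

wl_index <- function(wavelengths, w, what = "wavelength") {
  i <- match(as.integer(w), wavelengths)
  if (anyNA(i)) {
    stop(sprintf("%s %s nm not present in grid", what,
                 paste(w[is.na(i)], collapse = ", ")))
  }
  i
}

#' Subset a spectra set (or spectrum) to an inclusive wavelength range
#'
#' @param x A `spectra_set` or `spectrum`.
#' @param lo_nm,hi_nm Inclusive range bounds (nm).
#' @return The same class of object restricted to `[lo_nm, hi_nm]`; metadata
#'   preserved.
#' @export
subset_range <- function(x, lo_nm, hi_nm) {
  if (lo_nm > hi_nm) stop("lo_nm > hi_nm")
  if (inherits(x, "spectrum")) {
    keep <- x$wavelengths >= lo_nm & x$wavelengths <= hi_nm
    if (!any(keep)) stop("requested range contains no measured wavelengths")
    return(spectrum(x$wavelengths[keep], x$reflectance[keep], x$sample_id))
  }
  stopifnot(inherits(x, "spectra_set"))
  keep <- x$wavelengths >= lo_nm & x$wavelengths <= hi_nm
  if (!any(keep)) stop("requested range contains no measured wavelengths")
  spectra_set(x$reflectance[, keep, drop = FALSE], x$wavelengths[keep],
              x$sample_ids, x$metadata, allow_replicates = TRUE)
}

#' Resample a spectrum to a 1-nm grid by linear interpolation
#'
#' @param s A `spectrum`.
#' @param lo_nm,hi_nm Inclusive target range; must lie within the measured
#'   range (no extrapolation).
#' @return A `spectrum` on the integer grid `lo_nm:hi_nm`.
#' @export
resample_to_grid <- function(s, lo_nm, hi_nm) {
  stopifnot(inherits(s, "spectrum"))
  if (lo_nm > hi_nm) stop("lo_nm > hi_nm")
  if (lo_nm < min(s$wavelengths) || hi_nm > max(s$wavelengths)) {
    stop("requested grid extends beyond the measured range (extrapolation refused)")
  }
  grid <- lo_nm:hi_nm
  r <- stats::approx(s$wavelengths, s$reflectance, xout = grid,
                     method = "linear", ties = "ordered")$y
  spectrum(grid, r, s$sample_id)
}

#' Average replicate spectra per sample
#'
#' Replicate rows sharing a `sample_id` (e.g., four leaf areas per sample)
#' are combined into one per-wavelength arithmetic mean spectrum. The number
#' of replicates is recorded in the output metadata (`n_replicates`).
#'
#' @param x A `spectra_set` built with `allow_replicates = TRUE` (or any
#'   spectra set; single replicates pass through unchanged).
#' @return A `spectra_set` with one row per unique sample id, in first-seen
#'   order.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  ids <- unique(x$sample_ids)
  grp <- match(x$sample_ids, ids)
  counts <- tabulate(grp, nbins = length(ids))
  avg <- rowsum(x$reflectance, grp, reorder = TRUE) / counts
  meta <- data.frame(sample_id = ids, n_replicates = counts,
                     stringsAsFactors = FALSE)
  if (!is.null(x$metadata)) {
    extra <- x$metadata[!duplicated(x$metadata$sample_id), , drop = FALSE]
    meta <- merge(meta, extra, by = "sample_id", all.x = TRUE, sort = FALSE)
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  }
  spectra_set(avg, x$wavelengths, ids, meta)
}

#' Correct detector splice jumps by rigid segment shifts
#'
#' Field spectroradiometers stitch three detectors with boundaries at
#' 1000/1001 and 1800/1801 nm; misalignment shows up as step discontinuities
#' at those positions. The visible/near-infrared segment is taken as the
#' anchor and each subsequent segment is shifted rigidly (an additive offset)
#' so the spectrum is continuous across each splice.
#'
#' @param x A `spectra_set` or `spectrum` on a 1-nm grid around the splices.
#' @param splices Last wavelength (nm) of each detector segment; the step is
#'   removed between `s` and `s + 1`.
#' @return The corrected object. Splices wholly outside the measured range
#'   are ignored; a grid that straddles a splice but lacks its immediate
#'   neighbours is an error.
#' @export
splice_correct <- function(x, splices = c(1000L, 1800L)) {
  single <- inherits(x, "spectrum")
  set <- if (single) {
    spectra_set(matrix(x$reflectance, nrow = 1), x$wavelengths, x$sample_id)
  } else x
  stopifnot(inherits(set, "spectra_set"))
  wl <- set$wavelengths
  r <- set$reflectance
  for (s in sort(as.integer(splices))) {
    if (min(wl) > s || max(wl) <= s) next  # splice outside measured range
    i0 <- match(s, wl); i1 <- match(s + 1L, wl)
    if (is.na(i0) || is.na(i1)) {
      stop(sprintf("grid straddles the %d/%d nm splice but misses its neighbours",
                   s, s + 1L))
    }
    offset <- r[, i1] - r[, i0]
    right <- wl > s
    r[, right] <- r[, right] - offset
  }
  out <- spectra_set(r, wl, set$sample_ids, set$metadata, allow_replicates = TRUE)
  if (single) get_spectrum(out, 1L) else out
}

#' Default thresholds for spectral quality control
#'
#' @param vis_mean Mean 400-700 nm reflectance above which a spectrum is
#'   flagged `VIS_ELEVATED` (healthy leaves reflect little visible light).
#' @param jump Absolute step (reflectance units) across a detector splice
#'   above which `SPLICE_JUMP` is flagged.
#' @param jump_window Number of bands used on each side of a splice by the
#'   local slope-plus-step regression that estimates the jump; widening it
#'   makes the step estimate robust to per-band noise.
#' @param slope_window Wavelength window over which the red-edge end slope is
#'   estimated by a linear fit.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(vis_mean = 0.15, jump = 0.01, jump_window = 25L,
                          slope_window = c(735L, 750L)) {
  list(vis_mean = vis_mean, jump = jump, jump_window = as.integer(jump_window),
       slope_window = as.integer(slope_window))
}

# Robust step estimate across the splice between s and s+1 nm: a local
# regression of reflectance on wavelength plus a step indicator over
# `window` points on each side. The step coefficient is unbiased under a
# locally linear continuum (a plain window-mean difference picks up the
# local slope) and averages per-band noise down.
splice_step <- function(wl, r, s, window) {
  sel <- wl >= (s - window + 1L) & wl <= (s + window)
  if (sum(sel & wl <= s) < 2L || sum(sel & wl > s) < 2L) return(NA_real_)
  x <- wl[sel] - (s + 0.5)
  z <- as.numeric(wl[sel] > s)
  stats::lm.fit(cbind(1, x, z), r[sel])$coefficients[3]
}

#' Quality-control flags for a reflectance spectrum
#'
#' Screens for the three acquisition-error signatures seen in leaf-clip
#' spectroscopy: elevated visible reflectance (bad white reference),
#' splice jumps at the detector boundaries, and an inverted (concave)
#' red-edge shape. The red-edge test uses least-squares estimates of the
#' mean second difference (quadratic fit over 700-750 nm) and the end slope
#' (linear fit over `slope_window`), which keeps both sign tests stable under
#' per-band noise; the spectrum is flagged `REDEDGE_CONCAVE` when the mean
#' curvature is positive while the end slope is negative.
#'
#' @param s A `spectrum` on a 1-nm grid covering 400-2400 nm.
#' @param thresholds See [qc_thresholds()].
#' @return A list of class `qc_report` with `sample_id`, `flags` (subset of
#'   `VIS_ELEVATED`, `SPLICE_JUMP`, `REDEDGE_CONCAVE`), `metrics`, and `pass`.
#' @export
qc_flags <- function(s, thresholds = qc_thresholds()) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelengths
  if (min(wl) > 400L || max(wl) < 2400L || any(diff(wl) != 1L)) {
    stop("qc_flags needs a 1-nm grid covering 400-2400 nm")
  }
  r <- s$reflectance
  flags <- character(0)

  vis <- mean(r[wl >= 400L & wl <= 700L])
  if (vis > thresholds$vis_mean) flags <- c(flags, "VIS_ELEVATED")

  j1 <- splice_step(wl, r, 1000L, thresholds$jump_window)
  j2 <- splice_step(wl, r, 1800L, thresholds$jump_window)
  if (max(abs(c(j1, j2)), na.rm = TRUE) > thresholds$jump) {
    flags <- c(flags, "SPLICE_JUMP")
  }

  re <- wl >= 700L & wl <= 750L
  x <- wl[re] - 725
  fit <- stats::lm.fit(cbind(1, x, x^2), r[re])
  curvature <- 2 * fit$coefficients[3]  # mean second difference per nm^2
  sw <- thresholds$slope_window
  es <- wl >= sw[1] & wl <= sw[2]
  xs <- wl[es] - mean(wl[es])
  end_slope <- stats::lm.fit(cbind(1, xs), r[es])$coefficients[2]
  if (curvature > 0 && end_slope < 0) flags <- c(flags, "REDEDGE_CONCAVE")

  structure(list(sample_id = s$sample_id, flags = flags,
                 metrics = list(vis_mean = vis, jump_1000 = j1, jump_1800 = j2,
                                rededge_curvature = unname(curvature),
                                rededge_end_slope = unname(end_slope)),
                 pass = length(flags) == 0L),
            class = "qc_report")
}

#' Quality-control report for every spectrum in a set
#'
#' @param set A `spectra_set` on a 1-nm grid covering 400-2400 nm.
#' @param thresholds See [qc_thresholds()].
#' @return A data frame with one row per sample: `sample_id`, `pass`,
#'   `flags` (comma-separated), and the backing metrics.
#' @export
qc_report <- function(set, thresholds = qc_thresholds()) {
  stopifnot(inherits(set, "spectra_set"))
  rows <- lapply(seq_along(set$sample_ids), function(i) {
    q <- qc_flags(get_spectrum(set, i), thresholds)
    data.frame(sample_id = q$sample_id, pass = q$pass,
               flags = paste(q$flags, collapse = ","),
               vis_mean = q$metrics$vis_mean,
               jump_1000 = q$metrics$jump_1000,
               jump_1800 = q$metrics$jump_1800,
               rededge_curvature = q$metrics$rededge_curvature,
               rededge_end_slope = q$metrics$rededge_end_slope,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read or write a wide-format spectra CSV
#'
#' Wide format: header `sample_id,w350,...,w2500`, one row per spectrum.
#' Lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @param set A `spectra_set`.
#' @param metadata Optional metadata data frame written alongside is the
#'   caller's concern; only reflectance is stored here.
#' @return `read_spectra_csv` returns a `spectra_set`; `write_spectra_csv`
#'   returns `path` invisibly.
#' @export
read_spectra_csv <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  wl <- as.integer(sub("^w", "", wcols))
  ord <- order(wl)
  spectra_set(as.matrix(df[, wcols[ord], drop = FALSE]), wl[ord],
              df$sample_id, metadata, allow_replicates = TRUE)
}

#' @rdname read_spectra_csv
#' @param comment Optional comment line (e.g., the generating seed) written
#'   as a leading `#` line.
#' @export
write_spectra_csv <- function(set, path, comment = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  df <- data.frame(sample_id = set$sample_ids, set$reflectance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
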