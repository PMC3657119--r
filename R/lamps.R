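LAMP_TYPES <- c("LPS", "HPS", "LED", "MH", "custom")

#' Lamp emission spectrum
#'
#' @param grid Strictly increasing wavelengths (nm).
#' @param irradiance Relative spectral irradiance, non-negative, at least one
#'   strictly positive value.
#' @param lamp_type One of `"LPS"`, `"HPS"`, `"LED"`, `"MH"`, `"custom"`.
#' @return A `lamp_spectrum` object.
#' @export
lamp_spectrum <- function(grid, irradiance, lamp_type = "custom") {
  lamp_type <- match.arg(lamp_type, LAMP_TYPES)
  if (length(grid) != length(irradiance)) {
    stop("`grid` and `irradiance` must have the same length", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    stop("irradiance must be finite and non-negative", call. = FALSE)
  }
  if (all(irradiance == 0)) {
    stop("spectrum must contain at least one positive irradiance value",
         call. = FALSE)
  }
  structure(list(lamp_type = lamp_type, wavelength = grid,
                 irradiance = irradiance),
            class = "lamp_spectrum")
}

#' @export
print.lamp_spectrum <- function(x, ...) {
  cat(sprintf("<lamp_spectrum> %s: %d points, %.1f-%.1f nm, peak %.4g\n",
              x$lamp_type, length(x$wavelength), min(x$wavelength),
              max(x$wavelength), max(x$irradiance)))
  invisible(x)
}

#' Read a spectrometer lamp spectrum from a two-column text file
#'
#' Parses a two-column (wavelength nm, relative irradiance) text or CSV file
#' as produced by a field spectrometer. Lines starting with `#` are comments.
#' The spectrum is validated (strictly increasing wavelengths, non-negative
#' irradiance, at least 10 points; violations raise a format error naming the
#' offending data row) and resampled onto the package wavelength grid by
#' linear interpolation, with zero irradiance outside the file's wavelength
#' support.
#'
#' @param path File path; columns separated by comma and/or whitespace.
#' @param lamp_type Lamp technology label, see [lamp_spectrum()].
#' @param grid Target wavelength grid (nm).
#' @return A `lamp_spectrum` on `grid`.
#' @export
read_lamp_spectrum <- function(path, lamp_type = "custom",
                               grid = wavelength_grid()) {
  raw <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           col.names = c("wavelength", "irradiance"),
                           colClasses = "character", strip.white = TRUE)
  # tolerate comma-separated files by splitting a single combined column
  if (any(grepl(",", raw$wavelength, fixed = TRUE))) {
    parts <- strsplit(raw$wavelength, ",", fixed = TRUE)
    raw <- data.frame(wavelength = vapply(parts, `[`, character(1), 1),
                      irradiance = vapply(parts, `[`, character(1), 2))
  }
  w <- suppressWarnings(as.numeric(raw$wavelength))
  irr <- suppressWarnings(as.numeric(raw$irradiance))
  if (any(is.na(w)) || any(is.na(irr))) {
    stop("non-numeric value at data row ",
         which(is.na(w) | is.na(irr))[1], " of ", path, call. = FALSE)
  }
  if (length(w) < 10) {
    stop("spectrum file has fewer than 10 points: ", path, call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    stop("non-monotone wavelengths at data row ",
         which(diff(w) <= 0)[1] + 1L, " of ", path, call. = FALSE)
  }
  if (any(irr < 0)) {
    stop("negative irradiance at data row ", which(irr < 0)[1], " of ", path,
         call. = FALSE)
  }
  res <- stats::approx(w, irr, xout = grid, method = "linear",
                       yleft = 0, yright = 0, ties = "ordered")$y
  lamp_spectrum(grid, res, lamp_type)
}

#' Region over which a lamp emits light
#'
#' Determines the lamp's emission range: after baseline correction (the dark
#' offset, taken as the 1st percentile of irradiance, is subtracted and the
#' result floored at zero), the emission region is where corrected irradiance
#' is at least `rel_threshold` times the corrected peak. Crossing positions
#' are refined by linear interpolation; intervals separated by less than
#' `gap_merge` nm are merged. The `span` (first interval start to last
#' interval end) is the single contiguous range used downstream by default.
#'
#' @param spectrum A [lamp_spectrum].
#' @param rel_threshold Fraction of the corrected peak in (0, 1); default 0.01.
#' @param gap_merge Merge intervals closer than this many nm; default 5.
#' @return An `emission_range` object: list with `intervals` (tibble `lo`,
#'   `hi`), `span` (length-2 numeric), `lamp_type`, `rel_threshold`,
#'   `gap_merge`.
#' @export
emission_range <- function(spectrum, rel_threshold = 0.01, gap_merge = 5) {
  stopifnot(inherits(spectrum, "lamp_spectrum"))
  if (!is.numeric(rel_threshold) || rel_threshold <= 0 || rel_threshold >= 1) {
    stop("`rel_threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  w <- spectrum$wavelength
  irr <- spectrum$irradiance
  corrected <- pmax(irr - stats::quantile(irr, 0.01, names = FALSE), 0)
  peak <- max(corrected)
  if (peak <= 0) {
    stop("degenerate spectrum: no emission left after baseline correction",
         call. = FALSE)
  }
  thr <- rel_threshold * peak
  above <- corrected >= thr

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lo <- hi <- numeric(0)
  for (r in which(runs$values)) {
    i1 <- starts[r]; i2 <- ends[r]
    lo_r <- if (i1 == 1L) w[1] else
      interp_crossing(w[i1 - 1L], w[i1], corrected[i1 - 1L], corrected[i1], thr)
    hi_r <- if (i2 == length(w)) w[length(w)] else
      interp_crossing(w[i2], w[i2 + 1L], corrected[i2], corrected[i2 + 1L], thr)
    lo <- c(lo, lo_r); hi <- c(hi, hi_r)
  }

  # merge intervals separated by less than gap_merge nm
  if (length(lo) > 1) {
    keep_lo <- lo[1]; keep_hi <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] - keep_hi[length(keep_hi)] < gap_merge) {
        keep_hi[length(keep_hi)] <- hi[i]
      } else {
        keep_lo <- c(keep_lo, lo[i]); keep_hi <- c(keep_hi, hi[i])
      }
    }
    lo <- keep_lo; hi <- keep_hi
  }

  structure(list(
    intervals = tibble::tibble(lo = lo, hi = hi),
    span = c(lo[1], hi[length(hi)]),
    lamp_type = spectrum$lamp_type,
    rel_threshold = rel_threshold,
    gap_merge = gap_merge
  ), class = "emission_range")
}

#' @export
print.emission_range <- function(x, ...) {
  cat(sprintf(
    "<emission_range> %s: span %.1f-%.1f nm, %d interval(s), threshold %.2g\n",
    x$lamp_type, x$span[1], x$span[2], nrow(x$intervals), x$rel_threshold))
  invisible(x)
}
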