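#' Raw intensity scan
#'
#' Container for raw fNIRS light-intensity data: one time x channel
#' matrix per wavelength.  Intensities must be strictly positive so that
#' optical density (a log-ratio) is defined.
#'
#' @param intensity list of numeric matrices (time x channel), one per
#'   wavelength, or a 3-d array time x channel x wavelength.
#' @param fs sampling rate in Hz (default 7.8125 Hz, the rate of the
#'   continuous-wave system the default probe emulates).
#' @param wavelengths wavelengths in nm, aligned with the list elements.
#' @return An object of class `raw_scan`.
#' @export
raw_scan <- function(intensity, fs = 7.8125, wavelengths = c(760, 850)) {
  if (is.array(intensity) && length(dim(intensity)) == 3L)
    intensity <- lapply(seq_len(dim(intensity)[3]),
                        function(k) intensity[, , k])
  stopifnot(is.list(intensity), length(intensity) == length(wavelengths))
  intensity <- lapply(intensity, as.matrix)
  dm <- dim(intensity[[1]])
  if (dm[1] < 2L) stop("raw scan needs at least 2 time points")
  for (k in seq_along(intensity)) {
    if (!identical(dim(intensity[[k]]), dm))
      stop("intensity matrices must share dimensions across wavelengths")
    bad <- which(intensity[[k]] <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "non-positive intensity at sample %d, channel %d, wavelength %g nm",
        bad[1, 1], bad[1, 2], wavelengths[k]))
  }
  if (fs <= 0) stop("fs must be positive")
  structure(list(intensity = intensity, fs = fs,
                 wavelengths = as.numeric(wavelengths)),
            class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  dm <- dim(x$intensity[[1]])
  cat("<raw_scan> ", dm[1], " samples x ", dm[2], " channels x ",
      length(x$intensity), " wavelengths @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Hemoglobin concentration scan
#'
#' Container for chromophore concentration changes: a time x channel
#' matrix for oxy-hemoglobin (`hbo`) and one for deoxy-hemoglobin
#' (`hbr`), in micromolar, plus the sampling rate and (optionally) the
#' channel table of the probe it was measured with.  The `provenance`
#' flag records whether the data are raw conversions, filtered (and by
#' which filter), or synthetic.
#'
#' @param hbo,hbr numeric time x channel matrices (micromolar).
#' @param fs sampling rate (Hz).
#' @param channels optional channel table (as in
#'   [classify_channels()]), aligned with the matrix columns.
#' @param provenance character tag, e.g. `"raw"`, `"synthetic"`,
#'   `"filtered:pca"`.
#' @return An object of class `hemo_scan`.
#' @export
hemo_scan <- function(hbo, hbr, fs, channels = NULL, provenance = "raw") {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr)))
    stop("HbO2 and Hb blocks must have identical dimensions")
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(channels) && nrow(channels) != ncol(hbo))
    stop("channel table does not match the number of data columns")
  structure(list(hbo = hbo, hbr = hbr, fs = fs, channels = channels,
                 provenance = provenance),
            class = "hemo_scan")
}

#' @export
print.hemo_scan <- function(x, ...) {
  cat("<hemo_scan> ", nrow(x$hbo), " samples x ", ncol(x$hbo),
      " channels @ ", x$fs, " Hz  [", x$provenance, "]\n", sep = "")
  invisible(x)
}

#' Restrict a hemo_scan to a subset of channels
#'
#' @param scan a [hemo_scan()].
#' @param idx integer channel indices to keep.
#' @return A `hemo_scan` with the selected columns (channel table
#'   subset accordingly).
#' @export
subset_channels <- function(scan, idx) {
  stopifnot(inherits(scan, "hemo_scan"))
  hemo_scan(scan$hbo[, idx, drop = FALSE], scan$hbr[, idx, drop = FALSE],
            fs = scan$fs,
            channels = if (!is.null(scan$channels))
              scan$channels[idx, , drop = FALSE],
            provenance = scan$provenance)
}

chromophores <- c("hbo", "hbr")
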