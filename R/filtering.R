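#' Zero-phase bandpass filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth filter of order 4
#' per pass to every channel of a scan.  Zero-phase filtering is used so
#' that the hemodynamic response is not shifted in time, which would
#' bias subsequent GLM estimates.  Either edge may be `NULL` (or 0) for
#' a pass-through; with both edges absent the input is returned
#' unchanged.
#'
#' @param scan a [hemo_scan()].
#' @param low high-pass cutoff in Hz (`NULL`/0 = no high-pass).
#' @param high low-pass cutoff in Hz (`NULL`/0 = no low-pass).
#' @param order Butterworth order per pass.
#' @return A filtered [hemo_scan()] (provenance tagged).
#' @export
bandpass <- function(scan, low = NULL, high = NULL, order = 4) {
  stopifnot(inherits(scan, "hemo_scan"))
  lo <- if (is.null(low) || isTRUE(low == 0)) NULL else low
  hi <- if (is.null(high) || isTRUE(high == 0)) NULL else high
  if (is.null(lo) && is.null(hi)) return(scan)
  nyq <- scan$fs / 2
  for (f in c(lo, hi))
    if (f <= 0 || f >= nyq)
      stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  if (!is.null(lo) && !is.null(hi) && lo >= hi)
    stop("low cutoff must be below high cutoff")
  flt <- if (!is.null(lo) && !is.null(hi)) {
    signal::butter(order, c(lo, hi) / nyq, type = "pass")
  } else if (is.null(lo)) {
    signal::butter(order, hi / nyq, type = "low")
  } else {
    signal::butter(order, lo / nyq, type = "high")
  }
  apply_mat <- function(m) apply(m, 2, function(x) signal::filtfilt(flt, x))
  hemo_scan(apply_mat(scan$hbo), apply_mat(scan$hbr), fs = scan$fs,
            channels = scan$channels,
            provenance = sprintf("filtered:bandpass[%s,%s]",
                                 ifelse(is.null(lo), 0, lo),
                                 ifelse(is.null(hi), "Inf", hi)))
}

filtfilt_matrix <- function(m, flt) apply(m, 2, function(x) signal::filtfilt(flt, x))

#' Scalp coupling index
#'
#' Signal-quality metric for optode-scalp coupling: both wavelength
#' traces of a channel are band-limited to the cardiac band (default
#' 0.5-2.5 Hz) and their zero-lag Pearson correlation is computed.
#' Well-coupled channels show the cardiac pulse at both wavelengths and
#' give an SCI near 1; a threshold of 0.8 is the conventional
#' acceptability cut, exposed in the returned report.  The metric is
#' invariant to per-wavelength affine rescaling of the intensities.
#'
#' @param raw a [raw_scan()] with two wavelengths; at least 10 s long.
#' @param band cardiac band (Hz), length 2.
#' @param threshold acceptability threshold reported alongside.
#' @return A list of class `quality_report`: per-channel `sci`, the
#'   `band`, `threshold`, and logical `acceptable`.
#' @export
scalp_coupling_index <- function(raw, band = c(0.5, 2.5), threshold = 0.8) {
  stopifnot(inherits(raw, "raw_scan"))
  if (length(raw$intensity) != 2L)
    stop("SCI requires exactly two wavelengths")
  n <- nrow(raw$intensity[[1]])
  if (n / raw$fs < 10)
    stop("scan too short for SCI (need at least 10 s)")
  nyq <- raw$fs / 2
  hi <- min(band[2], 0.95 * nyq)
  flt <- signal::butter(4, c(band[1], hi) / nyq, type = "pass")
  b1 <- filtfilt_matrix(scale(raw$intensity[[1]], scale = FALSE), flt)
  b2 <- filtfilt_matrix(scale(raw$intensity[[2]], scale = FALSE), flt)
  sci <- vapply(seq_len(ncol(b1)), function(j) {
    s1 <- stats::sd(b1[, j]); s2 <- stats::sd(b2[, j])
    if (s1 == 0 || s2 == 0) {
      warning("zero-variance band-limited trace in channel ", j,
              "; SCI set to 0")
      return(0)
    }
    stats::cor(b1[, j], b2[, j])
  }, numeric(1))
  structure(list(sci = sci, band = c(band[1], hi), threshold = threshold,
                 acceptable = sci >= threshold),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> SCI band ", x$band[1], "-", x$band[2], " Hz; ",
      sum(x$acceptable), "/", length(x$sci), " channels >= ",
      x$threshold, "\n", sep = "")
  invisible(x)
}
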