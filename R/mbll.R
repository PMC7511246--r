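#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at the
#' requested wavelengths, in cm^-1 / (mol/L).  Values are the
#' Gratzer/Kollias compilation used throughout the fNIRS literature;
#' only 760 and 850 nm are tabulated here since those are the
#' wavelengths of the default probe.  Any consistent extinction
#' convention rescales the estimated concentrations by a constant and
#' therefore cancels in t-statistics and ROC rankings.
#'
#' @param wavelengths wavelengths in nm.
#' @return A 2x2 matrix, rows = wavelengths, columns = c("hbo", "hbr").
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(
    "760" = c(hbo = 1486.59, hbr = 3843.71),
    "850" = c(hbo = 2526.39, hbr = 1798.64))
  key <- as.character(round(wavelengths))
  if (!all(key %in% rownames(tab)))
    stop("no extinction coefficients tabulated for wavelength(s) ",
         paste(setdiff(key, rownames(tab)), collapse = ", "), " nm")
  tab[key, , drop = FALSE]
}

#' Optical density from raw intensity
#'
#' Converts raw intensities to optical-density changes
#' `OD(t) = -log(I(t) / mean_t I)`; normalisation is by the temporal
#' mean of each channel, so a constant channel gives OD identically 0.
#'
#' @param raw a [raw_scan()].
#' @return List of time x channel OD matrices, one per wavelength, with
#'   the per-channel mean intensities attached as attribute
#'   `"mean_intensity"`.
#' @export
od_from_intensity <- function(raw) {
  stopifnot(inherits(raw, "raw_scan"))
  out <- lapply(raw$intensity, function(I) {
    m <- colMeans(I)
    od <- -log(sweep(I, 2, m, "/"))
    attr(od, "mean_intensity") <- m
    od
  })
  names(out) <- as.character(raw$wavelengths)
  attr(out, "fs") <- raw$fs
  out
}

#' Hemoglobin concentrations via the modified Beer-Lambert law
#'
#' Per geometric channel, solves
#' `[dHbO2; dHb] = E^-1 [OD_l1 / (d DPF_l1); OD_l2 / (d DPF_l2)]`
#' with `d` the source-detector distance and `E` the extinction matrix,
#' returning concentration changes in micromolar.
#'
#' @param od list of OD matrices as returned by [od_from_intensity()]
#'   (one per wavelength, aligned with `geometry$wavelengths`).
#' @param geometry a [probe_geometry()]; exactly two wavelengths.
#' @param dpf differential pathlength factor, one scalar per wavelength
#'   (recycled if length 1).  Default 6.0 at both wavelengths, the usual
#'   adult-head convention.
#' @param extinction 2x2 extinction matrix (rows wavelengths, columns
#'   hbo/hbr); defaults to [extinction_coefficients()].
#' @param fs sampling rate; taken from the OD attribute (set by
#'   [od_from_intensity()]) when omitted.
#' @return A [hemo_scan()] with provenance `"raw"`.
#' @export
hemoglobin_from_od <- function(od, geometry, dpf = 6,
                               extinction = NULL, fs = NULL) {
  stopifnot(inherits(geometry, "probe_geometry"))
  if (length(geometry$wavelengths) != 2L || length(od) != 2L)
    stop("modified Beer-Lambert conversion requires OD at exactly two wavelengths")
  if (is.null(extinction))
    extinction <- extinction_coefficients(geometry$wavelengths)
  extinction <- as.matrix(extinction)
  if (abs(det(extinction)) < 1e-12 * prod(sqrt(rowSums(extinction^2))))
    stop("extinction matrix is singular; cannot separate chromophores")
  dpf <- rep_len(dpf, 2L)
  Einv <- solve(extinction)
  ch <- geometry$channels
  d_cm <- ch$distance / 10          # mm -> cm
  n_t <- nrow(od[[1]])
  hbo <- matrix(0, n_t, nrow(ch))
  hbr <- matrix(0, n_t, nrow(ch))
  for (j in seq_len(nrow(ch))) {
    # effective pathlength d * DPF per wavelength, OD scaled to absorbance/cm
    a <- cbind(od[[1]][, j] / (d_cm[j] * dpf[1]),
               od[[2]][, j] / (d_cm[j] * dpf[2]))
    conc <- a %*% t(Einv)           # mol/L
    hbo[, j] <- conc[, 1] * 1e6     # -> micromolar
    hbr[, j] <- conc[, 2] * 1e6
  }
  fs <- fs %||% attr(od, "fs")
  if (is.null(fs)) stop("sampling rate unknown: pass fs explicitly")
  hemo_scan(hbo, hbr, fs = fs, channels = ch, provenance = "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward Beer-Lambert synthesis of raw intensities
#'
#' Inverse of the OD -> hemoglobin pipeline: given concentration
#' changes, computes the optical densities each wavelength would show
#' and exponentiates around a baseline intensity.  Composing
#' `raw_from_hemo()` with [od_from_intensity()] and
#' [hemoglobin_from_od()] recovers the input concentrations exactly up
#' to one additive constant per channel, the unidentifiable DC level
#' absorbed by the temporal-mean normalisation of the OD step.
#'
#' @param scan a [hemo_scan()] whose columns align with
#'   `geometry$channels`.
#' @param geometry a [probe_geometry()].
#' @inheritParams hemoglobin_from_od
#' @param baseline_intensity baseline light level (arbitrary units).
#' @return A [raw_scan()].
#' @export
raw_from_hemo <- function(scan, geometry, dpf = 6, extinction = NULL,
                          baseline_intensity = 1e3) {
  stopifnot(inherits(scan, "hemo_scan"), inherits(geometry, "probe_geometry"))
  if (is.null(extinction))
    extinction <- extinction_coefficients(geometry$wavelengths)
  extinction <- as.matrix(extinction)
  dpf <- rep_len(dpf, 2L)
  ch <- geometry$channels
  if (ncol(scan$hbo) != nrow(ch))
    stop("scan channel count does not match the probe")
  d_cm <- ch$distance / 10
  I <- vector("list", 2L)
  for (k in 1:2) {
    od <- matrix(0, nrow(scan$hbo), nrow(ch))
    for (j in seq_len(nrow(ch))) {
      conc <- cbind(scan$hbo[, j], scan$hbr[, j]) * 1e-6  # molar
      od[, j] <- (conc %*% extinction[k, ]) * d_cm[j] * dpf[k]
    }
    I[[k]] <- baseline_intensity * exp(-od)
  }
  raw_scan(I, fs = scan$fs, wavelengths = geometry$wavelengths)
}
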