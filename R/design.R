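#' Stimulus design
#'
#' Event onsets and durations for one task condition.
#'
#' @param onsets event onsets (s), strictly increasing.
#' @param durations event durations (s), recycled to `length(onsets)`.
#' @param condition condition name.
#' @return Object of class `stim_design`.
#' @export
stim_design <- function(onsets, durations, condition = "task") {
  onsets <- as.numeric(onsets)
  durations <- rep_len(as.numeric(durations), length(onsets))
  if (length(onsets) == 0)
    stop("empty condition: no stimulus events")
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  if (any(durations <= 0)) stop("durations must be positive")
  structure(list(onsets = onsets, durations = durations,
                 condition = condition),
            class = "stim_design")
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: difference of two gamma densities with
#' response peak at 6 s, undershoot peak at 16 s and undershoot ratio
#' 1/6, normalised to unit peak.
#'
#' @param t time points (s) at which to evaluate.
#' @param peak1,peak2 peak times of response and undershoot (s).
#' @param ratio undershoot amplitude relative to the response.
#' @return Numeric vector, `max(h) == 1`.
#' @export
canonical_hrf <- function(t, peak1 = 6, peak2 = 16, ratio = 1/6) {
  # gamma densities with shape = peak + 1, scale = 1 (mode at `peak`)
  h <- stats::dgamma(t, shape = peak1 + 1, scale = 1) -
    ratio * stats::dgamma(t, shape = peak2 + 1, scale = 1)
  h / max(h)
}

#' Task regressor block
#'
#' Builds the canonical task regressors: a boxcar over each event
#' convolved with the double-gamma HRF, sampled at `fs`, one column per
#' condition, normalised to unit peak.
#'
#' @param stim a [stim_design()] or list of them (one per condition).
#' @param n_time number of samples in the scan.
#' @param fs sampling rate (Hz).
#' @param hrf_spec optional list with elements `peak1`, `peak2`,
#'   `ratio` overriding the canonical HRF shape.
#' @return Matrix `n_time` x conditions with condition names as column
#'   names.
#' @export
build_task_design <- function(stim, n_time, fs, hrf_spec = list()) {
  if (inherits(stim, "stim_design")) stim <- list(stim)
  if (fs <= 0) stop("fs must be positive")
  scan_end <- n_time / fs
  cols <- lapply(stim, function(s) {
    if (any(s$onsets + s$durations > scan_end + 1e-9))
      stop("stimulus events extend beyond the scan end (",
           round(scan_end, 2), " s)")
    box <- numeric(n_time)
    tt <- (seq_len(n_time) - 1) / fs
    for (k in seq_along(s$onsets))
      box[tt >= s$onsets[k] & tt < s$onsets[k] + s$durations[k]] <- 1
    if (all(box == 0))
      stop("empty condition '", s$condition,
           "': events produce an all-zero regressor")
    h <- do.call(canonical_hrf,
                 c(list(t = seq(0, 32, by = 1 / fs)), hrf_spec))
    x <- stats::convolve(box, rev(h), type = "open")[seq_len(n_time)]
    x / max(abs(x))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(stim, `[[`, "", "condition")
  if (anyDuplicated(colnames(out))) stop("condition names must be unique")
  out
}

#' Short-separation nuisance regressor block
#'
#' Extracts the SS channel time courses to be used as regressors of no
#' interest (or as a prefilter basis).  Columns are z-scored SS traces
#' of the requested chromophore(s); with `decorrelate = TRUE` the block
#' is replaced by the orthonormal non-zero principal components of
#' those columns (same span, identity Gram matrix), which removes the
#' collinearity between neighbouring SS channels.
#'
#' @param scan a [hemo_scan()] covering the full probe.
#' @param geometry the matching [probe_geometry()].
#' @param ld_channel LD channel index used to rank SS channels by
#'   proximity; ignored when `n_nearest = "all"`.
#' @param mode which chromophore(s) enter the block: `"hbo"`, `"hbr"`
#'   or `"both"`.
#' @param n_nearest how many of the nearest SS channels to use, or
#'   `"all"`.
#' @param decorrelate replace columns by their orthonormal principal
#'   components.
#' @return Matrix time x k with column names carrying provenance
#'   (channel, chromophore, or component index after decorrelation).
#' @export
build_ss_design <- function(scan, geometry, ld_channel = NULL,
                            mode = c("both", "hbo", "hbr"),
                            n_nearest = "all", decorrelate = TRUE) {
  stopifnot(inherits(scan, "hemo_scan"), inherits(geometry, "probe_geometry"))
  mode <- match.arg(mode)
  ch <- geometry$channels
  ss_all <- which(ch$type == "SS")
  if (length(ss_all) == 0L) stop("probe has no SS channels")
  sel <- if (identical(n_nearest, "all")) {
    ss_all
  } else {
    if (is.null(ld_channel))
      stop("ld_channel is required when selecting the nearest SS channels")
    nearest_ss(geometry, ld_channel, n_nearest)
  }
  want <- switch(mode, both = chromophores, hbo = "hbo", hbr = "hbr")
  cols <- list()
  for (cc in want)
    for (j in sel) {
      x <- scan[[cc]][, j]
      s <- stats::sd(x)
      cols[[paste0("ss", j, "_", cc)]] <-
        if (s > 0) (x - mean(x)) / s else x - mean(x)
    }
  xs <- do.call(cbind, cols)
  if (!decorrelate) return(xs)
  sv <- svd(xs)
  keep <- sv$d > max(dim(xs)) * .Machine$double.eps * sv$d[1]
  out <- sv$u[, keep, drop = FALSE]
  colnames(out) <- paste0("ss_pc", seq_len(ncol(out)))
  out
}
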