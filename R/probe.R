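#' Probe geometry for an fNIRS montage
#'
#' A probe geometry holds optode positions and the list of measured
#' source-detector channels.  Channels whose source-detector separation is
#' below `ss_threshold` are classified as short-separation (SS, scalp-only)
#' channels; the remainder are long-distance (LD, brain-sensitive) channels.
#'
#' @param sources numeric matrix of source positions (one row per source,
#'   columns x/y or x/y/z, millimetres).
#' @param detectors numeric matrix of detector positions, same layout.
#' @param channels data frame with integer columns `source` and `detector`
#'   (1-based indices into `sources` / `detectors`).
#' @param wavelengths numeric vector of the measured wavelengths in nm.
#' @param ss_threshold separation (mm) below which a channel is classified
#'   as short-separation.  Channels at exactly the threshold are LD
#'   (half-open convention), so classification is deterministic.
#'
#' @return An object of class `probe_geometry` with the validated inputs
#'   plus per-channel `distance` (mm) and `type` (`"SS"`/`"LD"`) columns.
#' @seealso [default_probe()], [classify_channels()], [nearest_ss()]
#' @export
probe_geometry <- function(sources, detectors, channels,
                           wavelengths = c(760, 850), ss_threshold = 15) {
  sources <- as.matrix(sources)
  detectors <- as.matrix(detectors)
  storage.mode(sources) <- "double"
  storage.mode(detectors) <- "double"
  if (!all(is.finite(sources)) || !all(is.finite(detectors)))
    stop("optode positions must be finite")
  if (ncol(sources) != ncol(detectors))
    stop("sources and detectors must have the same number of coordinates")
  channels <- as.data.frame(channels)
  if (!all(c("source", "detector") %in% names(channels)))
    stop("channels must have 'source' and 'detector' columns")
  si <- as.integer(channels$source)
  di <- as.integer(channels$detector)
  if (any(si < 1L) || any(si > nrow(sources)))
    stop("channel references a non-existent source")
  if (any(di < 1L) || any(di > nrow(detectors)))
    stop("channel references a non-existent detector")
  d <- sqrt(rowSums((sources[si, , drop = FALSE] -
                     detectors[di, , drop = FALSE])^2))
  if (any(d <= 0))
    stop("channel source-detector distance must be strictly positive (channel ",
         which(d <= 0)[1], ")")
  if (ss_threshold <= 0) stop("ss_threshold must be positive")
  geom <- list(
    sources = sources,
    detectors = detectors,
    channels = data.frame(
      source = si, detector = di, distance = d,
      type = ifelse(d < ss_threshold, "SS", "LD"),
      stringsAsFactors = FALSE),
    wavelengths = as.numeric(wavelengths),
    ss_threshold = ss_threshold)
  class(geom) <- "probe_geometry"
  geom
}

#' @export
print.probe_geometry <- function(x, ...) {
  tab <- table(x$channels$type)
  cat("<probe_geometry> ", nrow(x$sources), " sources, ",
      nrow(x$detectors), " detectors, ",
      nrow(x$channels), " channels (",
      sum(x$channels$type == "LD"), " LD / ",
      sum(x$channels$type == "SS"), " SS at <", x$ss_threshold, " mm)\n",
      sep = "")
  invisible(x)
}

#' Default motor-strip probe
#'
#' Builds the package's reference montage: 8 sources in a row at 10 mm
#' pitch, 8 LD detectors on a parallel row giving 22 long-distance
#' channels with separations of 30.0 or 33.2 mm, and one dedicated
#' short-separation detector 7.5 mm from each source (8 SS channels).
#' The SS optodes are angled so that for every LD channel the nearest SS
#' channel midpoint lies 13.4 to 15.5 mm away, matching the spacing of
#' commercial short-separation caps.
#'
#' @param ss_threshold separation threshold (mm) for SS classification.
#' @return A [probe_geometry()] with 22 LD + 8 SS channels.
#' @export
default_probe <- function(ss_threshold = 15) {
  pitch <- 10
  n_src <- 8L
  sx <- pitch * (0:(n_src - 1L))
  sources <- cbind(x = sx, y = rep(0, n_src))
  # LD detectors: +5 mm along the row, sqrt(875) mm across it, so that the
  # in-column pair is exactly 30 mm and the diagonal pair sqrt(1100) mm.
  ld_det <- cbind(x = sx + 5, y = rep(sqrt(875), n_src))
  # SS detectors: 7.5 mm from each source, 15 degrees off the source row.
  a <- 15 * pi / 180
  ss_det <- cbind(x = sx + 7.5 * cos(a), y = rep(7.5 * sin(a), n_src))
  detectors <- rbind(ld_det, ss_det)
  ld_pairs <- do.call(rbind, lapply(seq_len(n_src), function(k) {
    j <- intersect((k - 1L):(k + 1L), seq_len(n_src))
    cbind(source = k, detector = j)
  }))
  ss_pairs <- cbind(source = seq_len(n_src),
                    detector = n_src + seq_len(n_src))
  channels <- as.data.frame(rbind(ld_pairs, ss_pairs))
  probe_geometry(sources, detectors, channels, ss_threshold = ss_threshold)
}

#' Channel classification table
#'
#' @param geometry a [probe_geometry()].
#' @return Data frame with one row per channel: `source`, `detector`,
#'   `distance` (mm) and `type` (`"SS"` or `"LD"`).  A pure function of
#'   the geometry.
#' @export
classify_channels <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  geometry$channels
}

channel_midpoints <- function(geometry) {
  ch <- geometry$channels
  (geometry$sources[ch$source, , drop = FALSE] +
   geometry$detectors[ch$detector, , drop = FALSE]) / 2
}

#' Nearest short-separation channels for a long-distance channel
#'
#' Ranks SS channels by the distance between channel midpoints
#' ("center-to-center" distance) and returns the `n` closest.  Ties are
#' broken deterministically by channel index.
#'
#' @param geometry a [probe_geometry()].
#' @param ld_channel index (into the full channel table) of an LD channel.
#' @param n number of SS channels to return; `"all"` for every SS channel.
#' @return Integer vector of channel indices (ascending midpoint distance).
#' @export
nearest_ss <- function(geometry, ld_channel, n = "all") {
  stopifnot(inherits(geometry, "probe_geometry"))
  ch <- geometry$channels
  ld_channel <- as.integer(ld_channel)
  if (ld_channel < 1L || ld_channel > nrow(ch))
    stop("ld_channel out of range")
  if (ch$type[ld_channel] != "LD")
    stop("channel ", ld_channel, " is not a long-distance channel")
  ss_idx <- which(ch$type == "SS")
  if (identical(n, "all")) n <- length(ss_idx)
  n <- as.integer(n)
  if (n < 1L || n > length(ss_idx))
    stop("n must be between 1 and the number of SS channels (",
         length(ss_idx), ")")
  mids <- channel_midpoints(geometry)
  d <- sqrt(rowSums((mids[ss_idx, , drop = FALSE] -
                     matrix(mids[ld_channel, ], length(ss_idx),
                            ncol(mids), byrow = TRUE))^2))
  ord <- order(d, ss_idx)   # distance, then channel index for ties
  ss_idx[ord][seq_len(n)]
}
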