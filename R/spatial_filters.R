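#' Spatial principal components of a scan
#'
#' Singular value decomposition of the (time-centred) channel-space
#' data, used by the PCA prefilters.  The number of components to
#' remove is the smallest n whose cumulative squared-singular-value
#' share reaches `variance_fraction` of the spatial covariance
#' (the conventional 80% rule).
#'
#' @param x time x channel matrix (one chromophore; components are
#'   never shared between HbO2 and Hb).
#' @param variance_fraction target fraction of spatial covariance in
#'   (0, 1]; values <= 0 mean "remove nothing".
#' @return List of class `spatial_decomposition` with `u`, `d`
#'   (singular values, descending), `v` (orthonormal spatial
#'   components), `n_removed`, `variance_fraction`, and `center`.
#' @export
fit_spatial_components <- function(x, variance_fraction = 0.8) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 channels")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (all(abs(xc) < .Machine$double.eps))
    stop("degenerate (constant) data: no spatial covariance to decompose")
  sv <- svd(xc)
  share <- cumsum(sv$d^2) / sum(sv$d^2)
  n_removed <- if (variance_fraction <= 0) 0L else
    which(share >= variance_fraction - 1e-12)[1]
  structure(list(u = sv$u, d = sv$d, v = sv$v,
                 n_removed = as.integer(n_removed),
                 variance_fraction = variance_fraction,
                 center = ctr),
            class = "spatial_decomposition")
}

#' Spatial PCA / baseline-PCA prefilter
#'
#' Removes the dominant spatial components of the systemic physiology:
#' components are fit with [fit_spatial_components()] on the baseline
#' scan when one is supplied (bPCA) and on the task scan itself
#' otherwise (PCA), separately per chromophore, and the task data are
#' projected onto the orthogonal complement
#' `Yf = Y - (Y V) V'` over the removed components.
#'
#' @param task a [hemo_scan()] to be filtered.
#' @param baseline optional [hemo_scan()] with the same channel layout;
#'   when given, components come from it (bPCA).
#' @param variance_fraction cumulative-variance rule for the number of
#'   removed components (default 0.8).
#' @return The filtered [hemo_scan()].
#' @export
pca_filter <- function(task, baseline = NULL, variance_fraction = 0.8) {
  stopifnot(inherits(task, "hemo_scan"))
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "hemo_scan"))
    if (ncol(baseline$hbo) != ncol(task$hbo))
      stop("baseline and task scans have different channel layouts")
  }
  out <- list()
  for (cc in chromophores) {
    fit_on <- if (is.null(baseline)) task[[cc]] else baseline[[cc]]
    dec <- fit_spatial_components(fit_on, variance_fraction)
    y <- task[[cc]]
    if (dec$n_removed > 0L) {
      v <- dec$v[, seq_len(dec$n_removed), drop = FALSE]
      y <- y - (y %*% v) %*% t(v)
    }
    out[[cc]] <- y
  }
  hemo_scan(out$hbo, out$hbr, fs = task$fs, channels = task$channels,
            provenance = if (is.null(baseline)) "filtered:pca"
                         else "filtered:bpca")
}

#' Short-separation prefilter: unconstrained projection
#'
#' Projects the span of the SS nuisance time courses out of the
#' long-distance data:
#' `Yf = (I - Xs (Xs'Xs)^-1 Xs') Ylong`.
#' No spatial information is used; the residual is orthogonal to every
#' nuisance column.  `xshort` must have full column rank - decorrelate
#' collinear SS blocks first (see [build_ss_design()]).
#'
#' @param long time x channel matrix (or [hemo_scan()], filtered per
#'   chromophore with the same `xshort`).
#' @param xshort time x k nuisance matrix.
#' @return Object of the same type as `long`, filtered.
#' @export
ss_projection_filter <- function(long, xshort) {
  xshort <- as.matrix(xshort)
  if (inherits(long, "hemo_scan")) {
    if (nrow(xshort) != nrow(long$hbo))
      stop("xshort and data have different numbers of time points")
    return(hemo_scan(ss_projection_filter(long$hbo, xshort),
                     ss_projection_filter(long$hbr, xshort),
                     fs = long$fs, channels = long$channels,
                     provenance = "filtered:ss_projection"))
  }
  y <- as.matrix(long)
  if (nrow(xshort) != nrow(y))
    stop("xshort and data have different numbers of time points")
  qx <- qr(xshort)
  if (qx$rank < ncol(xshort))
    stop("xshort is rank deficient; decorrelate the SS block first ",
         "(build_ss_design(..., decorrelate = TRUE))")
  y - qr.fitted(qx, y)
}

#' Analytic skin sensitivity model
#'
#' Builds the measurement-to-skin forward operator used by the
#' image-reconstruction SS filter: a regular lattice of skin nodes is
#' laid over the probe's bounding box, each channel's sensitivity to a
#' node falls off as a Gaussian of the node's distance from the channel
#' midpoint, and long-distance channels carry a reduced amplitude
#' (partial pathlength through skin) relative to SS channels.  A
#' Gaussian spatial basis with unit-norm columns provides the
#' low-spatial-frequency smoothing of the reconstructed skin image.
#'
#' @param geometry a [probe_geometry()].
#' @param kernel_width_mm Gaussian width of the channel sensitivity and
#'   of the basis kernels (mm).
#' @param lam regularisation hyperparameter; `NULL` defers to the
#'   filter's spectral default.
#' @param grid_spacing_mm skin-node lattice pitch (mm).
#' @param pad_mm bounding-box padding (mm).
#' @param ld_skin_factor relative skin sensitivity of LD vs SS channels.
#' @return List of class `skin_model` with `L` (channels x nodes),
#'   `sbasis` (nodes x basis, unit-norm columns), `nodes`, `lam`.
#' @export
build_skin_model <- function(geometry, kernel_width_mm = 15, lam = NULL,
                             grid_spacing_mm = 10, pad_mm = 20,
                             ld_skin_factor = 0.3) {
  stopifnot(inherits(geometry, "probe_geometry"))
  if (kernel_width_mm <= 0 || grid_spacing_mm <= 0)
    stop("kernel width and grid spacing must be positive")
  if (!is.null(lam) && lam <= 0) stop("lam must be positive")
  pos <- rbind(geometry$sources, geometry$detectors)[, 1:2, drop = FALSE]
  gx <- seq(min(pos[, 1]) - pad_mm, max(pos[, 1]) + pad_mm,
            by = grid_spacing_mm)
  gy <- seq(min(pos[, 2]) - pad_mm, max(pos[, 2]) + pad_mm,
            by = grid_spacing_mm)
  nodes <- as.matrix(expand.grid(x = gx, y = gy))
  mids <- channel_midpoints(geometry)[, 1:2, drop = FALSE]
  ch <- geometry$channels
  d2 <- outer(rowSums(mids^2), rowSums(nodes^2), "+") -
    2 * mids %*% t(nodes)
  L <- exp(-pmax(d2, 0) / (2 * kernel_width_mm^2))
  L <- L * ifelse(ch$type == "SS", 1, ld_skin_factor)
  # Basis kernels: centred on a strided subset of the skin nodes,
  # restricted to the region the probe actually senses, so that every
  # basis column is informed by the data and L %*% sbasis keeps full
  # column rank (and the width -> 0 limit degenerates to single nodes).
  stride <- function(v, lo, hi) {
    v <- v[v >= lo & v <= hi]
    v[seq(1, length(v), by = 2L)]
  }
  bx <- stride(gx, min(mids[, 1]) - grid_spacing_mm,
               max(mids[, 1]) + grid_spacing_mm)
  by <- stride(gy, min(mids[, 2]) - grid_spacing_mm,
               max(mids[, 2]) + grid_spacing_mm)
  bcen <- as.matrix(expand.grid(x = bx, y = by))
  b2 <- outer(rowSums(nodes^2), rowSums(bcen^2), "+") -
    2 * nodes %*% t(bcen)
  sbasis <- exp(-pmax(b2, 0) / (2 * kernel_width_mm^2))
  sbasis <- sweep(sbasis, 2, sqrt(colSums(sbasis^2)), "/")
  structure(list(L = L, sbasis = sbasis, nodes = nodes, lam = lam),
            class = "skin_model")
}

#' Short-separation prefilter: image reconstruction
#'
#' Removes the superficial signal by reconstructing a smooth skin image
#' from all channels (SS and LD) and subtracting its forward
#' projection:
#' `Yf' = [I - L S (S'L'L S + lam I)^-1 S'L'] Y'`
#' where `L` is the skin sensitivity operator and `S` the smoothing
#' basis of a [build_skin_model()].  As `lam` grows the operator tends
#' to the identity; as `lam` shrinks, data in the span of `L S` are
#' annihilated.
#'
#' @param scan a [hemo_scan()] covering all channels (rows of `L`), or
#'   a plain time x channel matrix.
#' @param skin a [build_skin_model()].
#' @param lam override of the model's regularisation; default
#'   `0.01 * max eigenvalue of (LS)'(LS)`.
#' @return Filtered object of the same type as `scan`.
#' @export
ss_image_filter <- function(scan, skin, lam = NULL) {
  stopifnot(inherits(skin, "skin_model"))
  A <- skin$L %*% skin$sbasis             # channels x basis
  G <- crossprod(A)
  lam <- lam %||% skin$lam %||% (0.01 * max(eigen(G, symmetric = TRUE,
                                                  only.values = TRUE)$values))
  filt1 <- function(y) {
    y <- as.matrix(y)
    if (ncol(y) != nrow(skin$L))
      stop("scan has ", ncol(y), " channels but the skin model expects ",
           nrow(skin$L))
    # Y' columns are channel vectors: operate on t(y)
    yt <- t(y)
    yt_f <- yt - A %*% solve(G + lam * diag(ncol(G)), crossprod(A, yt))
    t(yt_f)
  }
  if (inherits(scan, "hemo_scan"))
    return(hemo_scan(filt1(scan$hbo), filt1(scan$hbr), fs = scan$fs,
                     channels = scan$channels,
                     provenance = "filtered:ss_image"))
  filt1(scan)
}
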