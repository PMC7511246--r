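#' Write a hemoglobin scan to CSV
#'
#' Plain-text interchange format: one `time` column followed by one
#' column per channel and chromophore, headers of the form
#' `ch<index>_<hbo|hbr>`.  Channel metadata (source, detector,
#' distance, type) and the sampling rate go to a sidecar
#' `<path>.channels.csv` so the scan can be reconstructed exactly.
#'
#' @param scan a [hemo_scan()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "hemo_scan"))
  n <- nrow(scan$hbo)
  df <- data.frame(time = (seq_len(n) - 1) / scan$fs)
  for (cc in chromophores) {
    m <- scan[[cc]]
    colnames(m) <- paste0("ch", seq_len(ncol(m)), "_", cc)
    df <- cbind(df, m)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- scan$channels %||%
    data.frame(source = NA, detector = NA, distance = NA,
               type = NA)[rep(1, ncol(scan$hbo)), ]
  meta_path <- paste0(path, ".channels.csv")
  meta$fs <- scan$fs
  meta$provenance <- scan$provenance
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' Read a hemoglobin scan written by [write_scan_csv()]
#'
#' @param path CSV path.
#' @return A [hemo_scan()].
#' @export
read_scan_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".channels.csv")
  if (!file.exists(meta_path))
    stop("missing channel sidecar file: ", meta_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  hbo <- as.matrix(df[, grepl("_hbo$", names(df)), drop = FALSE])
  hbr <- as.matrix(df[, grepl("_hbr$", names(df)), drop = FALSE])
  dimnames(hbo) <- dimnames(hbr) <- NULL
  fs <- meta$fs[1]
  channels <- if (nrow(meta)) meta[, c("source", "detector",
                                       "distance", "type")] else NULL
  hemo_scan(hbo, hbr, fs = fs, channels = channels,
            provenance = meta$provenance[1] %||% "raw")
}

#' Write benchmark results with a reproducibility snapshot
#'
#' Emits the summary table and pooled decisions as CSV, plus a YAML
#' snapshot of every resolved parameter (seeds, noise spec, pipeline
#' grid) and a run log with timestamps and package version, so a run
#' can be replayed exactly.
#'
#' @param bench a `benchmark_result`.
#' @param config list of resolved parameters to snapshot.
#' @param outdir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_results <- function(bench, config = list(), outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable")
  utils::write.csv(bench$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bench$pooled, file.path(outdir, "decisions.csv"),
                   row.names = FALSE)
  config$master_seed <- bench$master_seed
  config$n_failed <- bench$n_failed
  yaml::write_yaml(config, file.path(outdir, "config_snapshot.yaml"))
  writeLines(c(
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste("nirsphysio version:",
          as.character(utils::packageVersion("nirsphysio"))),
    paste("master seed:", bench$master_seed),
    paste("failed iterations:", bench$n_failed)),
    file.path(outdir, "run.log"))
  invisible(outdir)
}

#' Read a run configuration file
#'
#' YAML configuration with optional blocks `noise`, `simulation`,
#' `pipeline` and `seed`; unknown keys are rejected so typos fail
#' loudly.  Values override the package defaults of [noise_spec()],
#' [simulation_spec()] and [pipeline_spec()].
#'
#' @param path YAML file.
#' @return List with resolved `noise`, `simulation`, `pipeline`,
#'   `seed`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("noise", "simulation", "pipeline", "seed", "n_iterations",
             "outdir")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  list(
    noise = do.call(noise_spec, cfg$noise %||% list()),
    simulation = do.call(simulation_spec, cfg$simulation %||% list()),
    pipeline = do.call(pipeline_spec, cfg$pipeline %||% list()),
    seed = cfg$seed %||% 1L,
    n_iterations = cfg$n_iterations %||% 200L,
    outdir = cfg$outdir %||% "results")
}
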