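#!/usr/bin/env Rscript
# Thin command-line front end over the nirsphysio package.
#
#   nirsphysio simulate --config run.yaml --out scans/      # synthetic scans + truth
#   nirsphysio run      --config run.yaml --scan scan.csv   # one GLM fit -> tidy CSV
#   nirsphysio roc      --config run.yaml                   # benchmark grid -> CSVs
#
# Every run writes a resolved-config snapshot sufficient for exact replay.

suppressMessages({
  library(optparse)
  library(nirsphysio)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1 || !argv[1] %in% c("simulate", "run", "roc")) {
  cat("usage: nirsphysio <simulate|run|roc> [--config FILE] [options]\n")
  quit(status = 1)
}
cmd <- argv[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration file"),
  make_option("--scan", type = "character", default = NULL,
              help = "input scan CSV (run)"),
  make_option("--out", type = "character", default = NULL,
              help = "output directory"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed override"),
  make_option("--iterations", type = "integer", default = NULL,
              help = "iteration count override (roc)")))
opt <- parse_args(parser, args = argv[-1])

cfg <- if (!is.null(opt$config)) read_config(opt$config) else
  list(noise = noise_spec(), simulation = simulation_spec(),
       pipeline = pipeline_spec(), seed = 1L, n_iterations = 200L,
       outdir = "results")
`%||%` <- function(a, b) if (is.null(a)) b else a
if (!is.null(opt$seed)) cfg$seed <- opt$seed
if (!is.null(opt$iterations)) cfg$n_iterations <- opt$iterations
outdir <- opt$out %||% cfg$outdir %||% "results"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

geom <- default_probe()
message("resolved defaults: fs = ", cfg$noise$fs, " Hz, duration = ",
        cfg$noise$duration, " s, condition = ", cfg$pipeline$condition,
        ", seed = ", cfg$seed)

if (cmd == "simulate") {
  ev <- make_events(cfg$pipeline$condition, cfg$noise$duration,
                    seed = cfg$seed)
  scan <- generate_noise_scan(cfg$noise, ev, seed = cfg$seed + 1L,
                              geometry = geom)
  inj <- inject_response(scan, ev, cfg$simulation$cnr, seed = cfg$seed + 2L)
  write_scan_csv(inj$scan, file.path(outdir, "scan.csv"))
  utils::write.csv(data.frame(channel = seq_along(inj$truth),
                              truth = inj$truth),
                   file.path(outdir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(noise = unclass(cfg$noise),
                        simulation = unclass(cfg$simulation),
                        seed = cfg$seed),
                   file.path(outdir, "config_snapshot.yaml"))
  message("wrote scan.csv, truth.csv, config_snapshot.yaml to ", outdir)
} else if (cmd == "run") {
  if (is.null(opt$scan)) stop("run requires --scan")
  scan <- read_scan_csv(opt$scan)
  ev <- make_events(cfg$pipeline$condition, cfg$noise$duration,
                    seed = cfg$seed)
  xt <- build_task_design(ev$stim, nrow(scan$hbo), scan$fs)
  xs <- if (cfg$pipeline$ss_mode != "none")
    build_ss_design(scan, geom, mode = cfg$pipeline$ss_mode,
                    n_nearest = cfg$pipeline$n_nearest,
                    decorrelate = cfg$pipeline$solver != "me_ar_irls")
  des <- design_matrix(xt, xs, fs = scan$fs)
  ld <- which(classify_channels(geom)$type == "LD")
  yl <- subset_channels(scan, ld)
  tabs <- lapply(c("hbo", "hbr"), function(cc) {
    fit <- switch(cfg$pipeline$solver,
                  ols = ols_fit(yl, des, chromophore = cc),
                  ar_irls = ar_irls_fit(yl, des, chromophore = cc),
                  me_ar_irls = me_ar_irls_fit(yl, des, chromophore = cc))
    tidy_glm(fit, chromophore = cc)
  })
  utils::write.csv(do.call(rbind, tabs), file.path(outdir, "glm.csv"),
                   row.names = FALSE)
  message("wrote glm.csv to ", outdir)
} else if (cmd == "roc") {
  bench <- run_benchmark(cfg$pipeline, n_iterations = cfg$n_iterations,
                         master_seed = cfg$seed, geometry = geom,
                         noise = cfg$noise)
  write_results(bench, config = list(noise = unclass(cfg$noise),
                                     pipeline = unclass(cfg$pipeline)),
                outdir = outdir)
  message("wrote benchmark results to ", outdir)
}
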