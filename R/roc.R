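#' Pipeline specification
#'
#' One cell of the processing grid: a simulated condition, a
#' prefilter, a GLM solver, and the short-separation options.  The
#' full 3 conditions x 4 prefilters x 5 solver-variants grid of the
#' benchmark is expressible by crossing the argument levels.
#'
#' @param condition simulation condition (`rest`, `bh_random`,
#'   `bh_locked`).
#' @param prefilter `none`, `pca`, `bpca`, `ss_projection` or
#'   `ss_image`.
#' @param solver `ols`, `ar_irls` or `me_ar_irls`.
#' @param ss_mode chromophores entering the SS regression block:
#'   `none` (no SS regressors), `hbo`, `hbr` or `both`.
#' @param n_nearest SS channels per LD channel (`"all"` or a count).
#' @param bandpass optional `c(low, high)` cutoffs (Hz; `NA` = open
#'   edge).
#' @param cnr contrast-to-noise ratio of the injected responses.
#' @return List of class `pipeline_spec`.
#' @export
pipeline_spec <- function(condition = "rest", prefilter = "none",
                          solver = "ar_irls", ss_mode = "none",
                          n_nearest = "all", bandpass = NULL, cnr = 0.7) {
  prefilter <- match.arg(prefilter,
                         c("none", "pca", "bpca", "ss_projection", "ss_image"))
  solver <- match.arg(solver, c("ols", "ar_irls", "me_ar_irls"))
  ss_mode <- match.arg(ss_mode, c("none", "hbo", "hbr", "both"))
  condition <- match.arg(condition, c("rest", "bh_random", "bh_locked"))
  if (solver == "me_ar_irls" && ss_mode == "none")
    stop("the mixed-effects solver requires SS regressors (ss_mode != 'none')")
  structure(list(condition = condition, prefilter = prefilter,
                 solver = solver, ss_mode = ss_mode,
                 n_nearest = n_nearest, bandpass = bandpass, cnr = cnr),
            class = "pipeline_spec")
}

#' Run one simulation iteration through a pipeline
#'
#' Generates a background scan and events for the pipeline's
#' condition, injects responses at the requested CNR into half of the
#' LD channels, applies the prefilter, solves the GLM, and returns the
#' per-channel p-values with their truth labels.  Deterministic given
#' the seed.
#'
#' @param pipeline a [pipeline_spec()].
#' @param seed integer iteration seed.
#' @param geometry probe (default [default_probe()]).
#' @param noise a [noise_spec()].
#' @param joint also compute the Hotelling joint test.
#' @param chromophores which chromophores to fit (the headline metric
#'   is HbO2; restricting saves half the compute).
#' @return Data frame with one row per LD channel and test
#'   (`chromophore` in hbo/hbr/joint): `channel`, `chromophore`, `p`,
#'   `truth`, `seed`.
#' @export
run_iteration <- function(pipeline, seed, geometry = default_probe(),
                          noise = noise_spec(), joint = FALSE,
                          chromophores = c("hbo", "hbr")) {
  stopifnot(inherits(pipeline, "pipeline_spec"))
  ev <- make_events(pipeline$condition, noise$duration, seed = seed)
  scan <- generate_noise_scan(noise, ev, seed = seed + 1L,
                              geometry = geometry)
  inj <- inject_response(scan, ev, pipeline$cnr, seed = seed + 2L)
  scan <- inj$scan
  if (!is.null(pipeline$bandpass)) {
    bp <- pipeline$bandpass
    lo <- if (is.na(bp[1])) NULL else bp[1]
    hi <- if (length(bp) > 1 && !is.na(bp[2])) bp[2] else NULL
    scan <- bandpass(scan, low = lo, high = hi)
  }
  filtered <- apply_prefilter(scan, pipeline, geometry, noise, seed)
  ld <- which(geometry$channels$type == "LD")
  xtask <- build_task_design(ev$stim, nrow(scan$hbo), scan$fs)
  ylong <- subset_channels(filtered, ld)
  if (joint && length(chromophores) < 2L)
    stop("the joint test needs both chromophores")
  # The ME solver regularises the collinear raw SS block through its
  # pooled prior, so it gets the un-decorrelated traces; the fixed-effects
  # solvers get the PCA-decorrelated reparameterisation.
  decorr <- pipeline$solver != "me_ar_irls"
  solve_with <- function(y, des, cc)
    switch(pipeline$solver,
           ols = ols_fit(y, des, chromophore = cc),
           ar_irls = suppressWarnings(
             ar_irls_fit(y, des, chromophore = cc)),
           me_ar_irls = suppressWarnings(
             me_ar_irls_fit(y, des, chromophore = cc)))
  fits <- if (pipeline$ss_mode != "none" &&
              !identical(pipeline$n_nearest, "all")) {
    # nearest-n SS selection is relative to each LD channel
    des_list <- lapply(ld, function(ch) {
      xs_k <- build_ss_design(scan, geometry, ld_channel = ch,
                              mode = pipeline$ss_mode,
                              n_nearest = pipeline$n_nearest,
                              decorrelate = decorr)
      design_matrix(xtask, xs_k, fs = scan$fs)
    })
    if (pipeline$solver == "me_ar_irls") {
      # one joint fit: per-channel designs, probe-pooled prior
      lapply(chromophores, function(cc)
        suppressWarnings(me_ar_irls_fit(ylong, des_list,
                                        chromophore = cc)))
    } else {
      lapply(chromophores, function(cc) {
        per <- lapply(seq_along(ld), function(k) {
          f <- solve_with(ylong[[cc]][, k, drop = FALSE],
                          des_list[[k]], cc)
          f$stats$channel <- k
          f
        })
        list(stats = do.call(rbind, lapply(per, `[[`, "stats")),
             details = lapply(per, function(f) f$details[[1]]))
      })
    }
  } else {
    xshort <- if (pipeline$ss_mode != "none")
      build_ss_design(scan, geometry, mode = pipeline$ss_mode,
                      n_nearest = "all", decorrelate = decorr)
    des <- design_matrix(xtask, xshort, fs = scan$fs)
    lapply(chromophores, function(cc) solve_with(ylong, des, cc))
  }
  names(fits) <- chromophores
  truth_ld <- inj$truth[ld]
  rows <- lapply(chromophores, function(cc) {
    st <- fits[[cc]]$stats
    st <- st[st$term == colnames(xtask)[1], ]
    data.frame(channel = ld[st$channel], chromophore = cc, p = st$p,
               truth = truth_ld[st$channel], seed = seed)
  })
  if (joint) {
    hj <- hotelling_joint(fits$hbo, fits$hbr)
    rows <- c(rows, list(
      data.frame(channel = ld[hj$channel], chromophore = "joint",
                 p = hj$p, truth = truth_ld[hj$channel], seed = seed)))
  }
  do.call(rbind, rows)
}

apply_prefilter <- function(scan, pipeline, geometry, noise, seed) {
  switch(pipeline$prefilter,
         none = scan,
         pca = pca_filter(scan),
         bpca = {
           # independent baseline scan from the same noise process
           base_ev <- if (pipeline$condition == "rest") NULL else
             make_events(pipeline$condition, noise$duration,
                         seed = seed + 7919L)
           base <- generate_noise_scan(noise, base_ev, seed = seed + 7919L,
                                       geometry = geometry)
           pca_filter(scan, baseline = base)
         },
         ss_projection = {
           xs <- build_ss_design(scan, geometry, mode = ss_mode_or_both(pipeline),
                                 n_nearest = "all", decorrelate = TRUE)
           ss_projection_filter(scan, xs)
         },
         ss_image = {
           skin <- build_skin_model(geometry)
           ss_image_filter(scan, skin)
         })
}

ss_mode_or_both <- function(pipeline)
  if (pipeline$ss_mode == "none") "both" else pipeline$ss_mode

#' Empirical ROC curve from pooled p-values
#'
#' Ranks channels by `1 - p` and sweeps the decision threshold over
#' the unique p-values.  The area under the curve is computed by the
#' trapezoidal rule, which for the empirical ROC equals the
#' Mann-Whitney probability that a random truth-positive channel gets
#' a smaller p-value than a random truth-negative one (ties counted
#' half).
#'
#' @param p p-values.
#' @param truth logical truth labels (same length).
#' @return List of class `roc_curve`: `fpr`, `tpr` (non-decreasing),
#'   `thresholds` (p-value cutoffs), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(p, truth) {
  keep <- !is.na(truth) & !is.na(p)
  p <- p[keep]; truth <- as.logical(truth[keep])
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("both truth classes must be present")
  th <- sort(unique(p))
  cum <- t(vapply(th, function(cut)
    c(tpr = sum(p[truth] <= cut), fpr = sum(p[!truth] <= cut)),
    numeric(2)))
  tpr <- c(0, cum[, "tpr"] / n_pos)
  fpr <- c(0, cum[, "fpr"] / n_neg)
  # Mann-Whitney AUC (ties half-weighted)
  r <- rank(p)
  auc <- (sum(r[!truth]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(0, th),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 p = p, truth = truth),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", x$n_pos, " pos / ", x$n_neg, " neg, AUC = ",
      round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "FPR", ylab = "TPR", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Partial area under the ROC curve
#'
#' Trapezoidal area restricted to `fpr <= fpr_max`, with linear
#' interpolation of the curve at the cut.  The normalised value
#' divides by `fpr_max`, so a perfect classifier scores 1 and the
#' chance line scores `fpr_max / 2`.
#'
#' @param curve a [roc_curve()].
#' @param fpr_max upper FPR bound (default 0.05, the conventional
#'   reporting range).
#' @param normalized divide by `fpr_max`.
#' @return Scalar pAUC.
#' @export
partial_auc <- function(curve, fpr_max = 0.05, normalized = TRUE) {
  if (fpr_max <= 0 || fpr_max > 1) stop("fpr_max must be in (0, 1]")
  fpr <- curve$fpr; tpr <- curve$tpr
  if (max(fpr) < fpr_max) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  cut <- max(which(fpr <= fpr_max))
  xs <- fpr[seq_len(cut)]; ys <- tpr[seq_len(cut)]
  if (fpr[cut] < fpr_max) {
    nxt <- cut + 1L
    y_cut <- ys[cut] + (tpr[nxt] - ys[cut]) *
      (fpr_max - xs[cut]) / (fpr[nxt] - xs[cut])
    xs <- c(xs, fpr_max); ys <- c(ys, y_cut)
  }
  raw <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  if (normalized) raw / fpr_max else raw
}

#' DeLong test for the difference of two correlated AUCs
#'
#' Nonparametric comparison of two classifiers scored on the same
#' channels: AUCs are written as means of placement values, whose
#' empirical covariance yields the variance of the AUC difference and
#' a two-sided normal test.
#'
#' @param p_a,p_b p-values of the two pipelines, paired.
#' @param truth shared truth labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(p_a, p_b, truth) {
  keep <- !is.na(truth)
  truth <- as.logical(truth[keep])
  scores <- list(-p_a[keep], -p_b[keep])   # larger score = more positive
  m <- sum(truth); n <- sum(!truth)
  if (m == 0 || n == 0) stop("both truth classes must be present")
  place <- lapply(scores, function(s) {
    xs <- s[truth]; ys <- s[!truth]
    v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)),
                  numeric(1))
    v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)),
                  numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  })
  auc_a <- place[[1]]$auc; auc_b <- place[[2]]$auc
  s10 <- stats::cov(cbind(place[[1]]$v10, place[[2]]$v10))
  s01 <- stats::cov(cbind(place[[1]]$v01, place[[2]]$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = p)
}

#' Bootstrap test for a partial-AUC difference
#'
#' Resamples iterations with replacement, recomputes the normalised
#' pAUC of both pipelines on each resample, and refers the observed
#' difference to the bootstrap standard error with a Student-t
#' reference (df = `n_boot - 1`).
#'
#' @param p_a,p_b paired p-values.
#' @param truth truth labels.
#' @param iteration iteration id per observation (the bootstrap
#'   resampling unit); a single id degrades to resampling channels.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param fpr_max pAUC range.
#' @param seed bootstrap seed.
#' @return List: `pauc_a`, `pauc_b`, `diff`, `se_boot`, `p`.
#' @export
pauc_bootstrap_test <- function(p_a, p_b, truth, iteration = NULL,
                                n_boot = 500, fpr_max = 0.05, seed = 1) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  keep <- !is.na(truth)
  p_a <- p_a[keep]; p_b <- p_b[keep]; truth <- as.logical(truth[keep])
  iteration <- if (is.null(iteration)) seq_along(p_a) else iteration[keep]
  ids <- unique(iteration)
  pauc_of <- function(p, tr) partial_auc(roc_curve(p, tr), fpr_max)
  obs_a <- pauc_of(p_a, truth); obs_b <- pauc_of(p_b, truth)
  set.seed(as.integer(seed))
  diffs <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(lapply(sample(ids, length(ids), replace = TRUE),
                          function(id) which(iteration == id)))
    tr <- truth[take]
    if (!any(tr) || all(tr)) return(NA_real_)
    pauc_of(p_a[take], tr) - pauc_of(p_b[take], tr)
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  se <- stats::sd(diffs)
  if (!is.finite(se) || se == 0) {
    warning("degenerate bootstrap variance; p set to 1")
    return(list(pauc_a = obs_a, pauc_b = obs_b, diff = obs_a - obs_b,
                se_boot = se, p = 1))
  }
  tstat <- (obs_a - obs_b) / se
  list(pauc_a = obs_a, pauc_b = obs_b, diff = obs_a - obs_b,
       se_boot = se,
       p = 2 * stats::pt(-abs(tstat), df = length(diffs) - 1))
}

#' Type-I calibration curve
#'
#' For noise-only channels, the empirical false-positive rate at each
#' nominal threshold: `FPR(p_hat) = mean(p <= p_hat)` on a fixed grid.
#' A well-calibrated solver tracks the identity line; positive
#' deviation means overstated significance.
#'
#' @param p p-values from noise-only (truth-negative) channels; at
#'   least 100 recommended.
#' @param grid nominal thresholds.
#' @return List of class `calibration_curve`: `p_hat`, `fpr`,
#'   `max_deviation`.
#' @export
calibration_curve <- function(p, grid = seq(0.005, 1, by = 0.005)) {
  p <- p[!is.na(p)]
  fpr <- vapply(grid, function(g) mean(p <= g), numeric(1))
  structure(list(p_hat = grid, fpr = fpr,
                 max_deviation = max(abs(fpr - grid)),
                 n = length(p)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  i05 <- which.min(abs(x$p_hat - 0.05))
  cat("<calibration_curve> n=", x$n,
      "; FPR at p<0.05: ", round(100 * x$fpr[i05], 1),
      "%; max |FPR - p_hat| = ", round(x$max_deviation, 3), "\n", sep = "")
  invisible(x)
}

#' Run a benchmark grid
#'
#' Crosses the supplied pipelines over `n_iterations` simulated scans
#' each, pools the (p, truth) decisions across iterations and
#' channels, and summarises every pipeline by AUC, raw and normalised
#' pAUC, the empirical FPR at p < 0.05, and the calibration curve.
#' Per-iteration seeds are `master_seed + iteration`, so the whole
#' table is reproducible from the master seed.  Iterations that fail
#' are dropped with a count (never imputed).
#'
#' @param pipelines list of [pipeline_spec()]s.
#' @param n_iterations iterations per pipeline.
#' @param master_seed integer master seed.
#' @param geometry,noise probe and noise model shared by all
#'   pipelines.
#' @param joint include the Hotelling joint test.
#' @param chromophores which chromophores to fit per iteration.
#' @return List of class `benchmark_result`: `summary` data frame
#'   (pipeline x chromophore), `pooled` decisions, `curves`, and
#'   `n_failed`.
#' @export
run_benchmark <- function(pipelines, n_iterations = 200, master_seed = 1,
                          geometry = default_probe(), noise = noise_spec(),
                          joint = FALSE, chromophores = c("hbo", "hbr")) {
  if (inherits(pipelines, "pipeline_spec")) pipelines <- list(pipelines)
  pooled <- list()
  n_failed <- 0L
  for (pi in seq_along(pipelines)) {
    pl <- pipelines[[pi]]
    rows <- vector("list", n_iterations)
    for (it in seq_len(n_iterations)) {
      seed_it <- master_seed + it * 101L
      rows[[it]] <- tryCatch(
        run_iteration(pl, seed = seed_it, geometry = geometry,
                      noise = noise, joint = joint,
                      chromophores = chromophores),
        error = function(e) {
          warning("iteration ", it, " of pipeline ", pi, " failed: ",
                  conditionMessage(e))
          NULL
        })
    }
    n_failed <- n_failed + sum(vapply(rows, is.null, TRUE))
    df <- do.call(rbind, rows)
    df$pipeline <- pi
    pooled[[pi]] <- df
  }
  pooled <- do.call(rbind, pooled)
  labels <- vapply(pipelines, function(pl)
    paste(pl$condition, pl$prefilter, pl$solver, pl$ss_mode, sep = "/"),
    character(1))
  combos <- unique(pooled[, c("pipeline", "chromophore")])
  curves <- list()
  summ <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- pooled[pooled$pipeline == combos$pipeline[i] &
                  pooled$chromophore == combos$chromophore[i], ]
    rc <- roc_curve(sub$p, sub$truth)
    key <- paste(combos$pipeline[i], combos$chromophore[i], sep = ".")
    curves[[key]] <<- list(roc = rc,
                           calibration = calibration_curve(
                             sub$p[sub$truth == FALSE]))
    data.frame(pipeline = combos$pipeline[i],
               label = labels[combos$pipeline[i]],
               chromophore = combos$chromophore[i],
               auc = rc$auc,
               pauc_raw = partial_auc(rc, normalized = FALSE),
               pauc_norm = partial_auc(rc, normalized = TRUE),
               fpr_at_05 = mean(sub$p[sub$truth == FALSE] <= 0.05),
               n_decisions = nrow(sub))
  })
  structure(list(summary = do.call(rbind, summ), pooled = pooled,
                 curves = curves, n_failed = n_failed,
                 master_seed = master_seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> master_seed=", x$master_seed,
      if (x$n_failed) paste0(", ", x$n_failed, " failed iterations"),
      "\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
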