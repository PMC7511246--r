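#' Robust standard deviation via the median absolute deviation
#'
#' `1.4826 * median(|x - median(x)|)`: a robust estimator of the
#' standard deviation (the factor makes it consistent for the normal
#' distribution), used both for contrast-to-noise scaling of injected
#' responses and for the pooled variance update of the mixed-effects
#' solver.
#'
#' @param x numeric vector, at least 2 values.
#' @return Non-negative scalar; 0 (with a warning) for a constant
#'   series.
#' @export
robust_sigma <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  s <- 1.4826 * stats::median(abs(x - stats::median(x)))
  if (s == 0) warning("constant series: robust sigma is 0")
  s
}

#' Noise specification for the semisynthetic generator
#'
#' Describes the statistical structure of the simulated background:
#' a slowly drifting AR(1) process, cardiac / respiratory / Mayer-wave
#' oscillations with randomised phases and slowly wandering
#' amplitudes, a vasomotor response to breath-hold events, and white
#' measurement noise.  The same superficial signal drives the SS
#' channels (scaled by per-channel gains) and, attenuated through the
#' coupling parameter, the LD channels.
#'
#' All amplitudes are in the micromolar units of the HbO2 traces; the
#' Hb block is a scaled-down replica (factor `hbr_factor`) with its
#' own random phases.
#'
#' @param fs sampling rate (Hz).
#' @param duration scan length (s).
#' @param drift_phi AR(1) coefficient of the vascular drift at `fs`.
#' @param drift_sd stationary standard deviation of the drift.
#' @param cardiac,resp,mayer `c(freq_hz, amplitude)` of the three
#'   oscillations.
#' @param amp_wander depth of the slow amplitude modulation of the
#'   oscillations (0 = pure sinusoids).
#' @param ld_ss_coupling correlation between the superficial signal
#'   seen by an LD channel and the common signal seen by the SS
#'   channels, in [0, 1].
#' @param ld_gain_range,ss_gain_range uniform ranges for the
#'   per-channel mixing weights of the superficial signal.
#' @param channel_ar_phi,channel_ar_sd AR(1) coefficient and stationary
#'   sd of the channel-private coloured noise.
#' @param white_noise_sd white measurement noise sd.
#' @param bh_amplitude peak amplitude of the breath-hold vasomotor
#'   response (active only in breath-hold conditions).
#' @param hbr_factor amplitude of the Hb physiology relative to HbO2.
#' @param chromophore_coupling correlation between the HbO2 and Hb
#'   superficial signals (systemic oscillations drive both species).
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(fs = 7.8125, duration = 300,
                       drift_phi = 0.98, drift_sd = 1.0,
                       cardiac = c(1.0, 0.35), resp = c(0.25, 0.2),
                       mayer = c(0.1, 0.5), amp_wander = 0.3,
                       ld_ss_coupling = 0.85,
                       ld_gain_range = c(0.5, 1.5),
                       ss_gain_range = c(0.7, 1.3),
                       channel_ar_phi = 0.9, channel_ar_sd = 0.3,
                       white_noise_sd = 0.2,
                       bh_amplitude = 2.0, hbr_factor = 1/3,
                       chromophore_coupling = 0.8) {
  spec <- as.list(environment())
  for (osc in list(cardiac, resp, mayer)) {
    if (osc[1] <= 0 || osc[1] >= fs / 2)
      stop("oscillation frequencies must lie in (0, fs/2)")
    if (osc[2] < 0) stop("amplitudes must be non-negative")
  }
  if (ld_ss_coupling < 0 || ld_ss_coupling > 1)
    stop("ld_ss_coupling must be in [0, 1]")
  if (abs(drift_phi) >= 1 || abs(channel_ar_phi) >= 1)
    stop("AR coefficients must be inside the unit circle")
  class(spec) <- "noise_spec"
  spec
}

#' Simulation condition specification
#'
#' @param condition `"rest"`, `"bh_random"` (breath-holds present,
#'   stimuli jittered independently) or `"bh_locked"` (stimuli
#'   coincide with the holds - the worst case for systemic
#'   contamination).
#' @param cnr contrast-to-noise ratio of the injected response: peak
#'   amplitude over the robust sd ([robust_sigma()]) of the
#'   pre-injection channel, per channel and chromophore.
#' @param truth_fraction fraction of LD channels receiving a response
#'   (default one half, selected uniformly at random).
#' @param n_iterations default iteration count for benchmarks.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(condition = c("rest", "bh_random", "bh_locked"),
                            cnr = 0.7, truth_fraction = 0.5,
                            n_iterations = 200) {
  condition <- match.arg(condition)
  if (cnr < 0) stop("cnr must be non-negative")
  structure(list(condition = condition, cnr = cnr,
                 truth_fraction = truth_fraction,
                 n_iterations = n_iterations),
            class = "simulation_spec")
}

#' Stimulus and breath-hold event timings
#'
#' Generates the event structure of one simulated scan.  Breath-hold
#' (physiological) events follow the block paradigm: 25 s holds
#' separated by 30 s rest.  Stimulus events are either locked to the
#' holds (`bh_locked`), or jittered independently with inter-stimulus
#' intervals (offset-to-onset) drawn uniformly from 15 to 50 s
#' (`bh_random` and `rest`).
#'
#' @param condition simulation condition (see [simulation_spec()]).
#' @param duration scan length (s).
#' @param seed integer seed; identical seeds give identical event
#'   lists.
#' @param task_duration stimulus block length (s).
#' @param isi_range inter-stimulus-interval range (s).
#' @return List with `stim` (a [stim_design()]) and `bh_onsets`
#'   (numeric, empty for `rest`).
#' @export
make_events <- function(condition, duration, seed,
                        task_duration = 25, isi_range = c(15, 50)) {
  condition <- match.arg(condition, c("rest", "bh_random", "bh_locked"))
  if (duration < task_duration + isi_range[1])
    stop("scan too short for a single task block")
  set.seed(as.integer(seed))
  bh_onsets <- if (condition == "rest") numeric(0) else {
    on <- seq(15, duration - task_duration - 5, by = task_duration + 30)
    utils::head(on, 5)
  }
  if (condition == "bh_locked") {
    onsets <- bh_onsets
  } else {
    onsets <- numeric(0)
    t0 <- stats::runif(1, isi_range[1], isi_range[2])
    while (t0 + task_duration <= duration - 1) {
      onsets <- c(onsets, t0)
      t0 <- t0 + task_duration + stats::runif(1, isi_range[1], isi_range[2])
    }
  }
  if (length(onsets) == 0)
    stop("scan too short for a single task block")
  list(stim = stim_design(onsets, task_duration, condition),
       bh_onsets = bh_onsets)
}

## internal: one AR(1) path with given stationary sd
ar1_path <- function(n, phi, sd_stat) {
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
}

## internal: oscillation with random phase and wandering amplitude
oscillation <- function(tt, freq, amp, wander, fs) {
  phase <- stats::runif(1, 0, 2 * pi)
  env <- 1 + wander * ar1_path(length(tt), 0.995, 1)
  amp * env * sin(2 * pi * freq * tt + phase)
}

## internal: biphasic vasomotor response to one breath-hold
## (gamma difference: peak ~15 s after hold onset, ~20 s wide,
## shallow late undershoot)
bh_kernel <- function(fs, len_s = 60) {
  t <- seq(0, len_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, scale = 2.8) -
    0.35 * stats::dgamma(t, shape = 12, scale = 3)
  h / max(h)
}

## internal: one realisation of the superficial signal
superficial_signal <- function(spec, tt, bh_onsets, scale = 1) {
  g <- ar1_path(length(tt), spec$drift_phi, spec$drift_sd) +
    oscillation(tt, spec$cardiac[1], spec$cardiac[2], spec$amp_wander, spec$fs) +
    oscillation(tt, spec$resp[1], spec$resp[2], spec$amp_wander, spec$fs) +
    oscillation(tt, spec$mayer[1], spec$mayer[2], spec$amp_wander, spec$fs)
  if (length(bh_onsets)) {
    k <- bh_kernel(spec$fs)
    imp <- numeric(length(tt))
    idx <- round(bh_onsets * spec$fs) + 1
    imp[idx[idx <= length(tt)]] <- 1
    bh <- stats::convolve(imp, rev(k), type = "open")[seq_along(tt)]
    g <- g + spec$bh_amplitude * bh
  }
  g * scale
}

#' Generate a semisynthetic background scan
#'
#' Builds one noise-only scan for the default (or a supplied) probe:
#' per chromophore a shared superficial signal `g(t)` (drift +
#' oscillations + breath-hold response) drives every SS channel
#' through a per-channel gain plus white noise, while each LD channel
#' sees its own superficial realisation correlated `ld_ss_coupling`
#' with `g`, mixed with channel-private AR(1) noise and white noise.
#' Identical seeds reproduce the scan bitwise.
#'
#' @param spec a [noise_spec()].
#' @param events output of [make_events()] (or `NULL` for no
#'   breath-hold component).
#' @param seed integer seed.
#' @param geometry probe; defaults to [default_probe()].
#' @return A [hemo_scan()] (provenance `"synthetic"`) whose columns
#'   follow `geometry$channels`; the shared superficial signals are
#'   attached as attribute `"superficial"` for diagnostics.
#' @export
generate_noise_scan <- function(spec, events = NULL, seed = 1,
                                geometry = default_probe()) {
  stopifnot(inherits(spec, "noise_spec"))
  set.seed(as.integer(seed))
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  ch <- geometry$channels
  bh <- if (is.null(events)) numeric(0) else events$bh_onsets
  rho <- spec$ld_ss_coupling
  kap <- spec$chromophore_coupling
  hf <- spec$hbr_factor
  # the shared superficial signal, seen by both chromophores: the Hb
  # part is a scaled replica correlated `kap` with the HbO2 part
  s1 <- superficial_signal(spec, tt, bh)
  s2 <- superficial_signal(spec, tt, bh)
  g <- list(hbo = s1, hbr = hf * (kap * s1 + sqrt(1 - kap^2) * s2))
  # channel-private superficial component: local slow vasomotion only -
  # the oscillatory physiology (one heart, one respiratory rhythm) is
  # common to the whole probe and never duplicated per channel
  local_pair <- function() {
    l1 <- ar1_path(n, spec$drift_phi, 1)
    l2 <- ar1_path(n, spec$drift_phi, 1)
    list(hbo = l1 / stats::sd(l1) * stats::sd(g$hbo),
         hbr = (kap * l1 + sqrt(1 - kap^2) * l2) /
           stats::sd(kap * l1 + sqrt(1 - kap^2) * l2) * stats::sd(g$hbr))
  }
  hbo <- matrix(0, n, nrow(ch))
  hbr <- matrix(0, n, nrow(ch))
  ld_gain <- stats::runif(nrow(ch), spec$ld_gain_range[1],
                          spec$ld_gain_range[2])
  ss_gain <- stats::runif(nrow(ch), spec$ss_gain_range[1],
                          spec$ss_gain_range[2])
  for (j in seq_len(nrow(ch))) {
    if (ch$type[j] == "SS") {
      hbo[, j] <- ss_gain[j] * g$hbo +
        stats::rnorm(n, sd = spec$white_noise_sd)
      hbr[, j] <- ss_gain[j] * g$hbr +
        hf * stats::rnorm(n, sd = spec$white_noise_sd)
    } else {
      loc <- local_pair()
      for (cc in chromophores) {
        gj <- rho * g[[cc]] + sqrt(1 - rho^2) * loc[[cc]]
        scl <- if (cc == "hbo") 1 else hf
        tr <- ld_gain[j] * gj +
          scl * ar1_path(n, spec$channel_ar_phi, spec$channel_ar_sd) +
          scl * stats::rnorm(n, sd = spec$white_noise_sd)
        if (cc == "hbo") hbo[, j] <- tr else hbr[, j] <- tr
      }
    }
  }
  scan <- hemo_scan(hbo, hbr, fs = spec$fs, channels = ch,
                    provenance = "synthetic")
  attr(scan, "superficial") <- g
  scan
}

#' Inject canonical evoked responses at a fixed contrast-to-noise ratio
#'
#' Adds a canonical response (double-gamma HRF convolved with the
#' stimulus boxcar) to a uniformly random half of the LD channels
#' (never to SS channels).  Per channel and chromophore the response
#' is scaled so its peak equals `cnr` times the robust standard
#' deviation ([robust_sigma()]) of the pre-injection trace; HbO2
#' responses are positive, Hb responses negative.  Channels not
#' selected are returned unchanged.
#'
#' @param scan a [hemo_scan()] over the full probe.
#' @param events output of [make_events()].
#' @param cnr contrast-to-noise ratio (>= 0; 0 injects nothing but
#'   still draws truth labels).
#' @param seed integer seed for the channel selection.
#' @param truth_fraction fraction of LD channels to activate.
#' @return List: `scan` (injected), `truth` (logical per channel,
#'   `NA` for SS channels), `response` (unit-peak response shape).
#' @export
inject_response <- function(scan, events, cnr, seed,
                            truth_fraction = 0.5) {
  stopifnot(inherits(scan, "hemo_scan"))
  if (cnr < 0) stop("cnr must be non-negative")
  set.seed(as.integer(seed))
  ch <- scan$channels
  ld <- which(ch$type == "LD")
  n_pos <- floor(length(ld) * truth_fraction)
  pos <- sort(sample(ld, n_pos))
  truth <- rep(NA, nrow(ch))
  truth[ld] <- FALSE
  truth[pos] <- TRUE
  resp <- build_task_design(events$stim, nrow(scan$hbo), scan$fs)[, 1]
  hbo <- scan$hbo; hbr <- scan$hbr
  if (cnr > 0) {
    for (j in pos) {
      hbo[, j] <- hbo[, j] + cnr * robust_sigma(scan$hbo[, j]) * resp
      hbr[, j] <- hbr[, j] - cnr * robust_sigma(scan$hbr[, j]) * resp
    }
  }
  out <- hemo_scan(hbo, hbr, fs = scan$fs, channels = ch,
                   provenance = scan$provenance)
  attr(out, "superficial") <- attr(scan, "superficial")
  list(scan = out, truth = truth, response = resp)
}
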