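# Shared fixtures, built in code.

# small 2-source / 2-detector probe: one 30 mm LD and one 7 mm SS channel
tiny_probe <- function() {
  probe_geometry(
    sources = rbind(c(0, 0), c(50, 0)),
    detectors = rbind(c(30, 0), c(50, 7)),
    channels = data.frame(source = c(1, 2), detector = c(1, 2)))
}

# short synthetic hemo scan with k channels of white noise
white_scan <- function(n = 200, k = 4, fs = 7.8125, sd = 1, seed = 1) {
  set.seed(seed)
  hemo_scan(matrix(rnorm(n * k, sd = sd), n, k),
            matrix(rnorm(n * k, sd = sd), n, k),
            fs = fs, provenance = "synthetic")
}

# fast noise spec for tests: shorter scans, same structure
quick_noise <- function(duration = 120, ...) {
  noise_spec(duration = duration, ...)
}

# quick stimulus design covering an n-sample scan
quick_stim <- function(n = 200, fs = 7.8125) {
  stim_design(onsets = c(2, 12), durations = 5)
}
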