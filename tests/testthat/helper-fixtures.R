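# shared fixtures and independent mini-oracles

# small synthetic world for fast unit tests
tiny_config <- function(seed = 1L, ...) {
  synth_config(n_channels = 6L, trials_per_finger = 4L,
               signal_channels = 2:4, seed = seed, ...)
}

# moderate world used by the heavier property tests
small_config <- function(seed = 1L, ...) {
  synth_config(n_channels = 12L, trials_per_finger = 12L,
               signal_channels = 4:9, seed = seed, ...)
}

# amplitude of a sinusoid at frequency f in x, via the FFT bin (f must sit
# on the grid fs/n * k)
fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs)
  2 * Mod(fft(x)[k + 1]) / n
}

# brute-force movement-peak scan honoring all four detection criteria;
# independent of the package implementation
oracle_detect <- function(trace_abs, fs, cue_on, cue_end, thr = 200,
                          latency = 0.4, tail = 0.5, merge = 0.4) {
  i0 <- ceiling((cue_on + latency) * fs) + 1
  i1 <- floor((cue_end - tail) * fs) + 1
  cand <- integer(0)
  for (i in (i0 + 1):(i1 - 1)) {
    if (trace_abs[i] >= thr && trace_abs[i] > trace_abs[i - 1] &&
        trace_abs[i] >= trace_abs[i + 1] && trace_abs[i] != trace_abs[i - 1])
      cand <- c(cand, i)
  }
  times <- (cand - 1) / fs
  amps <- trace_abs[cand]
  keep <- logical(length(cand))
  for (j in order(-amps, times)) {
    if (!any(keep & abs(times - times[j]) < merge)) keep[j] <- TRUE
  }
  sort(times[keep])
}

# generate, preprocess and epoch a dataset end to end (shared by spectral /
# decode / acceptance tests); memoized per config hash within a session
run_frontend <- local({
  cache <- new.env()
  function(cf) {
    key <- paste(cf$seed, cf$n_channels, cf$trials_per_finger,
                 paste(cf$broadband_gain, collapse = "_"), cf$erd_depth,
                 sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    ds <- generate_dataset(cf)
    rec <- common_average_reference(notch(highpass(ds$recording)))
    ev <- fingerbci:::detect_all_fingers(ds$kinematics, cf$fs, ds$trials,
                                         detector_params())
    eps <- extract_epochs(rec, ev, ds$trials)
    out <- list(dataset = ds, recording = rec, events = ev,
                movement = psd_hanning(eps$movement),
                rest = psd_hanning(eps$rest))
    cache[[key]] <- out
    out
  }
})

# the 20-point two-class fixture used for the frozen classifier oracle
# (expected values computed with scikit-learn 1.9.0 SVC, tol = 1e-6)
svm_fixture <- function() {
  x1 <- c(1.4967, 1.6477, 0.7658, 2.5792, 0.5305, 0.5366, 1.242, -0.7249,
          -0.0128, 0.092, 1.4656, 0.0675, -0.5444, -1.151, -0.6006, -0.6017,
          -0.0135, 0.8225, 0.2089, -1.3282)
  x2 <- c(0.8617, 2.523, 0.7659, 1.7674, 1.5426, 0.5343, -0.9133, 0.4377,
          1.3142, -0.4123, -0.2258, -1.4247, 0.1109, 0.3757, -0.2917, 1.8523,
          -1.0577, -1.2208, -1.9597, 0.1969)
  list(x = cbind(x1, x2), y = c(rep(1L, 10), rep(-1L, 10)),
       xtest = rbind(c(0, 0), c(1, 1), c(2, 2), c(-1, -1), c(0.5, 1.5),
                     c(1.5, 0.5), c(-2, 2), c(2, -2), c(0, 1)))
}
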