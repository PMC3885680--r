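#' Synthetic-dataset configuration
#'
#' Parameters of the generator that emulates the statistical structure the
#' decoding pipeline assumes: a blank/fixation/cue trial protocol (2 s each),
#' Gaussian 1/f background, alpha and beta rhythms that desynchronize during
#' movement, a finger-specific multiplicative broadband power increase on a
#' contiguous "centro-parietal" channel subset, and ~1 Hz kinematic flexion
#' peaks during cues.
#'
#' @param n_channels number of EEG channels.
#' @param fs sampling rate, 250 or 1000 Hz.
#' @param trials_per_finger trials per finger (the protocol used 60 or 80).
#' @param fingers ordered finger labels.
#' @param background_exponent 1/f^exponent slope of the background.
#' @param alpha_band,beta_band rhythm bands in Hz.
#' @param erd_depth fractional rhythm power reduction during movement, in
#'   \[0, 1\] (scaled by the per-finger spatial profile on signal channels).
#' @param broadband_gain multiplicative PSD factor >= 1 during movement on
#'   signal channels; the per-channel factor is `1 + (gain - 1) * w` with a
#'   finger-specific spatial profile `w` normalized to unit mean over the
#'   signal channels, so the mean PSD ratio across signal channels equals
#'   `broadband_gain`.
#' @param signal_channels index set of the planted signal channels
#'   (default: a contiguous block of 10 centered in the montage).
#' @param rhythm_snr ratio of rhythm PSD to background PSD at the band
#'   centers on all channels.
#' @param rhythm_variability log-amplitude standard deviation of the slow
#'   (~5 s timescale) spontaneous waxing and waning of the alpha and beta
#'   rhythms, independent per band and channel; this epoch-scale variance is
#'   what lets the PCA decouple the rhythm structure from the movement
#'   contrast, as in real recordings.
#' @param background_variability log-amplitude standard deviation of a slow
#'   per-channel gain drift (electrode-impedance / arousal non-stationarity).
#'   It modulates each channel's whole background spectrum coherently across
#'   frequency, creating the large flat variance direction that the first
#'   principal component locks onto in real data; independent draws per
#'   channel keep it from masquerading as a spatial pattern.
#' @param peak_amplitude_uv kinematic peak amplitude.
#' @param peaks_per_cue flexion peaks per cue window.
#' @param blank_s,fix_s,cue_s protocol window durations in seconds.
#' @param line_amp_uv amplitude of the additive 60 Hz line component.
#' @param seed integer seed; the same config and seed regenerate the dataset
#'   bit-identically.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 64L, fs = 250,
                         trials_per_finger = 60L,
                         fingers = c("thumb", "index", "middle", "ring",
                                     "little"),
                         background_exponent = 1,
                         alpha_band = c(8, 12), beta_band = c(13, 30),
                         erd_depth = 0.5, broadband_gain = 2,
                         signal_channels = NULL, rhythm_snr = 4,
                         rhythm_variability = 0.5,
                         background_variability = 0.35,
                         peak_amplitude_uv = 300, peaks_per_cue = 2L,
                         blank_s = 2, fix_s = 2, cue_s = 2,
                         line_amp_uv = 1, seed = 1L) {
  if (!fs %in% c(250, 1000)) stop("fs must be 250 or 1000 Hz")
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must lie in [0, 1]")
  if (any(broadband_gain < 1)) stop("broadband_gain must be >= 1")
  if (alpha_band[2] >= beta_band[1] || beta_band[2] >= fs / 2 ||
      alpha_band[1] <= 0)
    stop("alpha and beta bands must be disjoint and within (0, fs/2)")
  if (is.null(signal_channels)) {
    c0 <- n_channels %/% 2L - 4L
    signal_channels <- c0:(c0 + 9L)
  }
  if (any(signal_channels < 1L) || any(signal_channels > n_channels))
    stop("signal_channels out of range")
  if (length(broadband_gain) == 1L)
    broadband_gain <- rep(broadband_gain, length(fingers))
  if (length(broadband_gain) != length(fingers))
    stop("broadband_gain must be scalar or one value per finger")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 trials_per_finger = as.integer(trials_per_finger),
                 fingers = fingers,
                 background_exponent = background_exponent,
                 alpha_band = alpha_band, beta_band = beta_band,
                 erd_depth = erd_depth, broadband_gain = broadband_gain,
                 signal_channels = as.integer(signal_channels),
                 rhythm_snr = rhythm_snr,
                 rhythm_variability = rhythm_variability,
                 background_variability = background_variability,
                 peak_amplitude_uv = peak_amplitude_uv,
                 peaks_per_cue = as.integer(peaks_per_cue),
                 blank_s = blank_s, fix_s = fix_s, cue_s = cue_s,
                 line_amp_uv = line_amp_uv, seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian noise with a prescribed one-sided amplitude-spectral shape,
# via frequency-domain shaping of white noise. `shape(f)` is evaluated on
# the FFT grid (f in Hz, f > 0); DC is zeroed.
shaped_noise <- function(n, fs, shape) {
  w <- fft(rnorm(n))
  f <- seq(0, n - 1) / n * fs
  f2 <- pmin(f, fs - f)            # fold to [0, fs/2]
  g <- shape(pmax(f2, 1e-12))
  g[1] <- 0
  Re(fft(w * g, inverse = TRUE)) / n
}

# lognormal amplitude envelope (spontaneous waxing/waning), unit mean
# square. The correlation time (~1/(pi*cutoff), default ~0.6 s) is kept
# shorter than the ~1 s spacing of successive movements so that two epochs
# from the same trial share no envelope state: without that, a classifier
# can match a test epoch to its same-trial twin in the training folds and
# null decoding drifts above chance (the generator's null-soundness
# contract).
slow_envelope <- function(n, fs, sigma, cutoff = 0.55) {
  if (sigma <= 0) return(rep(1, n))
  z <- shaped_noise(n, fs, function(f) exp(-f^2 / (2 * cutoff^2)))
  z <- z / sd(z)
  exp(sigma * z - sigma^2)
}

# smooth unimodal spatial profile over the signal channels for one finger:
# a broad common pedestal plus a finger-specific bump whose center shifts by
# two channels per finger; normalized to unit mean over the signal channels
finger_profile <- function(n_signal, finger_idx, n_fingers, sigma = 3,
                           spacing = 2) {
  center <- (n_signal + 1) / 2 + spacing * (finger_idx - (n_fingers + 1) / 2)
  w <- 0.5 + exp(-((seq_len(n_signal) - center)^2) / (2 * sigma^2))
  w / mean(w)
}

#' Synthesize one kinematic trace from event times
#'
#' Each event contributes one ~1 Hz flexion pulse (a Hann-windowed single
#' 1 Hz cycle) whose dominant extremum falls at the event time. Successive
#' pulses alternate polarity, as the potential difference on a bipolar
#' sensor pair does over a flexion-extension sequence; this also makes the
#' negative lobes of neighbouring pulses cancel rather than add, so the
#' detector sees exactly one supra-threshold extremum per event. The pulse
#' is scaled so that its amplitude *after* the detector's 0.5-2 Hz band-pass
#' equals `peak_amplitude_uv` (the raw extremum is correspondingly larger),
#' and its energy is concentrated in 0.5-2 Hz. The trace is zero outside
#' events (noise is added by the dataset generator, not here).
#'
#' @param event_times strictly increasing event times in seconds.
#' @param n_samples trace length in samples.
#' @param fs sampling rate in Hz.
#' @param peak_amplitude_uv band-passed pulse peak amplitude.
#' @param width_s pulse support in seconds.
#' @return numeric trace of length `n_samples`.
#' @export
synth_kinematic_trace <- function(event_times, n_samples, fs,
                                  peak_amplitude_uv = 300, width_s = 1) {
  if (length(event_times) > 1L) {
    d <- diff(event_times)
    if (any(d <= 0)) stop("event times must be strictly increasing")
    if (any(d < 0.2)) stop("events closer than 200 ms violate detector assumptions")
  }
  x <- numeric(n_samples)
  tpl <- kinematic_pulse_template(fs, width_s)
  halfn <- (length(tpl) - 1L) %/% 2L
  sign <- 1
  for (t0 in event_times) {
    ic <- round(t0 * fs)              # 0-based center sample
    i0 <- ic - halfn; i1 <- ic + halfn
    j0 <- max(0L, i0); j1 <- min(n_samples - 1L, i1)
    if (j1 >= j0)
      x[(j0:j1) + 1L] <- x[(j0:j1) + 1L] +
        sign * peak_amplitude_uv * tpl[(j0:j1) - i0 + 1L]
    sign <- -sign
  }
  x
}

# single-cycle 1 Hz pulse on a +/- 2 s grid, normalized to unit amplitude
# after the 0.5-2 Hz detector band-pass (memoized per fs/width)
kinematic_pulse_template <- local({
  cache <- list()
  function(fs, width_s) {
    key <- sprintf("%g_%g", fs, width_s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    half <- width_s / 2
    n <- round(4 * fs) + 1L
    tt <- (seq_len(n) - 1 - (n - 1) / 2) / fs
    w <- ifelse(abs(tt) <= half, 0.5 * (1 + cos(pi * tt / half)), 0)
    p <- w * cos(2 * pi * 1 * tt)
    f <- butter_filter(2L, c(0.5, 2), fs, "pass")
    pf <- filtfilt_zero_phase(f$b, f$a, p, padlen = n - 1L)
    p <- p / max(abs(pf))
    cache[[key]] <<- p
    p
  }
})

#' Generate a synthetic finger-movement dataset
#'
#' Produces a continuous multichannel recording, one kinematic trace per
#' finger, the trial table, and the planted ground truth. During each cue
#' the background (broadband) component on the signal channels is scaled in
#' amplitude by `sqrt(1 + (gain - 1) w)` (so PSD scales multiplicatively)
#' and the alpha/beta oscillators are attenuated by
#' `sqrt(1 - min(1, erd_depth * w))`, where `w` is the cued finger's spatial
#' profile. Flexion peaks are planted inside each cue with uniform jitter,
#' >= 450 ms after cue onset, >= 500 ms apart and clear of the final 500 ms.
#'
#' @param config a [synth_config()].
#' @return list with elements `recording` ([recording()]), `kinematics`
#'   (matrix fingers x time, uV), `trials` ([trial_table()]), and
#'   `ground_truth` (events [event_set()], spectral templates, spatial
#'   weights).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  n_f <- length(cf$fingers)
  n_trials <- cf$trials_per_finger * n_f
  trial_s <- cf$blank_s + cf$fix_s + cf$cue_s
  n <- round(n_trials * trial_s * cf$fs)

  # peak layout feasibility inside the cue: first peak 0.42-0.47 s after
  # onset, repeats ~1 s apart (in phase at the ~1 Hz movement rate), nothing
  # in the final 500 ms
  first_lo <- 0.42; first_jit <- 0.05; gap_lo <- 0.93; gap_jit <- 0.09
  need <- first_lo + first_jit + (cf$peaks_per_cue - 1) * (gap_lo + gap_jit)
  if (need > cf$cue_s - 0.5 - 0.01)
    stop(sprintf("cue of %g s cannot hold %d peaks with the required layout",
                 cf$cue_s, cf$peaks_per_cue))

  finger_seq <- sample(rep(cf$fingers, cf$trials_per_finger))
  trials <- trial_table(cue_onset = (seq_len(n_trials) - 1) * trial_s +
                          cf$blank_s + cf$fix_s,
                        finger = finger_seq, blank_s = cf$blank_s,
                        fix_s = cf$fix_s, cue_s = cf$cue_s)

  # planted events
  ev_time <- numeric(0); ev_fing <- character(0); ev_trial <- integer(0)
  for (i in seq_len(n_trials)) {
    t0 <- trials$cue_onset[i] + first_lo + runif(1, 0, first_jit)
    ts <- t0
    if (cf$peaks_per_cue > 1L)
      for (k in 2:cf$peaks_per_cue)
        ts <- c(ts, ts[k - 1] + gap_lo + runif(1, 0, gap_jit))
    ev_time <- c(ev_time, ts)
    ev_fing <- c(ev_fing, rep(trials$finger[i], length(ts)))
    ev_trial <- c(ev_trial, rep(i, length(ts)))
  }
  truth_events <- event_set(ev_time, ev_fing, ev_trial,
                            cf$peak_amplitude_uv, "ground_truth")

  # spatial weights (fingers x n_channels), nonzero on signal channels only
  n_sig <- length(cf$signal_channels)
  W <- matrix(0, n_f, cf$n_channels, dimnames = list(cf$fingers, NULL))
  for (k in seq_len(n_f))
    W[k, cf$signal_channels] <- finger_profile(n_sig, k, n_f)

  # per-sample cue envelope value: index of cued finger or 0
  cue_idx <- integer(n)
  tvec <- (seq_len(n) - 1) / cf$fs
  for (i in seq_len(n_trials)) {
    sel <- tvec >= trials$cue_onset[i] & tvec < trials$cue_end[i]
    cue_idx[sel] <- match(trials$finger[i], cf$fingers)
  }

  bg_amp <- 10  # background scale, uV RMS order of magnitude
  a0 <- mean(cf$alpha_band); b0 <- mean(cf$beta_band)
  bg_shape <- function(f) f^(-cf$background_exponent / 2)
  al_shape <- function(f) sqrt(cf$rhythm_snr) * bg_shape(a0) *
    exp(-(f - a0)^2 / (2 * 1.5^2))
  be_shape <- function(f) sqrt(cf$rhythm_snr) * bg_shape(b0) *
    exp(-(f - b0)^2 / (2 * 4^2))

  X <- matrix(0, cf$n_channels, n)
  in_cue <- cue_idx > 0L
  # recording-wide gain fluctuation: coherent across channels (so decoding
  # can cancel it as common mode) and across frequency (so each channel's
  # PCA sees a flat variance direction)
  genv <- slow_envelope(n, cf$fs, cf$background_variability)
  for (ch in seq_len(cf$n_channels)) {
    bg <- shaped_noise(n, cf$fs, bg_shape)
    scale_f <- bg_amp / sd(bg)   # common scale keeps rhythm/background PSD ratio
    bg <- bg * scale_f * genv
    al <- shaped_noise(n, cf$fs, al_shape) * scale_f * slow_envelope(n, cf$fs, cf$rhythm_variability)
    be <- shaped_noise(n, cf$fs, be_shape) * scale_f * slow_envelope(n, cf$fs, cf$rhythm_variability)
    env_bb <- rep(1, n); env_rh <- rep(1, n)
    if (ch %in% cf$signal_channels) {
      wch <- W[, ch]
      g <- 1 + (cf$broadband_gain - 1) * wch        # per finger
      e <- pmin(1, cf$erd_depth * wch)
      env_bb[in_cue] <- sqrt(g[cue_idx[in_cue]])
      env_rh[in_cue] <- sqrt(1 - e[cue_idx[in_cue]])
    }
    X[ch, ] <- bg * env_bb + (al + be) * env_rh +
      cf$line_amp_uv * sin(2 * pi * 60 * tvec + ch)
  }

  # kinematic traces: pulses for own-finger events plus low-level noise
  Kin <- matrix(0, n_f, n, dimnames = list(cf$fingers, NULL))
  for (k in seq_len(n_f)) {
    own <- truth_events$events$finger == cf$fingers[k]
    Kin[k, ] <- synth_kinematic_trace(truth_events$events$time[own], n,
                                      cf$fs, cf$peak_amplitude_uv) +
      rnorm(n, sd = 5)
  }

  f_max <- min(125, cf$fs / 2)
  grid <- seq_len(f_max)
  bb_t <- rep(1, f_max); bb_t <- bb_t / sqrt(sum(bb_t^2))
  rh_t <- exp(-(grid - a0)^2 / (2 * 1.5^2)) + exp(-(grid - b0)^2 / (2 * 4^2))
  rh_t <- rh_t / sqrt(sum(rh_t^2))

  list(recording = recording(X, cf$fs),
       kinematics = Kin,
       trials = trials,
       ground_truth = list(events = truth_events,
                           broadband_template = bb_t,
                           rhythm_template = rh_t,
                           freqs = grid,
                           spatial_weights = W,
                           config = cf))
}
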