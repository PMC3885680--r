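#' Movement-peak detector parameters
#'
#' Detection criteria for individual finger-flexion peaks from bipolar
#' sensor traces (EEG protocol) or data-glove positions: the trace is
#' band-passed to the ~1 Hz kinematic band, peaks must exceed an amplitude
#' threshold (200 uV for bipolar sensors, 2 glove units), occur at least
#' 400 ms after cue onset, not fall in the last 500 ms of the cue, be at
#' least 200 ms apart, and when several candidates fall within a 400 ms
#' window only the strongest is kept.
#'
#' @param band kinematic band-pass in Hz.
#' @param amp_threshold peak amplitude threshold (uV or glove units).
#' @param min_latency_ms minimum peak latency after cue onset.
#' @param tail_exclusion_ms exclusion zone at the end of each cue.
#' @param min_separation_ms minimum distance between retained peaks.
#' @param merge_window_ms window within which only the strongest peak is kept.
#' @return list of class `detector_params`.
#' @export
detector_params <- function(band = c(0.5, 2), amp_threshold = 200,
                            min_latency_ms = 400, tail_exclusion_ms = 500,
                            min_separation_ms = 200, merge_window_ms = 400) {
  stopifnot(length(band) == 2L, all(band > 0), band[1] < band[2],
            amp_threshold > 0, min_latency_ms > 0, tail_exclusion_ms > 0,
            min_separation_ms > 0, merge_window_ms > 0)
  structure(list(band = band, amp_threshold = amp_threshold,
                 min_latency_ms = min_latency_ms,
                 tail_exclusion_ms = tail_exclusion_ms,
                 min_separation_ms = min_separation_ms,
                 merge_window_ms = merge_window_ms),
            class = "detector_params")
}

#' Detected-event container
#'
#' @param time event times in seconds.
#' @param finger finger label per event.
#' @param trial trial index per event (NA for glove events without trials).
#' @param amplitude peak amplitude per event.
#' @param provenance `"bipolar"`, `"glove"` or `"ground_truth"`.
#' @return object of class `event_set` with a data.frame `$events`.
#' @export
event_set <- function(time, finger, trial = NA_integer_, amplitude = NA_real_,
                      provenance = c("bipolar", "glove", "ground_truth")) {
  provenance <- match.arg(provenance)
  n <- length(time)
  ev <- data.frame(time = as.numeric(time), finger = as.character(finger),
                   trial = rep_len(as.integer(trial), n),
                   amplitude = rep_len(as.numeric(amplitude), n),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, provenance = provenance), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events (%s)\n", nrow(x$events), x$provenance))
  if (nrow(x$events))
    print(table(x$events$finger))
  invisible(x)
}

#' Write / read events as tab-separated text
#' @param ev an [event_set()].
#' @param path file path.
#' @return `read_event_set` returns an [event_set()].
#' @export
write_event_set <- function(ev, path) {
  write.table(ev$events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_set
#' @export
read_event_set <- function(path, provenance = "bipolar") {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  event_set(d$time, d$finger, d$trial, d$amplitude, provenance)
}

#' Band-pass a kinematic trace to the ~1 Hz flexion band
#'
#' Zero-phase Butterworth band-pass (default 0.5-2 Hz) capturing the
#' dominant ~1 Hz flexion-extension kinematics and removing DC offsets.
#'
#' @param trace numeric vector (uV or glove units).
#' @param fs sampling rate in Hz.
#' @param band length-2 band in Hz.
#' @param order low-pass prototype order (band-pass order is twice this).
#' @return filtered trace.
#' @export
bandpass_kinematic <- function(trace, fs, band = c(0.5, 2), order = 2L) {
  if (fs <= 2 * band[2]) stop("fs must exceed twice the band upper edge")
  f <- butter_filter(order, band, fs, "pass")
  filtfilt_zero_phase(f$b, f$a, trace,
                      padlen = min(ceiling(3 * fs / band[1]),
                                   length(trace) - 1L))
}

# local maxima of v (plateau-aware: a run of equal values rising before and
# falling after yields its midpoint); returns indices
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    rising <- i > 1L && r$values[i - 1L] < r$values[i]
    falling <- i < k && r$values[i + 1L] < r$values[i]
    if (rising && falling)
      out <- c(out, (starts[i] + ends[i]) %/% 2L)
  }
  out
}

# greedy strongest-first retention: candidates closer than `min_gap_s` to an
# already-kept stronger peak are discarded; ties keep the earlier peak
prune_peaks <- function(times, amps, min_gap_s) {
  keep <- logical(length(times))
  ord <- order(-amps, times)  # strongest first, earlier first on ties
  for (i in ord) {
    if (!any(keep & abs(times - times[i]) < min_gap_s)) keep[i] <- TRUE
  }
  which(keep)
}

#' Detect finger-movement peaks in a band-passed bipolar trace
#'
#' Scans each trial's cue window for local maxima of the absolute value of
#' the (already band-passed) trace and applies the four detection criteria
#' of [detector_params()]. Events inherit the cued finger label of their
#' trial.
#'
#' @param trace band-passed kinematic trace (see [bandpass_kinematic()]).
#' @param fs sampling rate in Hz.
#' @param trials a [trial_table()].
#' @param params a [detector_params()].
#' @param finger if given, only trials cuing this finger are scanned (the
#'   trace belongs to one finger's sensor pair).
#' @param exclude_trials optional integer vector of trials to skip (e.g.
#'   video-reviewed wrong-movement trials).
#' @return an [event_set()] with provenance `"bipolar"`.
#' @export
detect_peaks <- function(trace, fs, trials, params = detector_params(),
                         finger = NULL, exclude_trials = integer(0)) {
  stopifnot(inherits(trials, "trial_table"))
  if (nrow(trials) == 0L) stop("empty trial table")
  av <- abs(trace)
  times <- numeric(0); fing <- character(0); tri <- integer(0)
  amp <- numeric(0)
  rows <- seq_len(nrow(trials))
  if (!is.null(finger)) rows <- rows[trials$finger[rows] == finger]
  rows <- setdiff(rows, exclude_trials)
  for (i in rows) {
    lo <- trials$cue_onset[i] + params$min_latency_ms / 1000
    hi <- trials$cue_end[i] - params$tail_exclusion_ms / 1000
    i0 <- ceiling(lo * fs) + 1L       # 1-based sample of first valid time
    i1 <- floor(hi * fs) + 1L
    if (i1 <= i0) next
    seg <- av[i0:i1]
    cand <- local_maxima(seg)
    cand <- cand[seg[cand] >= params$amp_threshold]
    if (!length(cand)) next
    ct <- (i0 - 1L + cand - 1L) / fs  # back to seconds (0-based samples)
    gap <- max(params$min_separation_ms, params$merge_window_ms) / 1000
    sel <- prune_peaks(ct, seg[cand], gap)
    times <- c(times, ct[sel])
    fing <- c(fing, rep(trials$finger[i], length(sel)))
    tri <- c(tri, rep(trials$trial[i], length(sel)))
    amp <- c(amp, seg[cand][sel])
  }
  event_set(times, fing, tri, amp, provenance = "bipolar")
}

#' Detect movement peaks in a data-glove position trace
#'
#' Glove variant of the detector: peaks are local maxima of the raw position
#' trace above the glove threshold (default 2 on the [-5, 10] glove scale),
#' at least `min_separation_ms` apart, with the strongest peak kept when
#' several fall within the merge window. A trace that never crosses the
#' threshold yields an empty event set.
#'
#' @param trace glove position trace.
#' @param fs sampling rate in Hz.
#' @param params a [detector_params()] (use `amp_threshold = 2`).
#' @param finger finger label attached to detected events.
#' @return an [event_set()] with provenance `"glove"`.
#' @export
detect_peaks_glove <- function(trace, fs,
                               params = detector_params(amp_threshold = 2),
                               finger = "unknown") {
  cand <- local_maxima(trace)
  cand <- cand[trace[cand] >= params$amp_threshold]
  if (!length(cand))
    return(event_set(numeric(0), character(0), provenance = "glove"))
  ct <- (cand - 1L) / fs
  gap <- max(params$min_separation_ms, params$merge_window_ms) / 1000
  sel <- prune_peaks(ct, trace[cand], gap)
  event_set(ct[sel], rep(finger, length(sel)), NA_integer_,
            trace[cand][sel], provenance = "glove")
}
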