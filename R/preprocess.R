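#' Common average re-referencing
#'
#' Subtracts, at every sample, the instantaneous mean across all channels:
#' `V'_n(t) = V_n(t) - (1/N) sum_k V_k(t)`. Re-referencing an already
#' CAR-referenced recording is refused explicitly.
#'
#' @param rec a [recording()] with `reference == "original"`.
#' @return a [recording()] with `reference == "CAR"`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$reference == "CAR")
    stop("recording is already common-average referenced")
  if (nrow(rec$samples) < 2L)
    stop("common average reference requires at least 2 channels")
  out <- sweep(rec$samples, 2L, colMeans(rec$samples))
  recording(out, rec$fs, rec$labels, reference = "CAR")
}

#' Trial table constructor
#'
#' One row per trial with the onsets (seconds) of the blank, fixation and cue
#' windows and the cued finger label. Durations default to the 2 s / 2 s / 2 s
#' protocol.
#'
#' @param cue_onset numeric vector of cue onsets in seconds.
#' @param finger character/factor of cued finger labels, same length.
#' @param blank_s,fix_s,cue_s window durations in seconds.
#' @return a `data.frame` of class `trial_table` with columns `trial`,
#'   `blank_onset`, `fix_onset`, `cue_onset`, `cue_end`, `finger`.
#' @export
trial_table <- function(cue_onset, finger, blank_s = 2, fix_s = 2, cue_s = 2) {
  if (length(cue_onset) != length(finger))
    stop("`cue_onset` and `finger` lengths differ")
  if (length(cue_onset) == 0L) stop("empty trial table")
  o <- order(cue_onset)
  cue_onset <- cue_onset[o]; finger <- as.character(finger)[o]
  tt <- data.frame(trial = seq_along(cue_onset),
                   blank_onset = cue_onset - fix_s - blank_s,
                   fix_onset = cue_onset - fix_s,
                   cue_onset = cue_onset,
                   cue_end = cue_onset + cue_s,
                   finger = finger,
                   stringsAsFactors = FALSE)
  if (nrow(tt) > 1L && any(diff(tt$cue_onset) < cue_s))
    stop("overlapping trials in trial table")
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Read / write a trial table as tab-separated text
#' @param tt a [trial_table()].
#' @param path file path.
#' @return `read_trial_table` returns a [trial_table()].
#' @export
write_trial_table <- function(tt, path) {
  write.table(as.data.frame(tt), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  trial_table(d$cue_onset, d$finger,
              blank_s = d$fix_onset[1] - d$blank_onset[1],
              fix_s = d$cue_onset[1] - d$fix_onset[1],
              cue_s = d$cue_end[1] - d$cue_onset[1])
}

#' Epoch set container
#'
#' @param epochs numeric array, epoch x channel x time.
#' @param fs sampling rate (Hz).
#' @param condition `"movement"` or `"rest"`.
#' @param finger finger label per epoch.
#' @param centers center time (s) per epoch.
#' @param trial trial index per epoch.
#' @param labels channel labels.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, condition = c("movement", "rest"),
                      finger = character(0), centers = numeric(0),
                      trial = integer(0), labels = NULL) {
  condition <- match.arg(condition)
  stopifnot(length(dim(epochs)) == 3L)
  n <- dim(epochs)[1]
  stopifnot(length(finger) == n, length(centers) == n)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(dim(epochs)[2]))
  structure(list(epochs = epochs, fs = fs, condition = condition,
                 finger = as.character(finger), centers = centers,
                 trial = as.integer(trial), labels = labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d %s epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$epochs)[1], x$condition, dim(x$epochs)[2],
              dim(x$epochs)[3], x$fs))
  invisible(x)
}

# half-open 0-based sample window [i0 - w/2, i0 + w/2) around time t
epoch_sample_window <- function(t, fs, window_s) {
  i0 <- round(t * fs)
  w <- round(window_s * fs)
  c(i0 - w %/% 2L, i0 + w %/% 2L + w %% 2L)  # [start, end), 0-based
}

#' Extract movement and rest epochs
#'
#' Cuts fixed-length windows (default 1 s) from a recording: one movement
#' epoch per detected movement peak (centered at the peak) and one rest epoch
#' per trial (centered at the middle of the fixation window), labeled by the
#' finger moved in that trial. Windows use 0-based half-open sample indexing
#' `[center - T*fs/2, center + T*fs/2)`. Events whose window would cross a
#' recording edge are dropped with a warning.
#'
#' @param rec a [recording()].
#' @param events an [event_set()] of detected movement peaks.
#' @param trials a [trial_table()].
#' @param window_s epoch length in seconds.
#' @return list with elements `movement` and `rest`, both [epoch_set()]s.
#' @export
extract_epochs <- function(rec, events, trials, window_s = 1) {
  stopifnot(inherits(rec, "recording"), inherits(trials, "trial_table"))
  ns <- ncol(rec$samples)
  cut1 <- function(t) {
    w <- epoch_sample_window(t, rec$fs, window_s)
    if (w[1] < 0 || w[2] > ns) return(NULL)
    rec$samples[, (w[1] + 1L):w[2], drop = FALSE]
  }
  wlen <- round(window_s * rec$fs)

  ev <- if (is.null(events) || nrow(events$events) == 0L) {
    data.frame(time = numeric(0), finger = character(0), trial = integer(0))
  } else events$events
  mov <- array(0, c(nrow(ev), nrow(rec$samples), wlen))
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    x <- cut1(ev$time[i])
    if (is.null(x)) next
    mov[i, , ] <- x
    keep[i] <- TRUE
  }
  if (any(!keep))
    warning(sprintf("%d movement event(s) too close to recording edge; dropped",
                    sum(!keep)))
  movement <- epoch_set(mov[keep, , , drop = FALSE], rec$fs, "movement",
                        finger = ev$finger[keep], centers = ev$time[keep],
                        trial = ev$trial[keep], labels = rec$labels)

  rc <- (trials$fix_onset + trials$cue_onset) / 2  # fixation midpoint
  rest <- array(0, c(nrow(trials), nrow(rec$samples), wlen))
  rkeep <- logical(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    x <- cut1(rc[i])
    if (is.null(x)) next
    rest[i, , ] <- x
    rkeep[i] <- TRUE
  }
  if (any(!rkeep))
    warning(sprintf("%d rest window(s) outside the recording; dropped",
                    sum(!rkeep)))
  rest <- epoch_set(rest[rkeep, , , drop = FALSE], rec$fs, "rest",
                    finger = trials$finger[rkeep], centers = rc[rkeep],
                    trial = trials$trial[rkeep], labels = rec$labels)
  list(movement = movement, rest = rest)
}
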