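#' Per-epoch power spectral densities with a 1 s Hanning window
#'
#' Computes, for every epoch and channel, the magnitude-squared Hanning-
#' windowed Fourier coefficients at integer frequencies `1..f_max` Hz. With
#' the 1 s window length the native resolution is 1 Hz and the DC bin is
#' excluded (meaningless after high-pass filtering).
#'
#' @param eps an [epoch_set()] with 1 s epochs.
#' @param f_max upper bound frequency in Hz (125 for scalp EEG at 250 Hz or
#'   more, 200 for the 1000 Hz subdural recordings); capped by `fs/2`.
#' @return object of class `spectrum_set`: `psd` array (epoch x channel x
#'   frequency), `freqs`, `fs`, plus the epoch bookkeeping (`condition`,
#'   `finger`, `centers`, `trial`, `labels`).
#' @export
psd_hanning <- function(eps, f_max = NULL) {
  stopifnot(inherits(eps, "epoch_set"))
  nt <- dim(eps$epochs)[3]
  if (nt != round(eps$fs))
    stop("epochs must be exactly one second long")
  if (is.null(f_max)) f_max <- min(125, eps$fs / 2)
  if (f_max > eps$fs / 2) stop("f_max must not exceed fs/2")
  n_ep <- dim(eps$epochs)[1]; n_ch <- dim(eps$epochs)[2]
  h <- 0.5 * (1 - cos(2 * pi * seq(0, nt - 1) / nt))  # periodic Hann
  freqs <- seq_len(f_max)
  psd <- array(0, c(n_ep, n_ch, f_max))
  for (ch in seq_len(n_ch)) {
    # time x epoch matrix for one channel
    m <- t(slice_channel(eps$epochs, ch)) * h
    co <- mvfft(m)
    psd[, ch, ] <- t(abs(co[freqs + 1L, , drop = FALSE])^2)
  }
  structure(list(psd = psd, freqs = freqs, fs = eps$fs,
                 condition = rep(eps$condition, n_ep), finger = eps$finger,
                 centers = eps$centers, trial = eps$trial,
                 labels = eps$labels),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d epochs x %d channels x %d freqs (1..%d Hz)\n",
              dim(x$psd)[1], dim(x$psd)[2], dim(x$psd)[3], max(x$freqs)))
  invisible(x)
}

#' Concatenate spectrum sets (e.g. movement + rest of a finger pair)
#' @param ... `spectrum_set` objects on identical grids.
#' @return a `spectrum_set`.
#' @export
bind_spectra <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, TRUE, "spectrum_set")))
  f0 <- xs[[1]]$freqs
  for (x in xs) stopifnot(identical(x$freqs, f0))
  psd <- do.call(abind3, lapply(xs, `[[`, "psd"))
  structure(list(psd = psd, freqs = f0, fs = xs[[1]]$fs,
                 condition = unlist(lapply(xs, `[[`, "condition")),
                 finger = unlist(lapply(xs, `[[`, "finger")),
                 centers = unlist(lapply(xs, `[[`, "centers")),
                 trial = unlist(lapply(xs, `[[`, "trial")),
                 labels = xs[[1]]$labels),
            class = "spectrum_set")
}

# epoch x freq matrix for one channel of an epoch/spectrum array
slice_channel <- function(arr, ch) {
  m <- arr[, ch, , drop = FALSE]
  dim(m) <- dim(arr)[c(1, 3)]
  m
}

# bind 3-d arrays along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[-1]
  n <- sum(vapply(xs, function(x) dim(x)[1], 1L))
  out <- array(0, c(n, d))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1]
    if (k) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

# subset epochs of a spectrum_set
subset_spectra <- function(sp, idx) {
  structure(list(psd = sp$psd[idx, , , drop = FALSE], freqs = sp$freqs,
                 fs = sp$fs, condition = sp$condition[idx],
                 finger = sp$finger[idx], centers = sp$centers[idx],
                 trial = sp$trial[idx], labels = sp$labels),
            class = "spectrum_set")
}

#' Log-normalize spectra to the ensemble average
#'
#' Divides each epoch's PSD, per channel and frequency, by the ensemble mean
#' over the grouped epochs (the two compared fingers' movement epochs plus
#' their matched rest epochs) and takes the natural logarithm, so increases
#' are positive and decreases negative and both are treated symmetrically.
#' Optionally a pre-fitted normalizer (channel x frequency matrix) is
#' applied instead, e.g. one fitted on training folds only.
#'
#' @param sp a `spectrum_set` of the grouped epochs.
#' @param normalizer optional channel x frequency ensemble-mean matrix.
#' @return object of class `norm_spectrum_set` with fields `lognorm`
#'   (epoch x channel x frequency) and `ensemble_mean`.
#' @export
log_normalize <- function(sp, normalizer = NULL) {
  stopifnot(inherits(sp, "spectrum_set"))
  if (any(sp$psd <= 0))
    stop("degenerate input: zero PSD bin")
  if (is.null(normalizer)) normalizer <- apply(sp$psd, c(2, 3), mean)
  n_ep <- dim(sp$psd)[1]
  ln <- log(sweep(sp$psd, c(2, 3), normalizer, "/"))
  structure(list(lognorm = ln, ensemble_mean = normalizer, freqs = sp$freqs,
                 fs = sp$fs, condition = sp$condition, finger = sp$finger,
                 centers = sp$centers, trial = sp$trial, labels = sp$labels),
            class = "norm_spectrum_set")
}

#' Frequency bins retained for spectral PCA
#'
#' By default the bins within +/- 3 Hz of the line frequency (and of its
#' harmonics when they fall on the grid) are excluded: the notch filter
#' carves a deterministic dip there that would otherwise dominate the
#' spectral covariance.
#'
#' @param freqs integer frequency grid.
#' @param line_freq line frequency in Hz (`NULL` disables exclusion).
#' @param halfwidth exclusion half-width in Hz.
#' @param harmonics also exclude harmonics on the grid (for recordings whose
#'   notch removed them, i.e. the 1000 Hz subdural mode).
#' @return logical vector over `freqs`, `TRUE` = retained.
#' @export
line_bin_mask <- function(freqs, line_freq = 60, halfwidth = 3,
                          harmonics = FALSE) {
  keep <- rep(TRUE, length(freqs))
  if (is.null(line_freq)) return(keep)
  hs <- if (harmonics) seq(line_freq, max(freqs), by = line_freq) else
    line_freq
  for (h in hs) keep <- keep & abs(freqs - h) > halfwidth
  keep
}

#' Per-channel principal component analysis of log-normalized spectra
#'
#' For each channel, eigen-decomposes the frequency x frequency covariance
#' of the log-normalized PSDs across epochs (epoch-mean-centered, `M - 1`
#' denominator). Components are ordered by descending eigenvalue and each
#' eigenvector's sign is fixed so its mean over frequencies is non-negative.
#' Projection weights `w[n, k]` are the inner products of each epoch's
#' centered log-spectrum with the k-th component.
#'
#' @param nsp a `norm_spectrum_set` (see [log_normalize()]).
#' @param keep_bins logical mask over the frequency grid (see
#'   [line_bin_mask()]); default excludes the 60 Hz line bins.
#' @param center optional pre-fitted channel x frequency centering matrix
#'   (means on the retained grid), e.g. from a training fit.
#' @param basis optional pre-fitted `spectral_basis` whose eigenvectors and
#'   centering are applied to the new epochs (no refit).
#' @return object of class `spectral_basis`: `eigenvalues` (channel x
#'   component), `eigenvectors` (list per channel, freq x component),
#'   `projections` (epoch x channel x component), `center`, `freqs_used`.
#' @export
spectral_pca <- function(nsp, keep_bins = NULL, basis = NULL) {
  stopifnot(inherits(nsp, "norm_spectrum_set"))
  if (any(!is.finite(nsp$lognorm))) stop("non-finite values in spectra")
  if (is.null(keep_bins)) {
    # default: drop line bins, and the Nyquist bin whose single-taper PSD
    # has chi-squared(1) statistics (double log-variance vs interior bins)
    keep_bins <- if (!is.null(basis)) basis$keep_bins
    else line_bin_mask(nsp$freqs) & nsp$freqs < nsp$fs / 2
  }
  fr <- nsp$freqs[keep_bins]
  x <- nsp$lognorm[, , keep_bins, drop = FALSE]
  n_ep <- dim(x)[1]; n_ch <- dim(x)[2]; n_fr <- dim(x)[3]
  if (is.null(basis) && n_ep < 2L) stop("need at least 2 epochs per channel")

  if (!is.null(basis)) {
    proj <- array(0, c(n_ep, n_ch, ncol(basis$eigenvectors[[1]])))
    for (ch in seq_len(n_ch)) {
      xc <- sweep(slice_channel(x, ch), 2L, basis$center[ch, ])
      proj[, ch, ] <- xc %*% basis$eigenvectors[[ch]]
    }
    out <- basis
    out$projections <- proj
    out$finger <- nsp$finger; out$condition <- nsp$condition
    return(out)
  }

  eigenvalues <- matrix(0, n_ch, n_fr)
  eigenvectors <- vector("list", n_ch)
  center <- matrix(0, n_ch, n_fr)
  proj <- array(0, c(n_ep, n_ch, n_fr))
  for (ch in seq_len(n_ch)) {
    m <- slice_channel(x, ch)
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu)
    cv <- crossprod(xc) / (n_ep - 1)
    eg <- eigen(cv, symmetric = TRUE)
    vec <- eg$vectors
    flip <- colMeans(vec) < 0
    vec[, flip] <- -vec[, flip]
    eigenvalues[ch, ] <- eg$values
    eigenvectors[[ch]] <- vec
    center[ch, ] <- mu
    proj[, ch, ] <- xc %*% vec
  }
  structure(list(eigenvalues = eigenvalues, eigenvectors = eigenvectors,
                 projections = proj, center = center, freqs_used = fr,
                 keep_bins = keep_bins, labels = nsp$labels,
                 finger = nsp$finger, condition = nsp$condition),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> %d channels, %d frequency bins, %d epochs projected\n",
              length(x$eigenvectors), length(x$freqs_used),
              dim(x$projections)[1]))
  invisible(x)
}

#' Channel-averaged principal component profiles
#'
#' Averages the k-th eigenvector across a channel subset, for plotting the
#' broadband (first) and rhythm (second) spectral structures.
#'
#' @param basis a `spectral_basis`.
#' @param k component index.
#' @param channels channel indices to average (default: all).
#' @return data.frame with `frequency` and `value`.
#' @export
average_pc <- function(basis, k = 1L, channels = NULL) {
  if (is.null(channels)) channels <- seq_along(basis$eigenvectors)
  v <- rowMeans(vapply(channels,
                       function(ch) basis$eigenvectors[[ch]][, k],
                       numeric(length(basis$freqs_used))))
  data.frame(frequency = basis$freqs_used, value = v)
}

#' Mean log band power per epoch and channel
#'
#' Baseline features: the mean log PSD over the bins of a frequency band
#' (alpha 8-12 Hz, beta 13-30 Hz, or gamma = 40 Hz up to the grid maximum).
#'
#' @param sp a `spectrum_set`.
#' @param band length-2 numeric band in Hz, or one of `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @return matrix epoch x channel.
#' @export
band_power_features <- function(sp, band) {
  stopifnot(inherits(sp, "spectrum_set"))
  if (is.character(band))
    band <- switch(match.arg(band, c("alpha", "beta", "gamma")),
                   alpha = c(8, 12), beta = c(13, 30),
                   gamma = c(40, max(sp$freqs)))
  sel <- sp$freqs >= band[1] & sp$freqs <= band[2]
  if (!any(sel)) stop("band does not intersect the frequency grid")
  apply(log(sp$psd[, , sel, drop = FALSE]), c(1, 2), mean)
}
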