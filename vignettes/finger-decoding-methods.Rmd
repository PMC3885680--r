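---
title: "Decoding individual finger movements from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding individual finger movements from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Movements of individual fingers of one hand activate small, closely spaced,
overlapping patches of sensorimotor cortex. Subdural (ECoG) recordings show
two robust spectral signatures of such movements: a *broadband* multiplicative
power increase spanning the whole analyzable band, and a power *decrease* of
the alpha (8–12 Hz) and beta (13–30 Hz) rhythms — event-related
desynchronization (ERD). `fingerbci` implements a pipeline that asks whether
the same signatures, extracted from noninvasive scalp EEG by a per-channel
principal component analysis of single-epoch power spectra, suffice to tell
*which* finger moved, pairwise, at rates well above chance.

## Pipeline model

1. **Kinematics.** Each finger wears a bipolar sensor pair whose potential
   difference peaks at full flexion. Traces are band-passed to 0.5–2 Hz
   (zero-phase), and peaks are detected per cue window under four criteria:
   amplitude at least 200 µV, at least 400 ms after cue onset, not in the
   final 500 ms of the cue, at least 200 ms apart with only the strongest
   peak kept inside any 400 ms window. A data-glove variant thresholds
   positions at 2 (on the glove's [-5, 10] scale).
2. **Preprocessing.** 0.3 Hz zero-phase high-pass, 60 Hz notch
   (transition band 0.3 Hz; harmonics too for 1000 Hz subdural data), then
   common average reference: `V'_n(t) = V_n(t) − mean_k V_k(t)`.
3. **Epochs and spectra.** One-second windows centered at movement peaks
   (movement condition) and at the middle of each fixation period (rest
   condition, labeled by the finger moved afterwards). Per epoch and channel,
   the power spectral density is the squared magnitude of the Hanning-
   windowed Fourier transform on the integer grid 1..125 Hz (1..200 Hz for
   subdural data); the 1 s window makes the native resolution 1 Hz.
4. **Spectral decoupling.** For each pair of fingers, the pair's movement
   epochs and their rest epochs are pooled; each PSD is divided by the
   ensemble mean at its channel and frequency and log-transformed, so
   increases and decreases are treated symmetrically. Per channel, the
   frequency-by-frequency covariance of these log-normalized spectra is
   eigen-decomposed. The leading eigenvector is, in this regime, a
   near-uniform positive "broadband" shape; the second concentrates in the
   alpha/beta band (the ERD shape). Projections of each epoch onto the
   leading eigenvectors are the features `w[n, k]`.
5. **Decoding.** Features are the projections on a chosen component subset
   (first five considered; first three by default) over a channel set chosen
   either a priori (fixed set), by top-k squared point-biserial correlation
   (`r²`) computed on training data, or by an `r²` threshold. A
   radial-basis-kernel maximum-margin classifier (C-SVM dual solved by
   sequential minimal optimization) with grid-searched penalty and kernel
   width classifies the pair under stratified five-fold cross-validation,
   with epochs permuted before each of the repeated runs. Decoding accuracy
   (DA) is correct classifications over total movements.
6. **Statistics.** Chance is assessed two ways: the analytic two-class bound
   `0.5 ± z_{1−α/2} sqrt(0.25/m)` for `m` movements, and an empirical
   guessing level from full re-runs on label-permuted data (500 permutations
   by convention; tests use fewer). One-sample t-tests compare DA
   distributions against the guessing level; paired t-tests compare feature
   conditions. Report tables use the (n−1)-denominator standard deviation.

## Leakage control

All fitted state — the ensemble-mean normalizer, per-channel centering and
eigenbasis, `r²` channel selection, feature standardization, and the
classifier with its grid search — is estimated on training folds only and
applied unchanged to the test fold. The rest-condition control runs the
identical machinery on rest epochs; on data whose effects are confined to
cue windows it must stay inside the chance interval.

## The synthetic world

No recordings are deposited for the EEG study this design follows, so the
package ships a generator whose output has the statistical structure the
analysis assumes, with ground truth:

* **Protocol.** Trials of 2 s blank + 2 s fixation + 2 s cue; 60 trials per
  finger by default; cued finger order randomized.
* **Background.** Gaussian `1/f` noise (spectral shaping of white noise),
  ~10 µV RMS, plus a 1 µV 60 Hz line component.
* **Rhythms.** Narrowband Gaussian processes centered at 10 Hz (σ 1.5 Hz)
  and 21.5 Hz (σ 4 Hz) with PSD four times the background at band centers,
  each modulated by an independent lognormal burst envelope per channel and
  band (`rhythm_variability`, log-SD 0.5). This spontaneous waxing and
  waning makes the rhythm direction a variance axis of its own, so the PCA
  can separate it from the movement contrast — as in real EEG.
* **Gain fluctuation.** A recording-wide lognormal envelope
  (`background_variability`, log-SD 0.35) multiplies the background on all
  channels, emulating arousal/reference non-stationarity. Being coherent
  across frequency, it creates the large flat variance direction that the
  first principal component locks onto in real data; without it the first
  component would be the raw movement contrast (flat plus an ERD notch)
  rather than the clean broadband shape. Being coherent across channels, it
  acts as common mode that the classifier can cancel, so it does not drown
  the finger-specific topography.
* **Envelope timescale.** Both envelopes decorrelate in ~0.6 s —
  deliberately *shorter* than the ~1 s spacing of the two movements inside
  one cue. Epochs from the same trial would otherwise share envelope state,
  and a classifier can then match a test epoch to its same-trial "twin" in
  the training folds; with all effects off this pushes null decoding above
  chance, violating the generator's null-soundness contract. Burst-scale
  (rather than multi-second) envelopes keep every epoch exchangeable under
  the null while preserving the epoch-to-epoch power variance the PCA
  decomposes.
* **Movement effects.** During each cue, on a contiguous 10-channel "signal"
  subset, the background amplitude is scaled by `sqrt(1 + (gain − 1) w)` and
  the rhythms by `sqrt(1 − min(1, erd_depth · w))`, where `w` is a smooth
  spatial profile (pedestal + Gaussian bump, σ 3 channels) whose center
  shifts by two channels per finger and which is normalized to unit mean
  over the signal subset — so the mean movement/rest PSD ratio across those
  channels equals `broadband_gain` exactly, while fingers remain
  distinguishable by topography. Defaults `broadband_gain = 2`,
  `erd_depth = 0.5`: the study reports no effect sizes for its own data, so
  these are chosen to put pairwise DA in the range its tables report
  (roughly 0.6–1.0 per pair) rather than derived from any printed value.
* **Kinematics.** Each movement is one Hann-windowed 1 Hz cycle whose
  extremum marks the event; two per cue, the first 0.42–0.47 s after onset,
  repeats ~1 s apart (the natural repetition rate of paced flexion), and
  alternating polarity, as the bipolar potential does over a
  flexion–extension sequence. Pulses are scaled so the peak *after* the
  detector's 0.5–2 Hz band-pass equals `peak_amplitude_uv` (300 µV default);
  polarity alternation also makes neighbouring pulses' negative lobes cancel
  rather than sum, so the |trace| criterion sees exactly one
  supra-threshold extremum per movement. Non-cued fingers' traces carry only
  5 µV sensor noise.

What the generator does **not** emulate: volume conduction and electrode
geometry (channels are independent noise sources; there is no head model),
ocular/muscle artifacts (artifact rejection is correspondingly out of
scope; real inputs are assumed pre-cleaned), evoked potentials, or any
cross-channel correlation beyond the shared slow drift. A green test
therefore establishes that the *analysis machinery* behaves as specified on
data with the assumed statistical structure — not that scalp EEG itself
supports these accuracies.

## Numerical choices

* **Filters.** The named elliptic family requires a design routine
  unavailable here; order-4 Butterworth (bilinear transform with
  pre-warping) meets every stated response contract — ≥ 40 dB DC rejection,
  passband error under 2 %, zero phase via forward–reverse application with
  odd reflection padding and step-steady-state initial conditions. The pad
  length for the 0.3 Hz high-pass is ~3 cutoff time constants. The 60 Hz
  notch (quality factor 200) is *not* run as a recursive forward–reverse
  filter: on strong on-resonance input the reverse pass re-amplifies the
  forward pass's resonant transient (scipy's `filtfilt` shows the identical
  residual). Its squared magnitude is applied in the frequency domain
  instead — exactly zero-phase, same magnitude contract.
* **Spectral grid.** DC is excluded (meaningless after high-pass). Bins
  within ±3 Hz of 60 Hz are excluded from the PCA covariance by default
  (the notch carves a deterministic dip there); harmonics likewise in the
  1000 Hz mode. The Nyquist bin is excluded too: its single-taper PSD is
  chi-squared with one degree of freedom, i.e. double the log-variance of
  interior bins, which would otherwise attract the second component.
* **PCA conventions.** Covariance uses epoch-mean centering and the n−1
  denominator; eigenvectors are sign-fixed so their frequency-mean is
  non-negative; projections are of centered spectra, so the per-component
  projection variance equals the eigenvalue exactly.
* **Classifier.** SMO with maximal-violating-pair selection, duality-gap
  tolerance 1e-3 (1e-6 in oracle tests); verified against an independent
  reference implementation to 8 decimals in the dual objective. Grid search
  uses an internal stratified 3-fold split; ties resolve to the first grid
  point. The default grid (costs 2^-3..2^9 by 4; widths (1/d)·2^{-2,0,2})
  is a compute-scaled version of the classical exhaustive grid, which can be
  passed explicitly.
* **Detector ties.** Equal-amplitude candidates inside one merge window keep
  the earlier peak (deterministic, latency-faithful). Plateaus in glove
  traces yield their midpoint.
* **Degenerate inputs.** Zero PSD bins, non-finite samples, single-channel
  CAR, overlapping trials, empty trial tables and empty rest sets raise
  errors; zero-variance `r²` returns 0 with a warning; zero-variance t-tests
  fall back to exact comparison with a warning.

A note on joint chance checks: a single two-class dataset's cross-validated
null accuracy is itself a draw from roughly the binomial interval's
distribution, so demanding that *all ten* finger pairs sit inside per-pair
95% intervals would fail on a fraction of perfectly null datasets by
construction. Where the test suite verifies that decoding is at chance
across all pairs simultaneously (rest control, type-I control), it holds
each pair to the interval at the family-wise level (α/10) and the
across-pair mean to the unadjusted α — the package's reporting functions
themselves apply no multiple-testing correction, matching the protocol.

## Open design points resolved here

* The ensemble mean of the log-normalization is computed per channel (the
  normalization indexes channels), and the rest epochs of both fingers enter
  the normalizer, following the pooling described for the pair analysis.
* The 200 µV kinematic threshold is applied after the 0.5–2 Hz band-pass
  (the detection text introduces filtering first).
* Grid search is nested inside every cross-validation fold rather than run
  once per dataset; this is the stricter, leakage-free reading.
* Repetition counts trade compute for the variance of the DA estimate: the
  acceptance checks use 2 repetitions where the planted effect is large
  (positive decoding) and 10 where the quantity must sit inside an interval
  (null and rest controls); the protocol value of 20 remains the
  package default.
* Epoch windows are half-open in 0-based samples,
  `[center − T·fs/2, center + T·fs/2)`, making a 1 s epoch exactly `fs`
  samples.

## Known limitations

* The per-channel PCA assumes enough epochs per pair (tens) for a stable
  leading eigenvector; with very few epochs the rank-deficient covariance is
  permitted but the components beyond the rank are numerical noise.
* The empirical guessing level re-runs the whole pipeline per permutation
  and is the one deliberately expensive operation (500 permutations at
  protocol scale); the analytic bound is reported always.
* Frequency-domain notching assumes the recording is long relative to the
  notch width (minutes of data; true for this protocol).
* The generator's channel independence makes common-average referencing
  nearly a no-op on synthetic data; it is exercised for contract correctness,
  not for its SNR benefit.
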