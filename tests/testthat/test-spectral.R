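fs <- 250

# epoch_set with one channel from a plain matrix (epochs x time)
as_epochs <- function(m, fs = 250, finger = NULL, condition = "movement") {
  n <- nrow(m)
  epochs <- array(m, c(n, 1L, ncol(m)))
  epoch_set(epochs, fs, condition, finger = finger %||% rep("thumb", n),
            centers = seq_len(n), trial = seq_len(n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PSD bins align with sinusoid frequency and match a direct DFT", {
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sp <- psd_hanning(as_epochs(rbind(sin(2 * pi * 10 * t))))
  expect_identical(sp$freqs[which.max(sp$psd[1, 1, ])], 10L)

  set.seed(11)
  x <- rnorm(fs)
  sp <- psd_hanning(as_epochs(rbind(x)))
  # naive O(n^2) windowed DFT oracle
  h <- 0.5 * (1 - cos(2 * pi * (0:(fs - 1)) / fs))
  oracle <- vapply(1:125, function(f) {
    Mod(sum(h * x * exp(-2i * pi * f * (0:(fs - 1)) / fs)))^2
  }, numeric(1))
  expect_lt(max(abs(sp$psd[1, 1, ] - oracle)) / max(oracle), 1e-9)

  expect_error(psd_hanning(as_epochs(rbind(x)), f_max = 150), "fs/2")
  expect_error(psd_hanning(as_epochs(matrix(rnorm(200), 1))), "one second")
})

test_that("mean white-noise PSD is flat", {
  set.seed(12)
  sp <- psd_hanning(as_epochs(matrix(rnorm(500 * fs), 500)))
  m <- colMeans(sp$psd[, 1, ])
  expect_lt(max(abs(m / mean(m) - 1)), 0.25)
  # flatness of the band means, tighter
  bands <- split(m, cut(seq_along(m), 5))
  bm <- vapply(bands, mean, numeric(1))
  expect_lt(max(abs(bm / mean(bm) - 1)), 0.1)
})

test_that("log-normalization is exact and identity-preserving", {
  set.seed(13)
  base <- matrix(rexp(8 * fs), 1)
  sp <- psd_hanning(as_epochs(matrix(rnorm(6 * fs), 6)))
  nsp <- log_normalize(sp)
  # exp-mean over epochs equals 1 per channel x frequency
  expect_lt(max(abs(apply(exp(nsp$lognorm), c(2, 3), mean) - 1)), 1e-9)

  # all epochs identical -> all-zero lognorm
  same <- sp
  for (i in 2:6) same$psd[i, , ] <- same$psd[1, , ]
  expect_lt(max(abs(log_normalize(same)$lognorm)), 1e-12)

  # scalar hand-check: double one bin of one epoch among M at baseline
  M <- 5
  sp2 <- sp
  sp2$psd <- array(1, c(M, 1, 125))
  sp2$psd[1, 1, 10] <- 2
  nsp2 <- log_normalize(fingerbci:::subset_spectra(sp2, 1:M))
  mean_factor <- (2 + M - 1) / M
  expect_equal(nsp2$lognorm[1, 1, 10], log(2 / mean_factor))
  expect_equal(nsp2$lognorm[2, 1, 10], log(1 / mean_factor))

  sp2$psd[2, 1, 3] <- 0
  expect_error(log_normalize(sp2), "zero PSD")
})

test_that("per-channel PCA matches a brute-force covariance oracle", {
  set.seed(14)
  m <- matrix(rnorm(5 * 10), 5, 10)   # 5 epochs x 10 bins
  nsp <- structure(list(lognorm = array(m, c(5, 1, 10)), freqs = 1:10,
                        fs = 250, condition = rep("movement", 5),
                        finger = rep("thumb", 5), centers = 1:5,
                        trial = 1:5, labels = "ch01"),
                   class = "norm_spectrum_set")
  b <- spectral_pca(nsp, keep_bins = rep(TRUE, 10))
  # brute-force covariance: sum of centered outer products / (M - 1)
  mu <- colMeans(m)
  cv <- matrix(0, 10, 10)
  for (i in 1:5) cv <- cv + tcrossprod(m[i, ] - mu)
  cv <- cv / 4
  eg <- eigen(cv, symmetric = TRUE)
  expect_lt(max(abs(b$eigenvalues[1, ] - eg$values)), 1e-9)

  # orthonormality, eigenvalue conservation, projection variance identity
  V <- b$eigenvectors[[1]]
  expect_lt(max(abs(crossprod(V) - diag(10))), 1e-9)
  expect_lt(abs(sum(b$eigenvalues[1, ]) - sum(diag(cv))),
            1e-8 * sum(diag(cv)))
  pv <- apply(b$projections[, 1, ], 2, var)
  lam <- b$eigenvalues[1, ]
  big <- lam > 1e-10 * max(lam)    # identity holds above numerical rank
  expect_lt(max(abs(pv[big] - lam[big]) / lam[big]), 1e-6)

  # completeness: projections reconstruct the centered data exactly
  rec <- b$projections[, 1, ] %*% t(V)
  expect_lt(max(abs(rec - sweep(m, 2, mu))), 1e-9)

  # sign convention: non-negative mean per eigenvector
  expect_true(all(colMeans(V) >= -1e-12))

  nsp$lognorm[1] <- NaN
  expect_error(spectral_pca(nsp, keep_bins = rep(TRUE, 10)), "non-finite")
})

test_that("a planted spectral template is recovered as the first PC", {
  set.seed(15)
  F <- 40; M <- 300
  tpl <- sin(seq(0, pi, length.out = F)); tpl <- tpl / sqrt(sum(tpl^2))
  load <- rnorm(M, sd = 3)
  m <- outer(load, tpl) + matrix(rnorm(M * F, sd = 0.1), M, F)
  nsp <- structure(list(lognorm = array(m, c(M, 1, F)), freqs = 1:F,
                        fs = 250, condition = rep("movement", M),
                        finger = rep("thumb", M), centers = 1:M,
                        trial = 1:M, labels = "ch01"),
                   class = "norm_spectrum_set")
  b <- spectral_pca(nsp, keep_bins = rep(TRUE, F))
  pc1 <- b$eigenvectors[[1]][, 1]
  expect_gt(abs(cor(pc1, tpl)), 0.99)
})

test_that("two planted templates span the first two PCs", {
  set.seed(16)
  F <- 60; M <- 300
  t1 <- rep(1, F) / sqrt(F)
  t2 <- exp(-((1:F) - 12)^2 / 8); t2 <- t2 / sqrt(sum(t2^2))
  m <- outer(rnorm(M, sd = 2), t1) + outer(rnorm(M, sd = 1), t2) +
    matrix(rnorm(M * F, sd = 0.05), M, F)
  nsp <- structure(list(lognorm = array(m, c(M, 1, F)), freqs = 1:F,
                        fs = 250, condition = rep("movement", M),
                        finger = rep("thumb", M), centers = 1:M,
                        trial = 1:M, labels = "ch01"),
                   class = "norm_spectrum_set")
  b <- spectral_pca(nsp, keep_bins = rep(TRUE, F))
  V2 <- b$eigenvectors[[1]][, 1:2]
  # subspace angle of each template to span(PC1, PC2) < 5 degrees
  for (tpl in list(t1, t2)) {
    proj <- V2 %*% crossprod(V2, tpl)
    ang <- acos(min(1, sqrt(sum(proj^2)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("null spectra produce no broadband-like component", {
  cf <- small_config(seed = 33, broadband_gain = 1, erd_depth = 0,
                     rhythm_variability = 0, background_variability = 0)
  fe <- run_frontend(cf)
  g <- bind_spectra(fingerbci:::pair_spectra(fe$movement, c("thumb", "little")),
                    fingerbci:::pair_spectra(fe$rest, c("thumb", "little")))
  b <- spectral_pca(log_normalize(g))
  u <- rep(1, length(b$freqs_used)) / sqrt(length(b$freqs_used))
  for (ch in cf$signal_channels) {
    cors <- abs(crossprod(b$eigenvectors[[ch]], u))
    expect_lt(max(cors), 0.8)
  }
})

test_that("line and Nyquist bins are excluded by default", {
  keep <- line_bin_mask(1:125)
  expect_false(any(keep[57:63]))
  expect_true(all(keep[c(1:56, 64:125)]))
  keep2 <- line_bin_mask(1:200, harmonics = TRUE)
  expect_false(any(keep2[c(57:63, 117:123, 177:183)]))
  expect_true(all(line_bin_mask(1:200)[117:123]))   # fundamental-only default
  sp <- psd_hanning(as_epochs(matrix(rnorm(4 * fs), 4)))
  b <- spectral_pca(log_normalize(sp))
  expect_false(125 %in% b$freqs_used)  # Nyquist bin dropped at fs = 250
  expect_false(60 %in% b$freqs_used)
})

test_that("band power features average log power over band bins", {
  sp <- psd_hanning(as_epochs(matrix(rnorm(3 * fs), 3)))
  sp$psd[] <- exp(2)   # flat spectrum of value e^2
  for (band in c("alpha", "beta", "gamma"))
    expect_equal(unname(band_power_features(sp, band)[, 1]), rep(2, 3))

  # gamma ignores bins below 40 Hz
  sp2 <- sp
  sp2$psd[, , 10] <- exp(7)
  expect_equal(band_power_features(sp2, "gamma"),
               band_power_features(sp, "gamma"))
  expect_error(band_power_features(sp, c(300, 400)), "intersect")

  # alpha-band-limited noise scores higher than equal-power white noise
  set.seed(17)
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  osc <- sin(2 * pi * 9 * t) + sin(2 * pi * 10 * t) + sin(2 * pi * 11 * t) +
    rnorm(fs, sd = 0.3)              # floor keeps every alpha bin populated
  wn <- rnorm(fs); wn <- wn * sqrt(sum(osc^2) / sum(wn^2))
  spb <- psd_hanning(as_epochs(rbind(osc, wn)))
  af <- band_power_features(spb, "alpha")
  expect_gt(af[1, 1], af[2, 1])
})
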