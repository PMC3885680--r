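test_that("r-squared equals the squared point-biserial correlation", {
  a <- matrix(c(1, 1, 1), 3, 1)
  b <- matrix(c(2, 2, 2), 3, 1)
  expect_equal(r2_map(a, b), 1)
  expect_warning(r0 <- r2_map(a, a), "zero")
  expect_equal(r0, 0)

  # identical distributions as multisets
  a2 <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(suppressWarnings(r2_map(a2, a2[4:1, , drop = FALSE])), 0)

  set.seed(30)
  wa <- array(rnorm(20 * 3 * 2), c(20, 3, 2))
  wb <- array(rnorm(15 * 3 * 2, 1), c(15, 3, 2))
  r2 <- r2_map(wa, wb, aggregate = "none")
  lab <- c(rep(0, 20), rep(1, 15))
  for (ch in 1:3) for (k in 1:2) {
    oracle <- cor(c(wa[, ch, k], wb[, ch, k]), lab)^2
    expect_lt(abs(r2[ch, k] - oracle), 1e-12)
  }
  agg <- r2_map(wa, wb)
  expect_equal(agg, apply(r2, 1, max))
  expect_true(all(agg >= 0 & agg <= 1))
  expect_error(r2_map(wa[0, , , drop = FALSE], wb), "non-empty")
})

test_that("channel selection strategies behave as specified", {
  expect_identical(select_channels(NULL, "fixed_set", channels = c(3, 7, 9)),
                   c(3L, 7L, 9L))
  expect_error(select_channels(NULL, "fixed_set"), "non-empty")
  expect_identical(sort(select_channels(c(0.5, 0.1, 0.4, 0.3), "top_k", k = 3)),
                   c(1L, 3L, 4L))
  expect_identical(select_channels(c(0.05, 0.3, 0.2), "r2_threshold",
                                   threshold = 0.1), 2:3)
  expect_warning(s <- select_channels(c(0.05, 0.08), "r2_threshold",
                                      threshold = 0.5), "falling back")
  expect_identical(s, 2L)
})

test_that("cross-validation separates separable features and is seeded", {
  set.seed(31)
  n <- 60
  fm <- cbind(c(rnorm(n / 2, 0, 1), rnorm(n / 2, 10, 1)), rnorm(n))
  y <- rep(c("thumb", "index"), each = n / 2)
  r1 <- crossval_pairwise(feature_matrix = fm, labels = y, folds = 5,
                          reps = 3, seed = 9)
  expect_gte(r1$da_mean, 0.99)
  r2 <- crossval_pairwise(feature_matrix = fm, labels = y, folds = 5,
                          reps = 3, seed = 9)
  expect_identical(r1$da, r2$da)

  # label-swap symmetry
  y2 <- ifelse(y == "thumb", "index", "thumb")
  r3 <- crossval_pairwise(feature_matrix = fm, labels = y2, folds = 5,
                          reps = 3, seed = 9)
  expect_equal(r1$da, r3$da)
  expect_error(crossval_pairwise(feature_matrix = fm, labels = y, folds = 1),
               "at least 2 folds")
})

test_that("label-independent features decode at chance", {
  set.seed(32)
  n <- 160
  fm <- matrix(rnorm(n * 4), n, 4)
  y <- rep(c("a", "b"), each = n / 2)
  res <- crossval_pairwise(feature_matrix = fm, labels = y, folds = 5,
                           reps = 20, seed = 5)
  ci <- guessing_ci(n)
  expect_gt(res$da_mean, ci[1])
  expect_lt(res$da_mean, ci[2])
})

test_that("no training state leaks from test folds", {
  cf <- tiny_config(seed = 51)
  fe <- run_frontend(cf)
  spm <- fingerbci:::pair_spectra(fe$movement, c("thumb", "little"))
  spr <- fingerbci:::pair_spectra(fe$rest, c("thumb", "little"))
  idx_tr <- seq_len(dim(spm$psd)[1] - 4L)
  idx_te <- setdiff(seq_len(dim(spm$psd)[1]), idx_tr)
  tr <- fingerbci:::subset_spectra(spm, idx_tr)
  te <- fingerbci:::subset_spectra(spm, idx_te)
  model <- fingerbci:::fit_feature_model(tr, spr)
  # perturbing test epochs must not change any fitted state
  te2 <- te; te2$psd <- te2$psd * 7
  w_a <- fingerbci:::apply_feature_model(model, te, 1:3)
  model_after <- fingerbci:::fit_feature_model(tr, spr)
  expect_identical(model$normalizer, model_after$normalizer)
  expect_identical(model$basis$eigenvectors, model_after$basis$eigenvectors)
  # transformed features are a deterministic function of the fitted state
  w_b <- fingerbci:::apply_feature_model(model, te, 1:3)
  expect_identical(w_a, w_b)
})

test_that("planted channels are recovered by r-squared selection", {
  # the stated recovery rate is for 60 trials per finger
  cf <- synth_config(n_channels = 12L, trials_per_finger = 60L,
                     signal_channels = 4:9, seed = 52L)
  fe <- run_frontend(cf)
  spm <- fingerbci:::pair_spectra(fe$movement, c("thumb", "little"))
  spr <- fingerbci:::pair_spectra(fe$rest, c("thumb", "little"))
  model <- fingerbci:::fit_feature_model(spm, spr)
  w <- fingerbci:::apply_feature_model(model, spm, 1:3)
  g <- spm$finger == "thumb"
  r2 <- r2_map(w[g, , , drop = FALSE], w[!g, , , drop = FALSE])
  sel <- select_channels(r2, "top_k", k = length(cf$signal_channels))
  overlap <- length(intersect(sel, cf$signal_channels)) /
    length(cf$signal_channels)
  expect_gte(overlap, 0.8)
})

test_that("rest-control decoding requires non-empty input", {
  cf <- tiny_config(seed = 53)
  fe <- run_frontend(cf)
  empty <- fingerbci:::subset_spectra(fe$rest, integer(0))
  expect_error(rest_control_decoding(empty), "empty rest")
})

test_that("more PCs help when rhythm effects carry finger information", {
  # dose response over seeded replicates; the world plants a weak broadband
  # effect and a strong finger-specific desynchronization, so the second and
  # third components carry information the first alone misses
  wins <- 0L
  for (s in c(61, 62, 63, 64, 65)) {
    cf <- synth_config(n_channels = 12L, trials_per_finger = 30L,
                       signal_channels = 4:9, broadband_gain = 1.2,
                       erd_depth = 1.0, seed = s)
    fe <- run_frontend(cf)
    spm <- fingerbci:::pair_spectra(fe$movement, c("thumb", "little"))
    spr <- fingerbci:::pair_spectra(fe$rest, c("thumb", "little"))
    da3 <- crossval_pairwise(spm, spr, pcs = 1:3,
                             channel_strategy = "fixed_set",
                             channels = cf$signal_channels, reps = 3,
                             seed = s)$da_mean
    da1 <- crossval_pairwise(spm, spr, pcs = 1L,
                             channel_strategy = "fixed_set",
                             channels = cf$signal_channels, reps = 3,
                             seed = s)$da_mean
    if (da3 >= da1) wins <- wins + 1L
  }
  expect_gte(wins, 4L)  # >= 80 % of replicates
})

test_that("broadband PC features beat alpha-band features on average", {
  diffs <- numeric(0)
  for (s in 71:76) {
    cf <- synth_config(n_channels = 8L, trials_per_finger = 10L,
                       signal_channels = 3:6, seed = s)
    fe <- run_frontend(cf)
    spm <- fingerbci:::pair_spectra(fe$movement, c("thumb", "little"))
    spr <- fingerbci:::pair_spectra(fe$rest, c("thumb", "little"))
    da_pc <- crossval_pairwise(spm, spr, pcs = 1L,
                               channel_strategy = "fixed_set",
                               channels = 3:6, reps = 1, seed = s)$da_mean
    af <- band_power_features(spm, "alpha")[, 3:6]
    da_al <- crossval_pairwise(feature_matrix = af, labels = spm$finger,
                               reps = 1, seed = s)$da_mean
    diffs <- c(diffs, da_pc - da_al)
  }
  expect_gt(mean(diffs), 0)
})
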