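#' Proportion of variance explained by the group-mean difference (r-squared)
#'
#' For each channel (and each principal component, aggregated by the maximum
#' over components), computes the squared point-biserial correlation between
#' the feature values of the two groups and their 0/1 group labels, i.e. the
#' proportion of total variance accounted for by the difference of the group
#' means. Zero total variance yields 0 with a warning.
#'
#' @param weights_a,weights_b projection weights of the two conditions:
#'   arrays (epoch x channel x component) or matrices (epoch x channel).
#' @param aggregate how to combine per-component values per channel.
#' @return numeric vector of per-channel r-squared values in \[0, 1\].
#' @export
r2_map <- function(weights_a, weights_b, aggregate = c("max", "none")) {
  aggregate <- match.arg(aggregate)
  if (length(dim(weights_a)) == 2L) {
    weights_a <- array(weights_a, c(dim(weights_a), 1L))
    weights_b <- array(weights_b, c(dim(weights_b), 1L))
  }
  stopifnot(length(dim(weights_a)) == 3L,
            dim(weights_a)[-1] == dim(weights_b)[-1])
  n1 <- dim(weights_a)[1]; n2 <- dim(weights_b)[1]
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  lab <- c(rep(0, n1), rep(1, n2))
  n_ch <- dim(weights_a)[2]; n_pc <- dim(weights_a)[3]
  r2 <- matrix(0, n_ch, n_pc)
  warned <- FALSE
  for (ch in seq_len(n_ch)) for (k in seq_len(n_pc)) {
    v <- c(weights_a[, ch, k], weights_b[, ch, k])
    if (var(v) == 0) {
      if (!warned) {
        warning("zero total variance; r-squared set to 0")
        warned <- TRUE
      }
      r2[ch, k] <- 0
    } else {
      r2[ch, k] <- cor(v, lab)^2
    }
  }
  if (aggregate == "max") apply(r2, 1L, max) else r2
}

#' Select feature channels
#'
#' Strategies: `fixed_set` (a predefined channel list, e.g. the montage's
#' centro-parietal set), `top_k` (k best by r-squared), or `r2_threshold`
#' (all channels above a threshold; falls back to the single best channel
#' with a warning when none passes).
#'
#' @param r2 per-channel r-squared values (ignored for `fixed_set`).
#' @param strategy selection strategy.
#' @param channels channel indices for `fixed_set`.
#' @param k number of channels for `top_k`.
#' @param threshold r-squared cutoff for `r2_threshold`.
#' @return integer vector of selected channel indices.
#' @export
select_channels <- function(r2, strategy = c("fixed_set", "top_k",
                                             "r2_threshold"),
                            channels = NULL, k = 50L, threshold = 0.1) {
  strategy <- match.arg(strategy)
  switch(strategy,
         fixed_set = {
           if (is.null(channels) || !length(channels))
             stop("fixed_set requires a non-empty channel list")
           as.integer(channels)
         },
         top_k = {
           k <- min(k, length(r2))
           order(r2, decreasing = TRUE)[seq_len(k)]
         },
         r2_threshold = {
           sel <- which(r2 > threshold)
           if (!length(sel)) {
             warning("no channel above threshold; falling back to best channel")
             sel <- which.max(r2)
           }
           sel
         })
}

# Fit the full feature-extraction state on training epochs only:
# ensemble-mean normalizer, per-channel centering + PCA basis.
fit_feature_model <- function(sp_train, sp_aux = NULL, keep_bins = NULL) {
  grouped <- if (!is.null(sp_aux)) bind_spectra(sp_train, sp_aux) else sp_train
  nsp <- log_normalize(grouped)
  basis <- spectral_pca(nsp, keep_bins = keep_bins)
  list(normalizer = nsp$ensemble_mean, basis = basis)
}

# projection weights (epoch x channel x pc) of epochs under a fitted model
apply_feature_model <- function(model, sp, pcs) {
  nsp <- log_normalize(sp, normalizer = model$normalizer)
  b <- spectral_pca(nsp, basis = model$basis)
  b$projections[, , pcs, drop = FALSE]
}

# flatten epoch x channel x pc to a feature matrix with bookkeeping
flatten_weights <- function(w, channels) {
  w <- w[, channels, , drop = FALSE]
  d <- dim(w)
  m <- matrix(w, nrow = d[1])
  colnames(m) <- as.vector(outer(channels, seq_len(d[3]),
                                 function(ch, k) sprintf("ch%02d_pc%d", ch, k)))
  m
}

#' Cross-validated pairwise decoding
#'
#' Decodes one pair of fingers from projection-weight features under
#' stratified five-fold cross-validation repeated `reps` times with the
#' epochs randomly permuted before each repetition. All fitted state
#' (ensemble normalizer, PCA basis and centering, r-squared channel
#' selection, feature standardization, classifier and its grid search) is
#' estimated on the training folds only and applied unchanged to the test
#' fold. Decoding accuracy (DA) per repetition is the number of correctly
#' classified movements divided by the total number of movements.
#'
#' @param sp_main `spectrum_set` of the classified epochs, restricted to the
#'   two fingers (typically movement epochs; rest epochs for the rest
#'   control).
#' @param sp_aux complementary `spectrum_set` entering normalization and PCA
#'   only (the pair's rest epochs, or movement epochs for the rest control);
#'   may be `NULL`.
#' @param pcs principal-component indices used as features (subset of 1:5).
#' @param channel_strategy,channels,top_k,r2_threshold see
#'   [select_channels()].
#' @param folds,reps cross-validation folds and repetitions.
#' @param seed master seed for permutation, fold draws and the grid search.
#' @param cost_grid,gamma_grid classifier search grid (see [svm_rbf_grid()]).
#' @param feature_matrix optional precomputed feature matrix (epochs x
#'   features); when given, spectral refitting is skipped and the features
#'   are used as-is (band-power baselines, permutation tests).
#' @param labels labels for `feature_matrix` mode.
#' @param keep_bins frequency-bin mask for the PCA (see [line_bin_mask()]).
#' @return list of class `decoding_result`: `da` (per-repetition DA),
#'   `da_mean`, `da_sd`, `m` (number of classified epochs), `fold_acc`,
#'   `channels_used`.
#' @export
crossval_pairwise <- function(sp_main, sp_aux = NULL, pcs = 1:3,
                              channel_strategy = "fixed_set",
                              channels = NULL, top_k = 50L,
                              r2_threshold = 0.1,
                              folds = 5L, reps = 20L, seed = 1L,
                              cost_grid = 2^seq(-3, 9, by = 4),
                              gamma_grid = NULL,
                              feature_matrix = NULL, labels = NULL,
                              keep_bins = NULL) {
  if (folds < 2L) stop("cross-validation requires at least 2 folds")
  direct <- !is.null(feature_matrix)
  if (direct) {
    y <- as.character(labels)
    n <- nrow(feature_matrix)
  } else {
    stopifnot(inherits(sp_main, "spectrum_set"))
    y <- sp_main$finger
    n <- dim(sp_main$psd)[1]
    if (n == 0L) stop("no epochs to classify")
    # fixed channel set: restrict spectra up front (selection-free)
    if (channel_strategy == "fixed_set") {
      if (is.null(channels)) stop("fixed_set requires a channel list")
      sp_main <- restrict_channels(sp_main, channels)
      if (!is.null(sp_aux)) sp_aux <- restrict_channels(sp_aux, channels)
    }
  }
  if (length(unique(y)) != 2L) stop("exactly two classes required")
  set.seed(seed)
  da <- numeric(reps)
  fold_acc <- matrix(NA_real_, reps, folds)
  used <- vector("list", reps)
  for (r in seq_len(reps)) {
    perm <- sample.int(n)  # random permutation before fold assignment
    fold <- integer(n)
    fold[perm] <- stratified_folds(y[perm], folds)
    hits <- 0L
    sel_all <- integer(0)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (direct) {
        xtr <- feature_matrix[tr, , drop = FALSE]
        xte <- feature_matrix[te, , drop = FALSE]
      } else {
        model <- fit_feature_model(subset_spectra(sp_main, tr), sp_aux,
                                   keep_bins = keep_bins)
        wtr <- apply_feature_model(model, subset_spectra(sp_main, tr), pcs)
        wte <- apply_feature_model(model, subset_spectra(sp_main, te), pcs)
        if (channel_strategy == "fixed_set") {
          sel <- seq_len(dim(wtr)[2])
        } else {
          g <- y[tr] == unique(y)[1]
          r2 <- r2_map(wtr[g, , , drop = FALSE], wtr[!g, , , drop = FALSE])
          sel <- select_channels(r2, channel_strategy, channels = channels,
                                 k = top_k, threshold = r2_threshold)
        }
        sel_all <- union(sel_all, sel)
        xtr <- flatten_weights(wtr, sel)
        xte <- flatten_weights(wte, sel)
      }
      mu <- colMeans(xtr); sg <- apply(xtr, 2L, sd); sg[sg == 0] <- 1
      xtr <- scale(xtr, mu, sg); xte <- scale(xte, mu, sg)
      fit <- svm_rbf_grid(xtr, y[tr], cost_grid = cost_grid,
                          gamma_grid = gamma_grid)
      pr <- predict(fit, xte)
      fold_acc[r, f] <- mean(pr == y[te])
      hits <- hits + sum(pr == y[te])
    }
    da[r] <- hits / n
    used[[r]] <- sel_all
  }
  structure(list(da = da, da_mean = mean(da), da_sd = sd(da), m = n,
                 fold_acc = fold_acc,
                 channels_used = sort(unique(unlist(used))),
                 pair = sort(unique(y)), pcs = pcs),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s vs %s: DA %.4f +/- %.4f (m = %d, %d reps)\n",
              x$pair[1], x$pair[2], x$da_mean, x$da_sd, x$m, length(x$da)))
  invisible(x)
}

# subset the channel dimension of a spectrum_set
restrict_channels <- function(sp, channels) {
  structure(list(psd = sp$psd[, channels, , drop = FALSE], freqs = sp$freqs,
                 fs = sp$fs, condition = sp$condition, finger = sp$finger,
                 centers = sp$centers, trial = sp$trial,
                 labels = sp$labels[channels]),
            class = "spectrum_set")
}

# subset the epochs of a spectrum_set by finger pair
pair_spectra <- function(sp, pair) {
  subset_spectra(sp, sp$finger %in% pair)
}

#' Rest-condition control decoding
#'
#' Runs the identical decoding procedure on rest epochs labeled by the
#' finger moved after them; on data whose effects are confined to the cue
#' windows this must stay at chance.
#'
#' @param sp_rest rest-epoch `spectrum_set` restricted to the pair.
#' @param sp_movement the pair's movement epochs (normalization/PCA group).
#' @param ... passed to [crossval_pairwise()].
#' @return a `decoding_result`.
#' @export
rest_control_decoding <- function(sp_rest, sp_movement = NULL, ...) {
  if (dim(sp_rest$psd)[1] == 0L) stop("empty rest epoch set")
  crossval_pairwise(sp_rest, sp_aux = sp_movement, ...)
}
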