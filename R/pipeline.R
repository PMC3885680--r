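# End-to-end orchestration: simulate -> preprocess -> detect -> features ->
# decode -> report, with provenance-stamped artifacts.

# tiny FNV-1a hash over the serialized object (hex string); used to stamp
# artifacts with their generating configuration. The 32-bit multiply is done
# in 16-bit halves so every intermediate stays exact in doubles.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- ((16777619 * hi) %% 65536 * 65536 + 16777619 * lo) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param synth a [synth_config()] describing the synthetic dataset (real
#'   recordings can be decoded by calling the stage functions directly).
#' @param detector a [detector_params()].
#' @param f_max spectral upper bound in Hz (default `min(125, fs/2)`).
#' @param line_exclude exclude line-frequency bins from the PCA.
#' @param pcs principal components used as features.
#' @param channel_strategy,channels,top_k see [select_channels()];
#'   `channels = NULL` with `fixed_set` uses the generator's planted signal
#'   channels.
#' @param folds,reps cross-validation settings.
#' @param n_perm label permutations for the empirical guessing level
#'   (0 skips the permutation test; the analytic interval is always
#'   reported).
#' @param alpha significance level.
#' @param seed master seed for the decode/stats stages.
#' @param out_dir artifact directory (`NULL` = no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), detector = detector_params(),
                            f_max = NULL, line_exclude = TRUE, pcs = 1:3,
                            channel_strategy = "fixed_set", channels = NULL,
                            top_k = 50L, folds = 5L, reps = 20L,
                            n_perm = 0L, alpha = 0.05, seed = 1L,
                            out_dir = NULL) {
  if (folds < 2L) stop("folds must be at least 2")
  if (reps < 1L) stop("reps must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(inherits(synth, "synth_config"), inherits(detector, "detector_params"))
  cfg <- list(synth = synth, detector = detector, f_max = f_max,
              line_exclude = line_exclude, pcs = pcs,
              channel_strategy = channel_strategy, channels = channels,
              top_k = top_k, folds = as.integer(folds),
              reps = as.integer(reps), n_perm = as.integer(n_perm),
              alpha = alpha, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full decoding pipeline
#'
#' Generates (or accepts) a dataset, applies the preprocessing chain
#' (0.3 Hz high-pass, 60 Hz notch, common average reference), detects
#' movement peaks from the kinematic traces, extracts movement and rest
#' epochs, computes Hanning-window PSDs, and decodes every pair of fingers
#' with spectral-PCA projection features, reporting per-pair accuracies,
#' chance bounds and significance. Deterministic given the master seed.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-generated output of [generate_dataset()]
#'   (skips simulation).
#' @return list of class `pipeline_report`: `report` (per-pair data.frame),
#'   `events`, `trials`, `results` (list of `decoding_result`), `hash`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  if (is.null(dataset)) dataset <- generate_dataset(config$synth)
  cf <- config$synth
  rec <- dataset$recording
  rec <- highpass(rec)
  rec <- notch(rec, harmonics = rec$fs >= 500)
  rec <- common_average_reference(rec)

  events <- detect_all_fingers(dataset$kinematics, cf$fs, dataset$trials,
                               config$detector)
  eps <- extract_epochs(rec, events, dataset$trials)
  f_max <- config$f_max %||% min(125, cf$fs / 2)
  sp_mov <- psd_hanning(eps$movement, f_max)
  sp_rest <- psd_hanning(eps$rest, f_max)
  # NULL lets the PCA apply its default mask (line bins + Nyquist bin)
  keep <- if (config$line_exclude) NULL else rep(TRUE, length(sp_mov$freqs))

  channels <- config$channels %||% cf$signal_channels
  pairs <- utils::combn(cf$fingers, 2L)
  results <- list()
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    pair <- pairs[, j]
    spm <- pair_spectra(sp_mov, pair)
    spr <- pair_spectra(sp_rest, pair)
    res <- crossval_pairwise(spm, spr, pcs = config$pcs,
                             channel_strategy = config$channel_strategy,
                             channels = channels, top_k = config$top_k,
                             folds = config$folds, reps = config$reps,
                             seed = config$seed + j, keep_bins = keep)
    ci <- guessing_ci(res$m, config$alpha)
    guess <- 0.5
    if (config$n_perm > 0L) {
      model <- fit_feature_model(spm, spr, keep_bins = keep)
      w <- apply_feature_model(model, spm, config$pcs)
      fm <- flatten_weights(w, seq_len(dim(w)[2]))
      guess <- empirical_guessing(fm, spm$finger, n_perm = config$n_perm,
                                  seed = config$seed + 1000L + j,
                                  folds = config$folds)$level
    }
    st <- if (length(res$da) >= 2L)
      suppressWarnings(significance_tests(res$da, guessing = guess))
    else list(p_value = NA_real_)
    results[[paste(pair, collapse = "_vs_")]] <- res
    rows[[j]] <- data.frame(pair = paste(pair, collapse = " vs "),
                            da_mean = res$da_mean, da_sd = res$da_sd,
                            m = res$m, guessing = guess,
                            ci_lower = ci[1], ci_upper = ci[2],
                            p_value = st$p_value,
                            significant = res$da_mean > ci[2],
                            row.names = NULL)
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report, events = events,
                        trials = dataset$trials, results = results,
                        hash = hash, config = config),
                   class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d pairs, config %s\n", nrow(x$report), x$hash))
  print(x$report, digits = 4)
  invisible(x)
}

# run the bipolar detector on every finger trace against its own cue trials
detect_all_fingers <- function(kinematics, fs, trials, params,
                               exclude_trials = integer(0)) {
  evs <- lapply(rownames(kinematics), function(f) {
    filt <- bandpass_kinematic(kinematics[f, ], fs, band = params$band)
    detect_peaks(filt, fs, trials, params, finger = f,
                 exclude_trials = exclude_trials)
  })
  ev <- do.call(rbind, lapply(evs, `[[`, "events"))
  event_set(ev$time, ev$finger, ev$trial, ev$amplitude, "bipolar")
}

write_pipeline_artifacts <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) { df$config_hash <- x$hash; df }
  write_event_set(x$events, file.path(out_dir, "events.tsv"))
  write_trial_table(x$trials, file.path(out_dir, "trials.tsv"))
  rep_rows <- do.call(rbind, lapply(names(x$results), function(nm) {
    r <- x$results[[nm]]
    data.frame(pair = nm, repetition = seq_along(r$da), da = r$da)
  }))
  write.table(stamp(rep_rows), file.path(out_dir, "da_repetitions.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write.table(stamp(x$report), file.path(out_dir, "report.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  summary <- list(config_hash = x$hash,
                  seed = x$config$seed,
                  package_version = as.character(utils::packageVersion("fingerbci")),
                  report = x$report)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(out_dir)
}

#' Export a per-channel topography table
#'
#' Writes per-channel values (e.g. first-PC projection weights or r-squared
#' maps) as a two-column CSV (`channel`, `value`), with no spatial
#' interpolation.
#'
#' @param values numeric vector, one value per channel.
#' @param labels channel labels, same length.
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
export_topography <- function(values, labels, path) {
  if (length(values) != length(labels))
    stop("`values` and `labels` lengths differ")
  d <- data.frame(channel = labels, value = values)
  write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' Command-line entry point
#'
#' Subcommand interface mirroring the pipeline stages:
#' `simulate`, `detect`, `all` (full pipeline + report). Arguments:
#' `--config <json>` (a JSON file of [pipeline_config()] fields),
#' `--out <dir>`, `--seed <int>`.
#'
#' @param argv character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the pipeline report (for `all`).
#' @export
pipeline_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) stop("usage: <simulate|detect|all> [--config f] [--out d] [--seed s]")
  cmd <- argv[1]
  opt <- function(name, default = NULL) {
    i <- which(argv == paste0("--", name))
    if (length(i)) argv[i + 1L] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "pipeline_out")
  cfg_path <- opt("config")
  cfg <- if (!is.null(cfg_path)) pipeline_config_from_json(cfg_path) else
    pipeline_config(synth = synth_config(seed = seed), seed = seed,
                    out_dir = out)
  cfg$out_dir <- out
  switch(cmd,
         simulate = {
           ds <- generate_dataset(cfg$synth)
           dir.create(out, showWarnings = FALSE, recursive = TRUE)
           write_recording(ds$recording, file.path(out, "recording.tsv"))
           write_trial_table(ds$trials, file.path(out, "trials.tsv"))
           write_event_set(ds$ground_truth$events,
                           file.path(out, "ground_truth_events.tsv"))
           invisible(NULL)
         },
         detect = {
           ds <- generate_dataset(cfg$synth)
           ev <- detect_all_fingers(ds$kinematics, cfg$synth$fs, ds$trials,
                                    cfg$detector)
           dir.create(out, showWarnings = FALSE, recursive = TRUE)
           write_event_set(ev, file.path(out, "events.tsv"))
           invisible(NULL)
         },
         all = invisible(run_pipeline(cfg)),
         stop(sprintf("unknown subcommand '%s'", cmd)))
}

# load a pipeline_config from a flat JSON file of field overrides
pipeline_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- do.call(synth_config, j$synth %||% list())
  det <- do.call(detector_params, j$detector %||% list())
  rest <- j[setdiff(names(j), c("synth", "detector"))]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(rest), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, c(list(synth = syn, detector = det), rest))
}
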