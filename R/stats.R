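#' Empirical guessing level by label permutation
#'
#' Randomly permutes the class labels `n_perm` times and re-runs the full
#' classification procedure on each permuted dataset; the mean accuracy over
#' permutations is the empirical guessing level.
#'
#' @param feature_matrix epochs x features matrix.
#' @param labels two-level label vector.
#' @param n_perm number of label permutations (the protocol value is 500;
#'   tests use fewer for speed).
#' @param seed master seed.
#' @param folds,reps cross-validation settings of each permutation run.
#' @param ... passed to [crossval_pairwise()] (e.g. classifier grids).
#' @return list of class `guessing_estimate`: `level` (mean permuted
#'   accuracy), `per_permutation`, `m`, plus the analytic interval at
#'   `alpha = 0.05` from [guessing_ci()].
#' @export
empirical_guessing <- function(feature_matrix, labels, n_perm = 500L,
                               seed = 1L, folds = 5L, reps = 1L, ...) {
  if (n_perm < 2L) stop("n_perm must be at least 2")
  labels <- as.character(labels)
  set.seed(seed)
  acc <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    yp <- labels[sample.int(length(labels))]
    res <- crossval_pairwise(feature_matrix = feature_matrix, labels = yp,
                             folds = folds, reps = reps,
                             seed = sample.int(.Machine$integer.max, 1L), ...)
    acc[p] <- res$da_mean
  }
  m <- length(labels)
  ci <- guessing_ci(m)
  structure(list(level = mean(acc), per_permutation = acc, m = m,
                 n_permutations = n_perm, ci_lower = ci[1], ci_upper = ci[2]),
            class = "guessing_estimate")
}

#' Binomial confidence interval around two-class chance
#'
#' Normal-approximation interval `p0 +/- z_{1-alpha/2} sqrt(p0 (1-p0) / m)`
#' for the accuracy of guessing in a two-class problem with `m` classified
#' movements; a decoder is significantly better than chance when its DA
#' exceeds the upper bound.
#'
#' @param m total number of movements from the two conditions compared.
#' @param alpha significance level.
#' @param p0 nominal chance level.
#' @return numeric `c(lower, upper)`.
#' @export
guessing_ci <- function(m, alpha = 0.05, p0 = 0.5) {
  if (m < 1) stop("m must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  z <- qnorm(1 - alpha / 2)
  hw <- z * sqrt(p0 * (1 - p0) / m)
  c(lower = p0 - hw, upper = p0 + hw)
}

#' Significance tests of decoding accuracies
#'
#' One-sample Student t-test of a repetition-level DA distribution against
#' the guessing level, and paired t-tests between feature conditions. With
#' zero variance in the accuracies an exact comparison is reported with a
#' warning (p = 0 if every value differs from the reference in the same
#' direction, p = 1 if all equal).
#'
#' @param da numeric vector of per-repetition decoding accuracies.
#' @param guessing guessing level to test against.
#' @param da_paired optional second DA vector for a paired comparison.
#' @param alternative test alternative, default `"greater"` for the
#'   one-sample test against chance and `"two.sided"` for paired tests.
#' @return list with `p_value`, `statistic`, `method`.
#' @export
significance_tests <- function(da, guessing = 0.5, da_paired = NULL,
                               alternative = NULL) {
  if (length(da) < 2L) stop("need at least 2 repetition-level accuracies")
  if (is.null(da_paired)) {
    if (is.null(alternative)) alternative <- "greater"
    if (sd(da) == 0) {
      warning("zero variance in accuracies; exact comparison fallback")
      p <- if (all(da == guessing)) 1 else {
        if (alternative == "greater") as.numeric(!(da[1] > guessing))
        else if (alternative == "less") as.numeric(!(da[1] < guessing))
        else as.numeric(da[1] == guessing)
      }
      return(list(p_value = p, statistic = NA_real_,
                  method = "exact fallback (degenerate)"))
    }
    tt <- t.test(da, mu = guessing, alternative = alternative)
  } else {
    if (is.null(alternative)) alternative <- "two.sided"
    d <- da - da_paired
    if (sd(d) == 0) {
      warning("zero variance in paired differences; exact comparison fallback")
      return(list(p_value = as.numeric(d[1] == 0), statistic = NA_real_,
                  method = "exact fallback (degenerate)"))
    }
    tt <- t.test(da, da_paired, paired = TRUE, alternative = alternative)
  }
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       method = tt$method)
}

#' Column means and sample standard deviations of an accuracy table
#'
#' Report-parity arithmetic for per-subject accuracy tables: per-column mean
#' and (n-1)-denominator standard deviation, rounded to 2 decimals.
#'
#' @param m numeric matrix or data.frame, subjects x conditions.
#' @param digits rounding for report parity.
#' @return data.frame with `column`, `mean`, `sd`.
#' @export
table_stats <- function(m, digits = 2L) {
  m <- as.matrix(m)
  if (ncol(m) == 0L || nrow(m) == 0L) stop("empty table")
  if (any(apply(m, 2L, function(x) all(is.na(x))))) stop("empty column")
  data.frame(column = colnames(m) %||% sprintf("V%d", seq_len(ncol(m))),
             mean = round(colMeans(m, na.rm = TRUE), digits),
             sd = round(apply(m, 2L, sd, na.rm = TRUE), digits),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
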