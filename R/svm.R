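# Max-margin binary classification with a radial-basis kernel, trained by
# sequential minimal optimization on the standard C-SVM dual.

rbf_kernel <- function(x, z = NULL, gamma) {
  if (is.null(z)) z <- x
  xx <- rowSums(x^2); zz <- rowSums(z^2)
  d2 <- outer(xx, zz, "+") - 2 * tcrossprod(x, z)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a binary RBF-kernel max-margin classifier
#'
#' Solves the C-SVM dual by sequential minimal optimization (maximal
#' violating pair working-set selection). Labels may be any two-level
#' vector; internally they map to -1/+1.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y two-level label vector.
#' @param cost penalty parameter C.
#' @param gamma RBF kernel width; default `1 / ncol(x)`.
#' @param eps SMO stopping tolerance on the duality gap.
#' @return object of class `svm_rbf`.
#' @export
svm_rbf <- function(x, y, cost = 1, gamma = NULL, eps = 1e-3) {
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("exactly two classes required")
  yi <- ifelse(as.character(y) == lev[2], 1L, -1L)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  K <- rbf_kernel(x, gamma = gamma)
  sol <- cpp_smo_solve(K, yi, cost, eps)
  structure(list(x = x, y = yi, levels = lev, alpha = sol$alpha,
                 rho = sol$rho, objective = sol$objective,
                 cost = cost, gamma = gamma), class = "svm_rbf")
}

#' @param object an `svm_rbf` fit.
#' @param newdata feature matrix to classify.
#' @param ... unused.
#' @rdname svm_rbf
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Kt <- rbf_kernel(object$x, newdata, object$gamma)
  dec <- drop(crossprod(Kt, object$alpha * object$y)) - object$rho
  object$levels[ifelse(dec >= 0, 2L, 1L)]
}

# decision values (signed margin) for diagnostics
svm_decision <- function(object, newdata) {
  Kt <- rbf_kernel(object$x, as.matrix(newdata), object$gamma)
  drop(crossprod(Kt, object$alpha * object$y)) - object$rho
}

# stratified fold assignment: within each class, a random permutation is
# dealt round-robin into `k` folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid-search the penalty and kernel width
#'
#' Internal stratified cross-validation on the training data over a log2
#' grid of `cost` and `gamma`; the combination with the best mean validation
#' accuracy (first in grid order on ties) is refit on the full training set.
#' The default grid is a coarse log2 grid scaled to the feature dimension;
#' the classical exhaustive grid (`cost` 2^-5..2^15, `gamma` 2^-15..2^3) can
#' be passed explicitly when compute allows.
#'
#' @param x training features (rows = samples), already standardized.
#' @param y two-level labels.
#' @param cost_grid,gamma_grid candidate values.
#' @param inner_folds folds of the internal validation split.
#' @return an `svm_rbf` fit with `$grid` (the search table) attached.
#' @export
svm_rbf_grid <- function(x, y, cost_grid = 2^seq(-3, 9, by = 4),
                         gamma_grid = NULL, inner_folds = 3L) {
  x <- as.matrix(x)
  if (is.null(gamma_grid)) gamma_grid <- 2^seq(-2, 2, by = 2) / ncol(x)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  fold <- stratified_folds(as.character(y), inner_folds)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hits <- 0L; tot <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) next
      fit <- svm_rbf(x[tr, , drop = FALSE], y[tr],
                     cost = grid$cost[g], gamma = grid$gamma[g])
      pr <- predict(fit, x[!tr, , drop = FALSE])
      hits <- hits + sum(pr == as.character(y[!tr]))
      tot <- tot + sum(!tr)
    }
    acc[g] <- if (tot) hits / tot else 0
  }
  best <- which.max(acc)
  fit <- svm_rbf(x, y, cost = grid$cost[best], gamma = grid$gamma[best])
  fit$grid <- cbind(grid, accuracy = acc)
  fit
}
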