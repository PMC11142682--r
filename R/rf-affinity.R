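# Random forest affinity: the fraction of trees that place two points in
# the same terminal bin. The forest itself comes from ranger behind a thin
# contract (leaf assignments + predictions); the affinity computation is
# bespoke.

#' Train a random forest exposing terminal-bin assignments
#'
#' Classification forests are probability forests with minimum bin size 1;
#' regression forests use a minimum bin size of `ceiling(0.10 n)` by
#' default (too small a bin size dilutes the affinity between similar
#' samples in the regression setting).
#'
#' @param x samples-by-features matrix.
#' @param y labels: a factor (or coercible) with at least two classes for
#'   classification, numeric for regression.
#' @param task `"classification"` or `"regression"`.
#' @param min_bin_size minimum number of samples per terminal bin;
#'   defaults to 1 (classification) or `ceiling(0.10 * n)` (regression).
#' @param n_trees number of trees.
#' @param seed integer seed making the fit deterministic.
#' @param ... forwarded to [ranger::ranger()].
#' @return an object of class `haar_forest`.
#' @export
fit_forest <- function(x, y, task = c("classification", "regression"),
                       min_bin_size = NULL, n_trees = 100, seed = NULL, ...) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two samples")
  if (length(y) != nrow(x)) stop("labels are not aligned to samples")
  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) < 2L)
      stop("classification requires at least two classes")
    if (is.null(min_bin_size)) min_bin_size <- 1L
  } else {
    y <- as.numeric(y)
    if (is.null(min_bin_size)) min_bin_size <- ceiling(0.10 * nrow(x))
  }
  colnames(x) <- feature_names(x)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees,
    min.bucket = min_bin_size,
    min.node.size = if (task == "classification") 1 else NULL,
    probability = task == "classification",
    seed = seed,
    num.threads = 1L,
    ...
  )
  structure(list(model = fit, task = task, levels = levels(y), y = y,
                 min_bin_size = min_bin_size, n_trees = n_trees,
                 seed = seed),
            class = "haar_forest")
}

feature_names <- function(x) {
  if (is.null(colnames(x))) paste0("f", seq_len(ncol(x))) else colnames(x)
}

#' Terminal-bin assignments of points in a fitted forest
#'
#' @param forest a `haar_forest` object.
#' @param x samples-by-features matrix (any points, not just training).
#' @return an integer matrix, samples by trees, of terminal node ids.
#' @export
leaf_assignments <- function(forest, x) {
  stopifnot(inherits(forest, "haar_forest"))
  x <- as.matrix(x)
  colnames(x) <- feature_names(x)
  stats::predict(forest$model, data = x, type = "terminalNodes",
                 num.threads = 1L)$predictions
}

#' Random forest affinity matrix
#'
#' `A(i, j)` is the fraction of trees placing points `i` and `j` in the
#' same terminal bin; the dissimilarity is `1 - A`. When `x` stacks
#' training and test points this is the full joint affinity used by the
#' transductive surrogate.
#'
#' @inheritParams leaf_assignments
#' @return a symmetric matrix with unit diagonal and entries in
#'   `{0, 1/M, ..., 1}`.
#' @export
rf_affinity <- function(forest, x) {
  tn <- leaf_assignments(forest, x)
  n <- nrow(tn)
  M <- ncol(tn)
  A <- matrix(0, n, n)
  for (m in seq_len(M)) {
    f <- tn[, m]
    A <- A + outer(f, f, "==")
  }
  A / M
}

#' Forest predictions
#'
#' @param forest a `haar_forest` object.
#' @param x samples-by-features matrix.
#' @return for regression, a numeric vector; for classification, a list
#'   with `class` (factor) and `prob` (samples-by-classes matrix).
#' @export
rf_predict <- function(forest, x) {
  stopifnot(inherits(forest, "haar_forest"))
  x <- as.matrix(x)
  colnames(x) <- feature_names(x)
  p <- stats::predict(forest$model, data = x, num.threads = 1L)$predictions
  if (forest$task == "regression") return(as.numeric(p))
  cls <- factor(forest$levels[max.col(p, ties.method = "first")],
                levels = forest$levels)
  list(class = cls, prob = p)
}

#' Kernel random-forest estimate (local average)
#'
#' Affinity-weighted average of training labels:
#' \eqn{\hat f(x) = \sum_i A(x, x_i) y_i / \sum_i A(x, x_i)}. Rows with
#' zero total affinity fall back to the global training-label mean.
#'
#' @param a affinities to the training points: a vector, or a matrix with
#'   one row per query point.
#' @param y_train numeric training labels (encode classes as 0/1 for
#'   binary classification).
#' @return numeric estimate(s).
#' @export
kerf_estimate <- function(a, y_train) {
  if (length(y_train) == 0L) stop("empty training set")
  if (is.vector(a)) a <- matrix(a, nrow = 1L)
  if (ncol(a) != length(y_train))
    stop("affinity row length does not match the number of training labels")
  tot <- rowSums(a)
  est <- as.numeric(a %*% y_train) / tot
  est[tot <= 0] <- mean(y_train)
  est
}
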