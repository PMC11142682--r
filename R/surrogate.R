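# Interpretable RF surrogate: Euclidean distances in the learned
# embedding are thresholded at one to form a Haar affinity, sparsified to
# the floor-sqrt(n) nearest training neighbours, and used as a local
# average estimator of the training labels.

#' Haar affinity between embedded points
#'
#' Pairwise Euclidean distances between embedding columns, thresholded at
#' a maximum of one; the affinity is one minus the thresholded distance.
#'
#' @param e1 query embedding (coordinates-by-samples).
#' @param e2 reference embedding; defaults to `e1`.
#' @return an affinity matrix in `[0, 1]`, query rows by reference
#'   columns.
#' @export
haar_affinity <- function(e1, e2 = e1) {
  e1 <- as.matrix(e1)
  e2 <- as.matrix(e2)
  if (nrow(e1) != nrow(e2)) stop("embeddings live in different spaces")
  d2 <- outer(colSums(e1^2), colSums(e2^2), "+") - 2 * crossprod(e1, e2)
  d <- sqrt(pmax(d2, 0))
  1 - pmin(d, 1)
}

#' Keep the k largest affinities per row
#'
#' Zeroes all but the `k` largest entries of each row (ties broken by
#' lowest column index), the K-nearest-neighbour sparsification of the
#' surrogate's affinity. The default neighbour count used elsewhere in
#' the package is `floor(sqrt(n))`.
#'
#' @param a an affinity vector or matrix (query rows by `n` reference
#'   columns).
#' @param k number of neighbours to keep; `k >= n` keeps all (with a
#'   warning when `k > n`).
#' @param exclude optional integer vector, one reference column per row to
#'   exclude before selection (self-affinity when scoring a training
#'   point).
#' @return the sparsified affinities, same shape as `a`.
#' @export
knn_sparsify <- function(a, k, exclude = NULL) {
  was_vec <- is.null(dim(a))
  if (was_vec) a <- matrix(a, nrow = 1L)
  n <- ncol(a)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) {
    warning("k exceeds the number of reference points; keeping all")
    k <- n
  }
  out <- matrix(0, nrow(a), n, dimnames = dimnames(a))
  for (i in seq_len(nrow(a))) {
    row <- a[i, ]
    if (!is.null(exclude)) row[exclude[i]] <- -Inf
    keep <- order(-row, seq_len(n))[seq_len(k)]
    out[i, keep] <- pmax(a[i, keep], 0)
    if (!is.null(exclude)) out[i, exclude[i]] <- 0
  }
  if (was_vec) out[1L, ] else out
}

# Local-average estimates from a (sparsified) affinity matrix.
# Classification encodes classes one-vs-rest and returns both scores and
# argmax classes; binary thresholds P(second level) at 0.5.
surrogate_estimates <- function(A, y, task, lev = NULL) {
  if (task == "regression") {
    return(list(prediction = kerf_estimate(A, as.numeric(y))))
  }
  y <- factor(y, levels = lev)
  if (nlevels(y) == 2L) {
    score <- kerf_estimate(A, as.numeric(y == lev[2L]))
    cls <- factor(ifelse(score > 0.5, lev[2L], lev[1L]), levels = lev)
    return(list(prediction = cls, score = score))
  }
  sc <- vapply(lev, function(cl) kerf_estimate(A, as.numeric(y == cl)),
               numeric(nrow(as.matrix(A))))
  sc <- matrix(sc, ncol = length(lev), dimnames = list(NULL, lev))
  cls <- factor(lev[max.col(sc, ties.method = "first")], levels = lev)
  list(prediction = cls, score = sc)
}

# One pipeline run evaluated along a whole sparsity path. The matching
# pursuit solution for budget s is the s-prefix of the run with the
# largest budget, so a single fit serves every s in the grid.
surrogate_path <- function(x_train, y, x_test, tree, basis, s_grid, task,
                           mode = "transductive", n_trees = 100,
                           min_bin_size = NULL, seed = NULL, k = NULL,
                           scaling = "mp") {
  s_grid <- sort(unique(as.integer(s_grid)))
  forest <- fit_forest(t(x_train), y, task = task,
                       min_bin_size = min_bin_size, n_trees = n_trees,
                       seed = seed)
  n_tr <- ncol(x_train)
  transductive <- mode == "transductive"
  x_all <- if (transductive) cbind(x_train, x_test) else x_train
  A_rf <- rf_affinity(forest, t(x_all))
  gt <- gram_from_dissimilarity(1 - A_rf)
  H_tr <- haar_coordinates(x_train, basis)
  H_te <- haar_coordinates(x_test, basis)
  H_fit <- if (transductive) cbind(H_tr, H_te) else H_tr
  mp <- nn_matching_pursuit(gt, build_dictionary(H_fit), s = max(s_grid),
                            scaling = scaling)
  if (is.null(k)) k <- max(1L, floor(sqrt(n_tr)))
  Hn_tr <- H_tr[-nrow(H_tr), , drop = FALSE]
  Hn_te <- H_te[-nrow(H_te), , drop = FALSE]
  lev <- forest$levels

  per_s <- lapply(s_grid, function(s) {
    take <- seq_len(min(s, length(mp$nodes)))
    w <- numeric(nrow(Hn_tr))
    for (i in take) w[mp$nodes[i]] <- w[mp$nodes[i]] + mp$coefficients[i]
    sup <- which(w > 0)
    E_tr <- Hn_tr[sup, , drop = FALSE] * sqrt(w[sup])
    E_te <- Hn_te[sup, , drop = FALSE] * sqrt(w[sup])
    A_h <- knn_sparsify(haar_affinity(E_te, E_tr), min(k, n_tr))
    c(surrogate_estimates(A_h, y, task, lev), list(s = s, weights = w))
  })
  names(per_s) <- as.character(s_grid)

  rf_out <- rf_predict(forest, t(x_test))
  list(forest = forest, mp = mp, per_s = per_s, rf = rf_out, k = k,
       gram = gt)
}

#' Surrogate prediction for new samples
#'
#' Predicts the labels of test samples with the interpretable random
#' forest surrogate: a forest is trained on the labeled samples, node
#' weights are learned by matching pursuit, and predictions are
#' affinity-weighted averages of the `floor(sqrt(n))` nearest training
#' labels in the learned embedding. In the default transductive mode the
#' weights are learned from the joint train+test RF affinity (training
#' labels only enter the local average); the inductive mode learns them
#' from the training affinity alone.
#'
#' @param x_train,x_test leaves-by-samples compositional matrices aligned
#'   to `tree`.
#' @param y training labels.
#' @param tree a `haar_phylo` object.
#' @param s sparsity budget.
#' @param task `"classification"` or `"regression"`.
#' @param mode `"transductive"` (default) or `"inductive"`.
#' @param n_trees,min_bin_size,seed forwarded to [fit_forest()].
#' @param k neighbour count; default `floor(sqrt(n_train))`.
#' @param basis optional precomputed [haar_basis()].
#' @param scaling see [nn_matching_pursuit()].
#' @return a list with `prediction` (and `score` for classification),
#'   `rf_prediction`/`rf_score` from the underlying forest, `weights`,
#'   `solution` (the `haar_mp`) and `k`.
#' @export
surrogate_predict <- function(x_train, y, x_test, tree, s = 10,
                              task = c("classification", "regression"),
                              mode = c("transductive", "inductive"),
                              n_trees = 100, min_bin_size = NULL,
                              seed = NULL, k = NULL, basis = NULL,
                              scaling = c("mp", "printed")) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  stopifnot(inherits(tree, "haar_phylo"))
  if (is.null(basis)) basis <- haar_basis(tree)
  path <- surrogate_path(x_train, y, x_test, tree, basis, s_grid = s,
                         task = task, mode = mode, n_trees = n_trees,
                         min_bin_size = min_bin_size, seed = seed, k = k,
                         scaling = scaling)
  res <- path$per_s[[as.character(s)]]
  rf <- path$rf
  list(
    prediction = res$prediction,
    score = res$score,
    rf_prediction = if (task == "regression") rf else rf$class,
    rf_score = if (task == "regression") rf else rf$prob,
    weights = res$weights,
    solution = path$mp,
    k = path$k
  )
}

#' Choose the sparsity by an inner validation split
#'
#' Splits the training data into an inner training part and a selection
#' part (stratified for classification), fits the surrogate along the
#' sparsity grid, and returns the best-scoring budget: highest selection
#' accuracy for classification, lowest squared error for regression. Ties
#' go to the smallest budget.
#'
#' @param x leaves-by-samples compositional matrix.
#' @param y labels.
#' @param tree a `haar_phylo` object.
#' @param grid candidate sparsity budgets (default 1..10).
#' @param inner_fraction fraction held out for selection (default 0.25).
#' @param task,mode,n_trees,min_bin_size,seed,basis,scaling as in
#'   [surrogate_predict()].
#' @return the selected sparsity (integer).
#' @export
tune_sparsity <- function(x, y, tree, grid = 1:10, inner_fraction = 0.25,
                          task = c("classification", "regression"),
                          mode = "transductive", n_trees = 100,
                          min_bin_size = NULL, seed = NULL, basis = NULL,
                          scaling = "mp") {
  task <- match.arg(task)
  if (length(grid) == 0L) stop("empty sparsity grid")
  grid <- sort(unique(as.integer(grid)))
  if (length(grid) == 1L) return(grid)
  if (is.null(basis)) basis <- haar_basis(tree)
  n <- ncol(x)
  idx_sel <- holdout_indices(y, inner_fraction, task, seed)
  path <- surrogate_path(x[, -idx_sel, drop = FALSE], y[-idx_sel],
                         x[, idx_sel, drop = FALSE], tree, basis,
                         s_grid = grid, task = task, mode = mode,
                         n_trees = n_trees, min_bin_size = min_bin_size,
                         seed = seed, scaling = scaling)
  score <- vapply(path$per_s, function(r) {
    if (task == "classification") {
      mean(r$prediction == y[idx_sel])
    } else {
      -mean((r$prediction - y[idx_sel])^2)
    }
  }, numeric(1))
  grid[which.max(score)]   # first max: smallest s wins ties
}

# Held-out indices for the inner selection split (stratified per class
# for classification).
holdout_indices <- function(y, fraction, task, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  if (task == "classification") {
    idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      m <- max(1L, round(length(ix) * fraction))
      sample(ix, m)
    }), use.names = FALSE)
  } else {
    idx <- sample(n, max(2L, round(n * fraction)))
  }
  sort(idx)
}

# Fold assignment: stratified per class for classification, plain random
# for regression. Errors when a class is too small to appear in every
# fold.
stratified_folds <- function(y, k, task = "classification", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (task == "classification") {
    cnt <- table(y)
    if (any(cnt < k))
      stop("class(es) with fewer than ", k,
           " members cannot be stratified into ", k, " folds: ",
           paste(names(cnt)[cnt < k], collapse = ", "))
    for (ix in split(seq_len(n), y)) {
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Repeated stratified cross-validation of the surrogate against its RF
#'
#' Runs `folds`-fold cross-validation repeated over `repeats`
#' randomizations (5 x 5 = 25 splits by default). Each split tunes the
#' sparsity on the training portion via [tune_sparsity()], fits the
#' surrogate, and scores both the surrogate and the underlying random
#' forest on the held-out portion.
#'
#' @inheritParams surrogate_predict
#' @param x leaves-by-samples compositional matrix.
#' @param folds number of folds (default 5; 80/20 splits).
#' @param repeats number of fold randomizations (default 5).
#' @param grid sparsity grid for tuning (default 1..10).
#' @param tune set `FALSE` to skip tuning and use `max(grid)` everywhere.
#' @return a data frame with one row per split: `repeat_`, `fold`, `s`
#'   (selected sparsity), and for classification `surrogate_accuracy`,
#'   `surrogate_auc`, `rf_accuracy`, `rf_auc` (AUC is `NA` for more than
#'   two classes); for regression `surrogate_mse` and `rf_mse`.
#' @export
cross_validate <- function(x, y, tree, folds = 5, repeats = 5, grid = 1:10,
                           task = c("classification", "regression"),
                           mode = "transductive", n_trees = 100,
                           min_bin_size = NULL, seed = 1, basis = NULL,
                           tune = TRUE, scaling = "mp") {
  task <- match.arg(task)
  stopifnot(inherits(tree, "haar_phylo"))
  if (task == "classification") y <- factor(y)
  if (is.null(basis)) basis <- haar_basis(tree)
  base_seed <- as.integer(abs(seed)) %% 1000000L
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, task, seed = base_seed * 31L + r)
    for (f in seq_len(folds)) {
      split_seed <- base_seed * 17L + r * 101L + f
      te <- which(fold == f)
      x_tr <- x[, -te, drop = FALSE]
      y_tr <- y[-te]
      s_best <- if (tune) {
        tune_sparsity(x_tr, y_tr, tree, grid = grid, task = task,
                      mode = mode, n_trees = n_trees,
                      min_bin_size = min_bin_size, seed = split_seed,
                      basis = basis, scaling = scaling)
      } else {
        max(grid)
      }
      pr <- surrogate_predict(x_tr, y_tr, x[, te, drop = FALSE], tree,
                              s = s_best, task = task, mode = mode,
                              n_trees = n_trees,
                              min_bin_size = min_bin_size,
                              seed = split_seed, basis = basis,
                              scaling = scaling)
      if (task == "classification") {
        binary <- nlevels(y) == 2L
        sur_auc <- rf_auc <- NA_real_
        if (binary && length(unique(y[te])) == 2L) {
          sur_auc <- classification_metrics(y[te], pr$score)$auc
          rf_auc <- classification_metrics(y[te],
                                           pr$rf_score[, levels(y)[2L]])$auc
        }
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = r, fold = f, s = s_best,
          surrogate_accuracy = mean(pr$prediction == y[te]),
          surrogate_auc = sur_auc,
          rf_accuracy = mean(pr$rf_prediction == y[te]),
          rf_auc = rf_auc
        )
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = r, fold = f, s = s_best,
          surrogate_mse = mean((pr$prediction - y[te])^2),
          rf_mse = mean((pr$rf_prediction - y[te])^2)
        )
      }
    }
  }
  do.call(rbind, rows)
}
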