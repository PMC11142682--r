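# Metric learning: extract a Gram target from the RF dissimilarity by
# classical MDS, form the dictionary of Haar coordinate outer products
# (held implicitly through the coordinate matrix), and run non-negative
# matching pursuit to learn sparse node weights.

#' Gram target from a dissimilarity matrix (classical MDS / PCoA)
#'
#' Double-centers the squared dissimilarities, clips negative eigenvalues
#' to zero, and returns the Gram matrix `G = Z'Z` of the principal
#' coordinates `Z`. When `D` is Euclidean the pairwise distances of the
#' columns of `Z` reproduce `D` exactly.
#'
#' @param D a symmetric dissimilarity matrix with zero diagonal (e.g.
#'   `1 - A` for an RF affinity `A`), or a [stats::dist].
#' @param tol relative eigenvalue tolerance for retaining components.
#' @return an object of class `gram_target`: list with `G` (n-by-n PSD,
#'   doubly centered), `Z` (components-by-n coordinates) and `eig` (all
#'   eigenvalues of the centered matrix).
#' @export
gram_from_dissimilarity <- function(D, tol = 1e-9) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(D)
  B <- D * D
  B <- B - rowMeans(B)
  B <- t(t(B) - colMeans(B))    # together with the row pass: J (D*D) J
  B <- -0.25 * (B + t(B))       # -1/2 scaling, symmetrized exactly
  e <- eigen(B, symmetric = TRUE)
  emax <- max(e$values, 0)
  keep <- which(e$values > tol * max(emax, 1e-300))
  if (length(keep) == 0L) {
    Z <- matrix(0, 0L, n)
  } else {
    Z <- t(e$vectors[, keep, drop = FALSE]) * sqrt(e$values[keep])
  }
  G <- crossprod(Z)
  dimnames(G) <- dimnames(D)
  structure(list(G = G, Z = Z, eig = e$values), class = "gram_target")
}

#' Haar outer-product dictionary
#'
#' Column `i` of the dictionary is `vec(h_i h_i')` for `h_i` the i-th row
#' of the (root-free) Haar coordinate matrix; columns are `n^2`-vectors
#' and are never materialized. Inner products against a symmetric matrix
#' `S` are computed as `h_i' S h_i` and the column norm is `||h_i||^2`.
#'
#' @param H Haar coordinate matrix without the root row (post-order node
#'   indices as row names), e.g. `haar_coordinates(x, basis)` minus its
#'   last row.
#' @return an object of class `haar_dictionary` with `H` and `norms`.
#' @export
build_dictionary <- function(H) {
  H <- as.matrix(H)
  if (identical(rownames(H)[nrow(H)], "root"))
    H <- H[-nrow(H), , drop = FALSE]
  if (!all(is.finite(H))) stop("coordinate matrix contains non-finite values")
  structure(list(H = H, norms = rowSums(H * H)), class = "haar_dictionary")
}

# <vec(S), M_i> = h_i' S h_i for every dictionary column at once.
dictionary_inner <- function(dict, S) {
  unname(rowSums((dict$H %*% S) * dict$H))
}

#' Non-negative matching pursuit over the Haar dictionary
#'
#' Greedy sparse approximation of a Gram target `G` by
#' \eqn{K_w = \sum_v w_v h_v h_v'}: at each iteration the dictionary
#' column with the largest normalized projection onto the residual is
#' selected (ties broken by lowest post-order index), its coefficient is
#' removed from the residual, and iteration stops after `s` selections or
#' when no positive projection remains (an empty solution is legal). The
#' same node may be selected more than once; repeated selections
#' accumulate into one weight.
#'
#' @param G a `gram_target`, or a symmetric numeric matrix.
#' @param dict a `haar_dictionary`, or the coordinate matrix to build one
#'   from.
#' @param s maximum number of iterations (sparsity budget).
#' @param scaling `"mp"` (default) uses the standard matching-pursuit
#'   coefficient \eqn{v = \langle R, M\rangle / \|M\|^2}, under which the
#'   removed energy \eqn{\|R_i - R_{i+1}\| = |v|\,\|M\|} is
#'   non-increasing; `"printed"` uses the raw inner product
#'   \eqn{v = \langle R, M\rangle} for comparison.
#' @return an object of class `haar_mp`: `nodes` (selected post-order
#'   indices, in selection order), `coefficients`, `importance`
#'   (`|v| * ||M||`, the energy removed per iteration), `residual_norms`
#'   (Frobenius norms, starting at `||G||_F`) and `weights` (named vector
#'   of accumulated positive weights over the distinct selected nodes).
#' @export
nn_matching_pursuit <- function(G, dict, s, scaling = c("mp", "printed")) {
  scaling <- match.arg(scaling)
  if (inherits(G, "gram_target")) G <- G$G
  G <- as.matrix(G)
  if (!inherits(dict, "haar_dictionary")) dict <- build_dictionary(dict)
  if (s < 1L) stop("sparsity budget s must be at least 1")
  H <- dict$H
  norms <- unname(dict$norms)       # ||M_i|| = ||h_i||^2
  active <- norms > .Machine$double.eps
  if (!any(active)) stop("dictionary has no nonzero columns")
  node_ids <- rownames(H)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(H)))

  R <- G
  sel <- integer(0)
  coef <- numeric(0)
  rnorms <- norm(R, "F")
  for (i in seq_len(s)) {
    ip <- dictionary_inner(dict, R)   # <R, M_j>
    score <- ip / norms               # <R, M_j / ||M_j||>
    score[!active] <- -Inf
    if (max(score) <= 0) break
    j <- which.max(score)             # first max = lowest index tie-break
    v <- if (scaling == "mp") ip[j] / norms[j]^2 else ip[j]
    R <- R - v * tcrossprod(H[j, ])
    sel <- c(sel, j)
    coef <- c(coef, v)
    rnorms <- c(rnorms, norm(R, "F"))
  }
  w <- vapply(split(coef, sel), sum, numeric(1))
  names(w) <- node_ids[as.integer(names(w))]
  structure(list(
    nodes = as.integer(node_ids[sel]),
    coefficients = coef,
    importance = abs(coef) * norms[sel],
    residual_norms = rnorms,
    weights = w,
    scaling = scaling
  ), class = "haar_mp")
}

#' @export
print.haar_mp <- function(x, ...) {
  cat("Non-negative matching pursuit solution:",
      length(x$coefficients), "iteration(s),",
      length(x$weights), "distinct node(s)\n")
  if (length(x$nodes)) {
    cat("  nodes (selection order):", paste(x$nodes, collapse = ", "), "\n")
    cat("  importances:",
        paste(signif(x$importance, 4), collapse = ", "), "\n")
  }
  cat("  residual norms:",
      paste(signif(x$residual_norms, 4), collapse = " -> "), "\n")
  invisible(x)
}

#' Learn adaptive Haar-like node weights from labeled samples
#'
#' The full metric-learning pipeline: train a random forest on the
#' samples, extract its affinity and dissimilarity, recover a Gram target
#' by classical MDS, project the samples onto the Haar-like basis, and run
#' non-negative matching pursuit to find at most `s` weighted internal
#' nodes whose kernel best reproduces the forest's affinity structure.
#'
#' @param x leaves-by-samples compositional matrix aligned to `tree` (see
#'   [align_abundance()]).
#' @param y labels (factor for classification, numeric for regression).
#' @param tree a `haar_phylo` object.
#' @param s sparsity budget (number of matching-pursuit iterations).
#' @param task `"classification"` or `"regression"`.
#' @param n_trees,min_bin_size,seed forwarded to [fit_forest()].
#' @param basis optional precomputed [haar_basis()].
#' @param scaling see [nn_matching_pursuit()].
#' @return an object of class `adaptive_haar_fit`: `weights` (full-length
#'   node weight vector, root 0), `solution` (the `haar_mp` object),
#'   `forest`, `gram`, `basis`.
#' @examples
#' \donttest{
#' tr <- random_binary_tree(40, seed = 1)
#' sim <- planted_classification(tr, n_per_class = 30, seed = 1)
#' fit <- learn_weights(sim$x, sim$labels, tr, s = 3, seed = 1)
#' fit$solution$nodes  # most important bifurcations, best first
#' }
#' @export
learn_weights <- function(x, y, tree, s = 10,
                          task = c("classification", "regression"),
                          n_trees = 100, min_bin_size = NULL, seed = NULL,
                          basis = NULL, scaling = c("mp", "printed")) {
  task <- match.arg(task)
  scaling <- match.arg(scaling)
  stopifnot(inherits(tree, "haar_phylo"))
  if (ncol(x) != length(y)) stop("labels are not aligned to samples")
  if (is.null(basis)) basis <- haar_basis(tree)
  forest <- fit_forest(t(x), y, task = task, min_bin_size = min_bin_size,
                       n_trees = n_trees, seed = seed)
  A <- rf_affinity(forest, t(x))
  gt <- gram_from_dissimilarity(1 - A)
  H <- haar_coordinates(x, basis)
  mp <- nn_matching_pursuit(gt, build_dictionary(H), s = s, scaling = scaling)
  w <- numeric(tree$n_node)
  w[as.integer(names(mp$weights))] <- mp$weights
  names(w) <- colnames(basis$Phi)
  structure(list(weights = w, solution = mp, forest = forest,
                 gram = gt, basis = basis),
            class = "adaptive_haar_fit")
}

#' @export
print.adaptive_haar_fit <- function(x, ...) {
  cat("Adaptive Haar-like metric fit\n")
  print(x$solution)
  invisible(x)
}

#' Export learned node weights as a table
#'
#' @param fit an `adaptive_haar_fit` object.
#' @return a data frame with columns `node` (post-order index), `weight`,
#'   `importance` (of the node's first selection) and `rank` (selection
#'   order).
#' @export
weight_table <- function(fit) {
  stopifnot(inherits(fit, "adaptive_haar_fit"))
  mp <- fit$solution
  first <- !duplicated(mp$nodes)
  data.frame(
    node = mp$nodes[first],
    weight = as.numeric(mp$weights[as.character(mp$nodes[first])]),
    importance = mp$importance[first],
    rank = seq_len(sum(first))
  )
}
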