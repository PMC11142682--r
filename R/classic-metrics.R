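# Fixed (non-adaptive) phylogenetic metrics: the phylogenetic covariance
# matrix, the DPCoA distance, the spectral node weights lambda_v, and the
# Haar-like distance they induce.

#' Phylogenetic covariance matrix
#'
#' `C(i, j)` is the total branch length on the path from the least common
#' ancestor of leaves `i` and `j` up to the out-root; the diagonal holds
#' root-to-leaf path lengths. This is the Brownian-motion trait covariance
#' of the tree.
#'
#' @param tree a `haar_phylo` object.
#' @return a symmetric positive semidefinite `|L| x |L|` matrix in
#'   branch-length units.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "haar_phylo"))
  n <- tree$n_tip
  depth <- node_depths(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip_label, tree$tip_label))
  for (j in seq_len(n - 1L)) {
    tl <- node_tips(tree, tree$child[j, 1L])
    tr_ <- node_tips(tree, tree$child[j, 2L])
    C[tl, tr_] <- depth[n + j]   # cross pairs have LCA exactly at node j
    C[tr_, tl] <- depth[n + j]
  }
  diag(C) <- depth[seq_len(n)]
  C
}

#' DPCoA distance between two compositional samples
#'
#' \eqn{\sqrt{(x_1-x_2)^T C (x_1-x_2)}} for the phylogenetic covariance
#' `C` (or any symmetric PSD matrix).
#'
#' @param x1,x2 compositional vectors aligned to `C`.
#' @param C covariance matrix, e.g. from [phylo_covariance()].
#' @param squared return the quadratic form itself instead of its square
#'   root (PERMANOVA-style analyses use squared distances).
#' @return a non-negative scalar; 0 iff `x1 - x2` lies in the null space
#'   of `C`.
#' @export
dpcoa_distance <- function(x1, x2, C, squared = FALSE) {
  if (length(x1) != length(x2) || length(x1) != nrow(C))
    stop("dimension mismatch between samples and covariance matrix")
  d <- x1 - x2
  q <- drop(crossprod(d, C %*% d))
  q <- max(q, 0)
  if (squared) q else sqrt(q)
}

#' Spectral node weights of the Haar-like distance
#'
#' \eqn{\lambda_v = \varphi_v^T C \varphi_v}, the diagonal of
#' \eqn{\Phi^T C \Phi}. On large trees this congruence nearly diagonalizes
#' the phylogenetic covariance, motivating the Haar-like distance as a
#' proxy for DPCoA.
#'
#' @param tree a `haar_phylo` object.
#' @param basis optional precomputed [haar_basis()].
#' @param C optional precomputed [phylo_covariance()].
#' @return a non-negative numeric vector, one entry per internal node in
#'   post-order (the last entry is the root wavelet's).
#' @export
lambda_weights <- function(tree, basis = NULL, C = NULL) {
  stopifnot(inherits(tree, "haar_phylo"))
  if (is.null(basis)) basis <- haar_basis(tree)
  if (is.null(C)) C <- phylo_covariance(tree)
  lam <- Matrix::colSums((C %*% basis$Phi) * basis$Phi)
  lam <- pmax(as.numeric(lam), 0)
  names(lam) <- colnames(basis$Phi)
  lam
}

#' Haar-like distance between two compositional samples
#'
#' \eqn{\sqrt{\sum_{v} \lambda_v \langle x_1-x_2, \varphi_v\rangle^2}}
#' over bifurcations (the root term vanishes for compositional data and is
#' excluded).
#'
#' @param x1,x2 compositional vectors aligned to the basis leaf order.
#' @param basis a `haar_basis` object.
#' @param lambda node weights from [lambda_weights()].
#' @param squared return the squared distance.
#' @return a non-negative scalar.
#' @export
haar_distance <- function(x1, x2, basis, lambda, squared = FALSE) {
  adaptive_distance(x1, x2, basis, lambda, squared = squared)
}

#' Pairwise beta-diversity distances
#'
#' Square matrix of pairwise Haar-like, adaptive Haar-like, or DPCoA
#' distances between the columns of a compositional abundance matrix.
#'
#' @param x a leaves-by-samples compositional matrix.
#' @param tree a `haar_phylo` object.
#' @param metric `"haar"`, `"dpcoa"` or `"adaptive"`.
#' @param weights node weights; required for `metric = "adaptive"`,
#'   defaults to [lambda_weights()] for `"haar"`.
#' @param basis optional precomputed [haar_basis()].
#' @return a [stats::dist] object over samples.
#' @export
beta_diversity <- function(x, tree, metric = c("haar", "dpcoa", "adaptive"),
                           weights = NULL, basis = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(tree, "haar_phylo"))
  if (metric == "dpcoa") {
    C <- phylo_covariance(tree)
    K <- crossprod(x, C %*% x)
    q <- diag(K)
    d2 <- pmax(outer(q, q, "+") - 2 * K, 0)
    return(stats::as.dist(sqrt(d2)))
  }
  if (is.null(basis)) basis <- haar_basis(tree)
  if (is.null(weights)) {
    if (metric == "adaptive")
      stop("metric = \"adaptive\" requires learned weights")
    weights <- lambda_weights(tree, basis = basis)
  }
  E <- haar_embed(x, basis, weights)
  stats::dist(t(E))
}
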