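# The adaptive Haar-like kernel/distance for an arbitrary non-negative
# node-weight vector, and the Euclidean embedding they induce. The root
# node always carries weight 0: its coordinate is constant across
# compositional samples and is disregarded.

# Normalize a weight vector to full length n_node with the root entry
# forced to 0. Accepts length n_node (root last) or n_node - 1 (non-root
# only, post-order).
check_weights <- function(w, basis) {
  n <- basis$tree$n_node
  w <- as.numeric(w)
  if (length(w) == n - 1L) w <- c(w, 0)
  if (length(w) != n)
    stop("weight vector must have one entry per internal node (", n,
         " or ", n - 1L, " excluding the root)")
  if (any(w < 0)) stop("node weights must be non-negative")
  w[n] <- 0
  w
}

#' Adaptive Haar-like kernel matrix
#'
#' \eqn{K_w = H^T \mathrm{diag}(w) H} with \eqn{H = \Phi^T X} the
#' Haar-like coordinates; symmetric PSD and linear in `w`.
#'
#' @param x leaves-by-samples compositional matrix, or a precomputed
#'   coordinate matrix from [haar_coordinates()] (detected by row count).
#' @param basis a `haar_basis` object.
#' @param w non-negative node weights (root entry forced to 0).
#' @return an `n x n` kernel matrix.
#' @export
adaptive_kernel <- function(x, basis, w) {
  w <- check_weights(w, basis)
  H <- as_coordinates(x, basis)
  crossprod(H * sqrt(w))
}

# Leaf-abundance and coordinate matrices are both |L| x n here (the basis
# is square); a matrix whose last row is named "root" is already a
# coordinate matrix, anything else is projected.
as_coordinates <- function(x, basis) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (identical(rownames(x)[nrow(x)], "root")) return(x)
  haar_coordinates(x, basis)
}

#' Adaptive Haar-like distance between two samples
#'
#' \eqn{d_w(x_1,x_2) = \sqrt{\sum_v w_v \langle x_1-x_2,
#' \varphi_v\rangle^2}}. With `w` equal to the spectral weights
#' \eqn{\lambda} this is the fixed Haar-like distance; with unit weights
#' on all bifurcations it equals the Euclidean distance between
#' compositional samples.
#'
#' @param x1,x2 compositional vectors aligned to the basis leaf order.
#' @param basis a `haar_basis` object.
#' @param w non-negative node weights.
#' @param squared return the squared distance.
#' @return a non-negative scalar.
#' @export
adaptive_distance <- function(x1, x2, basis, w, squared = FALSE) {
  w <- check_weights(w, basis)
  h <- haar_coordinates(cbind(x1, x2), basis)
  d2 <- sum(w * (h[, 1L] - h[, 2L])^2)
  if (squared) d2 else sqrt(d2)
}

#' Euclidean embedding under a learned metric
#'
#' Returns the coordinates \eqn{\sqrt{w_v}\,H(v,\cdot)} for the nodes in
#' the support of `w`; pairwise Euclidean distances between columns equal
#' the adaptive Haar-like distance and the Gram matrix of the columns is
#' the adaptive kernel.
#'
#' @inheritParams adaptive_kernel
#' @return a `|support(w)| x n` matrix with post-order node indices as row
#'   names. An empty support yields a 0-row embedding with a warning.
#' @export
haar_embed <- function(x, basis, w) {
  w <- check_weights(w, basis)
  H <- as_coordinates(x, basis)
  sup <- which(w > 0)
  if (length(sup) == 0L)
    warning("empty weight support: embedding has zero rows")
  H[sup, , drop = FALSE] * sqrt(w[sup])
}
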