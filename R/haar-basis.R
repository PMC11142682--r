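#' Haar-like wavelet basis of a phylogeny
#'
#' Builds the orthonormal Haar-like basis of an out-rooted binary
#' phylogeny. One wavelet per internal node, in post-order: bifurcation
#' \eqn{v} carries the two-valued, zero-sum, unit-norm wavelet
#' \deqn{\varphi_v = a_v \text{ on } L(v_+),\quad -b_v \text{ on } L(v_-),}
#' with \eqn{a_v = \sqrt{|L(v_-)| / (|L(v_+)|(|L(v_+)|+|L(v_-)|))}} and
#' \eqn{b_v} symmetric; the out-root carries the constant wavelet
#' \eqn{1/\sqrt{|L|}}. The projection scale
#' \eqn{c_v = \sqrt{|L(v_+)||L(v_-)|/(|L(v_+)|+|L(v_-)|)}} turns
#' differences of subtree mean abundances into wavelet coordinates.
#'
#' @param tree a `haar_phylo` object.
#' @return an object of class `haar_basis`: list with `Phi` (sparse
#'   `|L| x |I|` matrix, one column per internal node in post-order; the
#'   last column is the constant root wavelet), `c` (the projection
#'   constants, `NA` for the root column) and `tree`.
#' @examples
#' tr <- parse_newick("(a:1,b:1):0;")
#' b <- haar_basis(tr)
#' as.matrix(b$Phi)   # columns (1/sqrt(2), -1/sqrt(2)) and constant
#' @export
haar_basis <- function(tree) {
  stopifnot(inherits(tree, "haar_phylo"))
  n <- tree$n_tip
  ii <- vector("list", n)
  xx <- vector("list", n)
  cv <- numeric(n)
  for (j in seq_len(n - 1L)) {
    lp <- node_tips(tree, tree$child[j, 1L])
    lm <- node_tips(tree, tree$child[j, 2L])
    np <- length(lp)
    nm <- length(lm)
    a <- sqrt(nm / (np * (np + nm)))
    b <- sqrt(np / (nm * (np + nm)))
    ii[[j]] <- c(lp, lm)
    xx[[j]] <- c(rep(a, np), rep(-b, nm))
    cv[j] <- sqrt(np * nm / (np + nm))
  }
  ii[[n]] <- seq_len(n)
  xx[[n]] <- rep(1 / sqrt(n), n)
  cv[n] <- NA_real_
  Phi <- Matrix::sparseMatrix(
    i = unlist(ii),
    j = rep(seq_len(n), lengths(ii)),
    x = unlist(xx),
    dims = c(n, n),
    dimnames = list(tree$tip_label,
                    c(as.character(seq_len(n - 1L)), "root"))
  )
  structure(list(Phi = Phi, c = cv, tree = tree), class = "haar_basis")
}

#' @export
print.haar_basis <- function(x, ...) {
  cat("Haar-like wavelet basis:", nrow(x$Phi), "leaves,",
      ncol(x$Phi), "wavelets (post-order; last = constant root wavelet)\n")
  invisible(x)
}

#' Haar-like coordinates of samples
#'
#' Projects samples onto the Haar-like basis: the coordinate of sample
#' \eqn{x} at bifurcation \eqn{v} is
#' \eqn{c_v(\mathrm{avg}(x; L(v_+)) - \mathrm{avg}(x; L(v_-)))}, computed
#' in a single post-order subtree-sum pass in `O(|L| n)`; the root row is
#' the projection onto the constant wavelet (equal to
#' \eqn{1/\sqrt{|L|}} for every compositional sample).
#'
#' @param x a leaves-by-samples matrix aligned to the basis leaf order
#'   (see [align_abundance()]), or a single vector.
#' @param basis a `haar_basis` object.
#' @return a `|I| x n` matrix of coordinates; row names are post-order
#'   node indices, the last row is `"root"`.
#' @export
haar_coordinates <- function(x, basis) {
  stopifnot(inherits(basis, "haar_basis"))
  tree <- basis$tree
  n <- tree$n_tip
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (nrow(x) != n)
    stop("abundance matrix has ", nrow(x), " rows but the tree has ", n,
         " leaves")
  if (!is.null(rownames(x)) && !identical(rownames(x), tree$tip_label)) {
    if (!all(tree$tip_label %in% rownames(x)))
      stop("row names do not match the tree's tip labels")
    x <- x[tree$tip_label, , drop = FALSE]
  }
  m <- ncol(x)
  sums <- matrix(0, 2L * n, m)           # subtree sums per node
  sums[seq_len(n), ] <- x
  sizes <- integer(2L * n)
  sizes[seq_len(n)] <- 1L
  H <- matrix(0, n, m,
              dimnames = list(c(as.character(seq_len(n - 1L)), "root"),
                              colnames(x)))
  for (j in seq_len(n - 1L)) {
    c1 <- tree$child[j, 1L]
    c2 <- tree$child[j, 2L]
    s1 <- sums[c1, ]
    s2 <- sums[c2, ]
    sums[n + j, ] <- s1 + s2
    sizes[n + j] <- sizes[c1] + sizes[c2]
    H[j, ] <- basis$c[j] * (s1 / sizes[c1] - s2 / sizes[c2])
  }
  H[n, ] <- sums[n + n - 1L, ] / sqrt(n)
  H
}
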