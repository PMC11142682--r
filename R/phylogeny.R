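# Node id convention used throughout the package:
#   leaves 1..n in Newick (tip label) order,
#   internal node j of the post-order traversal is n + j, j = 1..n.
# For an out-rooted binary tree with n leaves there are exactly n internal
# nodes: n - 1 bifurcations (post-order indices 1..n-1) plus the out-root
# (post-order index n), whose single child is the top bifurcation.

#' Parse a Newick string into an out-rooted binary phylogeny
#'
#' Reads a rooted Newick tree, resolves multifurcations deterministically
#' (leftmost pairing, zero-length edges), and inserts a degree-one out-root
#' above the original root when needed. The out-root carries the constant
#' wavelet of the Haar-like basis; every bifurcation carries a difference
#' wavelet.
#'
#' @param text a Newick string.
#' @param strict if `TRUE`, refuse multifurcating input instead of resolving
#'   it.
#' @return an object of class `haar_phylo` with components `tip_label`,
#'   `n_tip`, `n_node` (internal nodes including the out-root), `child`
#'   (two-column matrix of child node ids per internal node, post-order),
#'   `edge_len` (length of the edge above each node; 0 for the out-root)
#'   and `tips` (descendant leaf indices per internal node).
#' @details Missing branch lengths default to 1 with a warning (they affect
#'   the phylogenetic covariance, not the basis). A Newick root edge, when
#'   present, becomes the edge between the out-root and the original root;
#'   otherwise that edge has length 0. Leaf order is the Newick
#'   left-to-right order and the post-order index is stable across runs for
#'   the same input.
#' @seealso [read_phylogeny()], [write_newick()], [leaf_sets()]
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1):0;")
#' tr$n_tip    # 4
#' tr$n_node   # 4: three bifurcations plus the out-root
#' @export
parse_newick <- function(text, strict = FALSE) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  from_ape(tr, strict = strict)
}

#' Read an out-rooted binary phylogeny from a Newick file
#'
#' @param file path to a Newick file.
#' @inheritParams parse_newick
#' @return a `haar_phylo` object; see [parse_newick()].
#' @export
read_phylogeny <- function(file, strict = FALSE) {
  tr <- tryCatch(ape::read.tree(file),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("cannot parse Newick file: ", file)
  from_ape(tr, strict = strict)
}

#' Ensure a tree is out-rooted
#'
#' A `haar_phylo` is out-rooted by construction and returned unchanged; an
#' `ape::phylo` object is converted (inserting a degree-one out-root above
#' its root when the root has two or more children).
#'
#' @param tree a `haar_phylo` or `ape::phylo` object.
#' @param strict refuse multifurcations instead of resolving them.
#' @return a `haar_phylo` object.
#' @export
ensure_out_rooted <- function(tree, strict = FALSE) {
  if (inherits(tree, "haar_phylo")) return(tree)
  from_ape(tree, strict = strict)
}

# Convert an ape phylo object into the package representation.
from_ape <- function(tr, strict = FALSE) {
  if (!inherits(tr, "phylo")) stop("input must be an ape 'phylo' object")
  n <- length(tr$tip.label)
  if (n < 2L) stop("tree must have at least two leaves (no bifurcation exists)")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("input tree has no branch lengths; defaulting all to 1")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) stop("missing branch length on an edge")
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")

  n_poly <- sum(tabulate(tr$edge[, 1L]) > 2L)
  if (n_poly > 0L) {
    if (strict)
      stop("tree contains ", n_poly, " multifurcation(s); strict mode refuses them")
    warning("resolving ", n_poly,
            " multifurcation(s) deterministically with zero-length edges")
    tr <- ape::multi2di(tr, random = FALSE)
  }
  tr <- ape::collapse.singles(tr, root.edge = TRUE)

  m <- tr$Nnode
  kids <- vector("list", n + m)
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1L]
    kids[[p]] <- c(kids[[p]], tr$edge[r, 2L])
  }
  elen <- numeric(n + m)
  elen[tr$edge[, 2L]] <- tr$edge.length
  top <- setdiff(unique(tr$edge[, 1L]), tr$edge[, 2L])
  if (length(top) != 1L) stop("tree is not rooted")
  out_len <- if (!is.null(tr$root.edge)) tr$root.edge else 0

  # post-order over the subtree below the out-root (reverse of a
  # root-right-left preorder)
  ord <- integer(n + m)
  stack <- integer(n + m)
  oi <- 0L
  sp <- 1L
  stack[1L] <- top
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    ord[oi <- oi + 1L] <- v
    if (v > n) {
      k <- kids[[v]]
      if (length(k) != 2L)
        stop("internal node without exactly two children after resolution")
      stack[sp + 1L] <- k[1L]
      stack[sp + 2L] <- k[2L]
      sp <- sp + 2L
    }
  }
  post <- rev(ord[seq_len(oi)])
  post_int <- post[post > n]
  d <- length(post_int)
  if (d != n - 1L) stop("internal error: expected ", n - 1L, " bifurcations")

  myid <- integer(n + m)
  myid[seq_len(n)] <- seq_len(n)
  myid[post_int] <- n + seq_len(d)

  child <- matrix(NA_integer_, n, 2L)
  for (j in seq_len(d)) child[j, ] <- myid[kids[[post_int[j]]]]
  child[n, 1L] <- n + d  # out-root -> top bifurcation

  edge_len <- numeric(2L * n)
  edge_len[seq_len(n)] <- elen[seq_len(n)]
  if (d > 1L) edge_len[n + seq_len(d - 1L)] <- elen[post_int[seq_len(d - 1L)]]
  edge_len[n + d] <- out_len
  edge_len[2L * n] <- 0

  tips <- vector("list", n)
  tip_of <- function(id) if (id <= n) id else tips[[id - n]]
  for (j in seq_len(d)) {
    tips[[j]] <- c(tip_of(child[j, 1L]), tip_of(child[j, 2L]))
  }
  tips[[n]] <- tips[[d]]

  structure(list(
    tip_label = tr$tip.label,
    n_tip = n,
    n_node = n,
    child = child,
    edge_len = edge_len,
    tips = tips,
    n_polytomies = n_poly
  ), class = "haar_phylo")
}

# Descendant leaf indices of an arbitrary node id.
node_tips <- function(tree, id) {
  if (id <= tree$n_tip) id else tree$tips[[id - tree$n_tip]]
}

#' Left/right descendant leaf sets of every bifurcation
#'
#' @param tree a `haar_phylo` object.
#' @param labels return tip labels (default) rather than leaf indices.
#' @return a list over bifurcations (named by post-order index); each
#'   element is `list(left = , right = )` with the two disjoint descendant
#'   leaf sets.
#' @export
leaf_sets <- function(tree, labels = TRUE) {
  stopifnot(inherits(tree, "haar_phylo"))
  n <- tree$n_tip
  out <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    l <- node_tips(tree, tree$child[j, 1L])
    r <- node_tips(tree, tree$child[j, 2L])
    if (labels) {
      l <- tree$tip_label[l]
      r <- tree$tip_label[r]
    }
    out[[j]] <- list(left = l, right = r)
  }
  names(out) <- as.character(seq_len(n - 1L))
  out
}

#' Write a phylogeny to Newick
#'
#' The edge between the out-root and the top bifurcation is emitted as a
#' Newick root edge when non-zero, so that parse -> write -> parse
#' round-trips topology, labels and branch lengths.
#'
#' @param tree a `haar_phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  stopifnot(inherits(tree, "haar_phylo"))
  n <- tree$n_tip
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  str_of <- function(id) {
    if (id <= n) {
      paste0(tree$tip_label[id], ":", fmt(tree$edge_len[id]))
    } else {
      j <- id - n
      paste0("(", str_of(tree$child[j, 1L]), ",", str_of(tree$child[j, 2L]),
             "):", fmt(tree$edge_len[id]))
    }
  }
  s <- paste0(str_of(tree$child[n, 1L]), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @export
print.haar_phylo <- function(x, ...) {
  cat("Out-rooted binary phylogeny ('haar_phylo')\n")
  cat("  leaves:        ", x$n_tip, "\n")
  cat("  internal nodes:", x$n_node,
      sprintf("(%d bifurcations + out-root)\n", x$n_tip - 1L))
  if (x$n_polytomies > 0L)
    cat("  resolved polytomies:", x$n_polytomies, "\n")
  cat("  total branch length:", sum(x$edge_len), "\n")
  invisible(x)
}

# Root-to-node path lengths (depth of the out-root is 0); used by the
# phylogenetic covariance and nowhere else.
node_depths <- function(tree) {
  n <- tree$n_tip
  depth <- numeric(2L * n)
  for (j in rev(seq_len(n))) {      # reverse post-order: parents first
    id <- n + j
    ch <- tree$child[j, ]
    ch <- ch[!is.na(ch)]
    depth[ch] <- depth[id] + tree$edge_len[ch]
  }
  depth
}
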