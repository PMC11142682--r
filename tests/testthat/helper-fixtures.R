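# Shared fixtures: tiny hand trees, random compositional samples, and a
# generator of multifurcating Newick strings for stress-testing the
# parser and basis.

balanced4 <- function() parse_newick("((a:1,b:1):1,(c:1,d:1):1):0;")

two_leaf <- function() parse_newick("(a:2,b:3):1;")

# random compositional columns (leaves x n)
rcomp <- function(n_leaves, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rgamma(n_leaves * n, shape = 1), n_leaves, n)
  sweep(x, 2, colSums(x), "/")
}

# Newick text of a random tree in which some internal edges were
# collapsed into multifurcations
rtree_poly_newick <- function(n, seed, collapse_frac = 0.25) {
  set.seed(seed)
  tr <- ape::rtree(n)
  if (n > 3) {
    internal <- which(tr$edge[, 2] > n)
    zap <- sample(internal, max(1, floor(length(internal) * collapse_frac)))
    tr$edge.length[zap] <- 0
    tr <- ape::di2multi(tr)
  }
  ape::write.tree(tr)
}

# dense n x n Haar-like basis matrix (independent of the sparse path)
dense_phi <- function(tree) as.matrix(haar_basis(tree)$Phi)
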