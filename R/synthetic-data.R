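# Synthetic phylogenies and abundance datasets with planted clade-level
# signal. Classes (or a continuous covariate) differ by a mass shift
# between the two child subtrees of chosen internal nodes, on top of a
# Dirichlet baseline composition with Dirichlet mixture noise.

#' Random binary phylogeny
#'
#' Coalescent-style topology: starting from the leaves, two uniformly
#' chosen lineages are merged until one remains; branch lengths are drawn
#' from `branch_dist` (exponential with mean 1 by default). Deterministic
#' under `seed`.
#'
#' @param n_leaves number of leaves (>= 2). Leaves are labeled
#'   `t1 ... tn`.
#' @param seed integer seed.
#' @param branch_dist function of one argument (count) returning branch
#'   lengths.
#' @return a `haar_phylo` object with `n_leaves - 1` bifurcations plus
#'   the out-root.
#' @export
random_binary_tree <- function(n_leaves, seed = NULL,
                               branch_dist = function(n) stats::rexp(n)) {
  if (n_leaves < 2L) stop("need at least two leaves")
  if (!is.null(seed)) set.seed(seed)
  node <- paste0("t", seq_len(n_leaves))
  len <- branch_dist(n_leaves)
  while (length(node) > 1L) {
    pick <- sample.int(length(node), 2L)
    merged <- paste0("(", node[pick[1L]], ":", format(len[pick[1L]], digits = 15),
                     ",", node[pick[2L]], ":", format(len[pick[2L]], digits = 15),
                     ")")
    keep <- setdiff(seq_along(node), pick)
    node <- c(node[keep], merged)
    len <- c(len[keep], if (length(keep)) branch_dist(1L) else 0)
  }
  parse_newick(paste0(node, ";"))
}

#' Pick a planted signal node
#'
#' Chooses the bifurcation whose clade size is closest to
#' `fraction * |L|` among those whose children both have at least
#' `min_child_leaves` descendant leaves (ties: lowest post-order index);
#' a deterministic, reasonably balanced split to carry planted signal.
#'
#' @param tree a `haar_phylo` object.
#' @param fraction target clade size as a fraction of the leaf count.
#' @param min_child_leaves minimum leaves per child subtree.
#' @return a post-order bifurcation index.
#' @export
select_planted_node <- function(tree, fraction = 0.25, min_child_leaves = 2L) {
  stopifnot(inherits(tree, "haar_phylo"))
  n <- tree$n_tip
  target <- fraction * n
  best <- NA_integer_
  best_gap <- Inf
  for (j in seq_len(n - 1L)) {
    n1 <- length(node_tips(tree, tree$child[j, 1L]))
    n2 <- length(node_tips(tree, tree$child[j, 2L]))
    if (n1 < min_child_leaves || n2 < min_child_leaves) next
    gap <- abs(n1 + n2 - target)
    if (gap < best_gap) {
      best_gap <- gap
      best <- j
    }
  }
  if (is.na(best)) stop("no bifurcation with large enough children")
  best
}

# Move a fraction `frac` of the mass under the right child of each planted
# node to the left child, proportionally within each subtree; total mass
# is preserved.
shift_mass <- function(x, tree, nodes, frac) {
  n <- tree$n_tip
  for (v in nodes) {
    if (v >= n) stop("planted node must be a bifurcation, not the root")
    lp <- node_tips(tree, tree$child[v, 1L])
    lm <- node_tips(tree, tree$child[v, 2L])
    shift <- frac * sum(x[lm])
    x[lm] <- x[lm] * (1 - frac)
    mp <- sum(x[lp])
    if (mp > 0) {
      x[lp] <- x[lp] * (1 + shift / mp)
    } else {
      x[lp] <- shift / length(lp)
    }
  }
  x
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  s <- sum(g)
  if (s <= 0) return(rep(1 / k, k))
  g / s
}

#' Planted-clade classification data
#'
#' Two balanced classes of compositional samples on the leaves of `tree`.
#' A dataset-level baseline composition is drawn from a symmetric
#' Dirichlet; for class `"B"` a fraction `delta` of the mass under each
#' planted node is moved from the right to the left child subtree
#' (proportionally within subtrees). Each sample mixes its class
#' composition with an independent Dirichlet draw:
#' `x = (1 - noise) * p_class + noise * u`. With `delta = 0` the classes
#' are exchangeable.
#'
#' @param tree a `haar_phylo` object.
#' @param nodes planted bifurcation indices (post-order); default
#'   [select_planted_node()].
#' @param delta effect size in `[0, 1]`: fraction of subtree mass shifted
#'   between the children of each planted node.
#' @param n_per_class samples per class.
#' @param concentration symmetric Dirichlet concentration of the baseline
#'   and noise draws.
#' @param noise mixing weight of the per-sample Dirichlet noise in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return a list with `x` (leaves-by-samples compositional matrix),
#'   `labels` (factor `"A"/"B"`) and `nodes` (the planted indices).
#' @export
planted_classification <- function(tree, nodes = NULL, delta = 0.5,
                                   n_per_class = 100, concentration = 1,
                                   noise = 0.1, seed = NULL) {
  stopifnot(inherits(tree, "haar_phylo"), delta >= 0, delta <= 1,
            noise >= 0, noise <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nodes)) nodes <- select_planted_node(tree)
  n <- tree$n_tip
  p0 <- rdirichlet1(n, concentration)
  pB <- shift_mass(p0, tree, nodes, delta)
  n_tot <- 2L * n_per_class
  x <- matrix(0, n, n_tot,
              dimnames = list(tree$tip_label, paste0("s", seq_len(n_tot))))
  labels <- factor(rep(c("A", "B"), each = n_per_class))
  for (i in seq_len(n_tot)) {
    p <- if (labels[i] == "A") p0 else pB
    u <- rdirichlet1(n, concentration)
    xi <- (1 - noise) * p + noise * u
    x[, i] <- xi / sum(xi)
  }
  list(x = x, labels = labels, nodes = nodes)
}

#' Planted-clade regression data
#'
#' Compositional samples whose planted-node mass shift grows linearly
#' with a latent covariate `t` drawn uniformly from `covariate_range`;
#' the label is `t` plus optional Gaussian noise. With `noise = 0` and
#' `label_noise_sd = 0` the Haar-like coordinate at the planted node is a
#' strictly monotone function of the label.
#'
#' @inheritParams planted_classification
#' @param n number of samples.
#' @param covariate_range range of the latent covariate.
#' @param label_noise_sd standard deviation of additive label noise.
#' @return a list with `x`, `labels` (numeric) and `nodes`.
#' @export
planted_regression <- function(tree, nodes = NULL, delta = 0.5, n = 100,
                               covariate_range = c(0, 1), concentration = 1,
                               noise = 0.1, label_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(tree, "haar_phylo"), delta >= 0, delta <= 1,
            noise >= 0, noise <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nodes)) nodes <- select_planted_node(tree)
  nl <- tree$n_tip
  p0 <- rdirichlet1(nl, concentration)
  t_raw <- stats::runif(n, covariate_range[1L], covariate_range[2L])
  t01 <- (t_raw - covariate_range[1L]) / diff(range(covariate_range))
  x <- matrix(0, nl, n,
              dimnames = list(tree$tip_label, paste0("s", seq_len(n))))
  for (i in seq_len(n)) {
    p <- shift_mass(p0, tree, nodes, delta * t01[i])
    u <- rdirichlet1(nl, concentration)
    xi <- (1 - noise) * p + noise * u
    x[, i] <- xi / sum(xi)
  }
  labels <- t_raw + if (label_noise_sd > 0) {
    stats::rnorm(n, sd = label_noise_sd)
  } else 0
  list(x = x, labels = labels, nodes = nodes)
}
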