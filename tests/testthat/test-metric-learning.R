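test_that("gram extraction double-centers and reproduces Euclidean input", {
  # zero dissimilarity
  expect_equal(max(abs(gram_from_dissimilarity(matrix(0, 3, 3))$G)), 0)
  # two points at distance 1 on a line
  G <- gram_from_dissimilarity(matrix(c(0, 1, 1, 0), 2))$G
  expect_equal(unname(G), matrix(c(0.25, -0.25, -0.25, 0.25), 2))
  # Euclidean distances are reconstructed exactly
  set.seed(10)
  Z <- matrix(stats::rnorm(3 * 8), 3, 8)
  D <- as.matrix(stats::dist(t(Z)))
  gt <- gram_from_dissimilarity(D)
  q <- diag(gt$G)
  D_rec <- sqrt(pmax(outer(q, q, "+") - 2 * gt$G, 0))
  expect_lt(max(abs(D_rec - D)), 1e-8)
  # centering and factorization invariants
  expect_lt(max(abs(rowSums(gt$G))), 1e-8)
  expect_lt(max(abs(crossprod(gt$Z) - gt$G)), 1e-8)
  expect_error(gram_from_dissimilarity(matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
})

test_that("dictionary inner products follow the trace identity", {
  tr <- random_binary_tree(18, seed = 20)
  b <- haar_basis(tr)
  X <- rcomp(18, 7, seed = 20)
  H <- haar_coordinates(X, b)
  dict <- build_dictionary(H)        # drops the root row
  expect_equal(nrow(dict$H), 17L)
  # hand example: h = (1, -1) has outer-product norm 2
  expect_equal(build_dictionary(rbind(h = c(1, -1)))$norms[["h"]], 2)
  set.seed(20)
  S <- matrix(stats::rnorm(49), 7, 7)
  S <- S + t(S)
  ip <- adaphaar:::dictionary_inner(dict, S)
  for (i in c(1L, 9L, 17L)) {
    expect_equal(ip[i], drop(dict$H[i, ] %*% S %*% dict$H[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("vec(K_w) is linear in w through the dictionary columns", {
  for (seed in c(3, 15)) {
    tr <- random_binary_tree(12, seed = seed)
    b <- haar_basis(tr)
    X <- rcomp(12, 6, seed = seed)
    H <- haar_coordinates(X, b)
    Hn <- H[-12, , drop = FALSE]
    set.seed(seed)
    w <- stats::runif(11)
    # explicit M: columns are vec(h_i h_i^T)
    M <- vapply(seq_len(11), function(i) as.vector(tcrossprod(Hn[i, ])),
                numeric(36))
    K <- adaptive_kernel(X, b, c(w, 0))
    expect_lt(max(abs(as.vector(K) - M %*% w)), 1e-10)
  }
})

test_that("matching pursuit reproduces the hand-worked orthogonal case", {
  # three orthonormal coordinate rows -> orthonormal rank-one atoms
  H <- diag(3)
  rownames(H) <- as.character(1:3)
  G <- 3 * tcrossprod(H[1, ]) + 1 * tcrossprod(H[2, ])
  mp <- nn_matching_pursuit(G, H, s = 2)
  expect_equal(mp$nodes, c(1L, 2L))
  expect_equal(mp$coefficients, c(3, 1))
  expect_equal(mp$residual_norms, c(sqrt(10), 1, 0))
  expect_equal(mp$importance, c(3, 1))
  expect_equal(unname(mp$weights[c("1", "2")]), c(3, 1))
})

test_that("matching pursuit returns empty when no positive projection exists", {
  H <- diag(2)
  rownames(H) <- as.character(1:2)
  G <- -tcrossprod(H[1, ]) - 0.5 * tcrossprod(H[2, ])
  mp <- nn_matching_pursuit(G, H, s = 5)
  expect_length(mp$nodes, 0L)
  expect_length(mp$weights, 0L)
  expect_equal(mp$residual_norms, norm(G, "F"))
})

test_that("exact sparse recovery with orthogonal active columns", {
  # orthogonal (non-normalized) rows
  set.seed(33)
  H <- qr.Q(qr(matrix(stats::rnorm(64), 8, 8)))[, 1:6]
  H <- t(H) * c(1, 2, 0.5, 1.5, 1, 3)
  rownames(H) <- as.character(1:6)
  w_star <- c(0, 2.5, 0, 0.8, 0, 1.2)
  G <- crossprod(H * sqrt(w_star))
  mp <- nn_matching_pursuit(G, H, s = 3)
  w_hat <- numeric(6)
  w_hat[as.integer(names(mp$weights))] <- mp$weights
  expect_lt(max(abs(w_hat - w_star)), 1e-8)
  expect_lt(mp$residual_norms[length(mp$residual_norms)], 1e-8)
})

test_that("residual norms and importances are non-increasing", {
  tr <- random_binary_tree(40, seed = 17)
  sim <- planted_classification(tr, n_per_class = 40, seed = 17)
  fit <- learn_weights(sim$x, sim$labels, tr, s = 8, seed = 17)
  mp <- fit$solution
  expect_true(all(diff(mp$residual_norms) <= 1e-10))
  expect_true(all(diff(mp$importance) <= 1e-10))
  # importance is the energy removed per iteration
  removed <- -diff(mp$residual_norms^2)
  expect_equal(sqrt(pmax(removed, 0)), mp$importance, tolerance = 1e-6)
  expect_true(all(mp$coefficients > 0))
  expect_true(all(fit$weights >= 0))
  expect_lte(length(mp$nodes), 8L)
})

test_that("the printed-update mode subtracts raw inner products", {
  H <- diag(2) * 2          # atom norms ||M|| = 4
  rownames(H) <- as.character(1:2)
  G <- 3 * tcrossprod(H[1, ] / 2)
  mp <- nn_matching_pursuit(G, H, s = 1, scaling = "printed")
  # v = <R, M> = 3 * 4 = 12 (overshoots), importance |v| * ||M||
  expect_equal(mp$coefficients, 12)
  expect_equal(mp$importance, 48)
})

test_that("the root atom is orthogonal to centered targets", {
  tr <- random_binary_tree(20, seed = 19)
  b <- haar_basis(tr)
  X <- rcomp(20, 10, seed = 19)
  H <- haar_coordinates(X, b)
  set.seed(19)
  D <- as.matrix(stats::dist(matrix(stats::rnorm(20), 10)))
  G <- gram_from_dissimilarity(D)$G
  h_root <- H["root", ]
  expect_lt(abs(drop(h_root %*% G %*% h_root)), 1e-10)
  # and the dictionary never offers it
  mp <- nn_matching_pursuit(G, build_dictionary(H), s = 10)
  expect_false(any(mp$nodes == 20L))
})

test_that("learn_weights recovers a strongly planted node", {
  tr <- random_binary_tree(80, seed = 23)
  sim <- planted_classification(tr, delta = 0.5, n_per_class = 60, seed = 23)
  fit <- learn_weights(sim$x, sim$labels, tr, s = 3, seed = 23)
  expect_equal(fit$solution$nodes[1], sim$nodes)
  # sparsity budget of one returns at most one node
  fit1 <- learn_weights(sim$x, sim$labels, tr, s = 1, seed = 23)
  expect_lte(length(fit1$solution$nodes), 1L)
  # determinism
  fit2 <- learn_weights(sim$x, sim$labels, tr, s = 3, seed = 23)
  expect_identical(fit$solution, fit2$solution)
  # the weight table is ranked by selection with positive weights
  wt <- weight_table(fit)
  expect_equal(wt$rank, seq_len(nrow(wt)))
  expect_true(all(wt$weight > 0))
})

test_that("the Gram residual is non-increasing in the sparsity budget", {
  tr <- random_binary_tree(40, seed = 29)
  sim <- planted_classification(tr, n_per_class = 40, seed = 29)
  res <- sapply(c(1, 3, 6), function(s) {
    fit <- learn_weights(sim$x, sim$labels, tr, s = s, seed = 29)
    K <- adaptive_kernel(sim$x, fit$basis, fit$weights)
    norm(fit$gram$G - K, "F")
  })
  expect_true(all(diff(res) <= 1e-10))
})
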