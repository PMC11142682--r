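# brute-force oracle for the pseudo-F decomposition
pseudo_f_oracle <- function(D, g) {
  n <- nrow(D)
  g <- factor(g)
  ss <- function(ix) {
    s <- 0
    for (i in ix) for (j in ix) s <- s + D[i, j]^2
    s / 2
  }
  ss_t <- ss(seq_len(n)) / n
  ss_w <- sum(vapply(split(seq_len(n), g),
                     function(ix) ss(ix) / length(ix), numeric(1)))
  ((ss_t - ss_w) / (nlevels(g) - 1)) / (ss_w / (n - nlevels(g)))
}

test_that("pseudo-F matches the Anderson decomposition", {
  # equidistant toy: two groups of two, all pairwise distances equal
  D <- matrix(1, 4, 4); diag(D) <- 0
  g <- factor(c("a", "a", "b", "b"))
  expect_equal(permanova_pseudo_f(D, g)$statistic, 1.0)
  # coincident groups separated by distance one
  D2 <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(1, 1, 0, 0), c(1, 1, 0, 0))
  res <- permanova_pseudo_f(D2, g)
  expect_true(is.infinite(res$statistic))
  expect_true(res$degenerate)
  # random instances against the brute-force oracle
  set.seed(6)
  for (r in 1:3) {
    pts <- matrix(stats::rnorm(24), 12, 2)
    D3 <- as.matrix(stats::dist(pts))
    g3 <- factor(sample(rep(c("x", "y", "z"), 4)))
    expect_equal(permanova_pseudo_f(D3, g3)$statistic,
                 pseudo_f_oracle(D3, g3), tolerance = 1e-10)
  }
  expect_error(permanova_pseudo_f(D, factor(c("a", "a", "a", "b"))),
               "size one")
})

test_that("pseudo-F agrees with vegan's PERMANOVA and is label-invariant", {
  set.seed(9)
  pts <- matrix(stats::rnorm(40), 20, 2)
  pts[11:20, ] <- pts[11:20, ] + 1.5
  D <- stats::dist(pts)
  g <- factor(rep(c("u", "v"), each = 10))
  f_pkg <- permanova_pseudo_f(D, g)$statistic
  ad <- vegan::adonis2(D ~ g, permutations = 2)
  expect_equal(f_pkg, ad$F[1], tolerance = 1e-8)
  # invariance under group relabeling and sample permutation
  expect_equal(permanova_pseudo_f(D, factor(g, labels = c("v", "u")))$statistic,
               f_pkg)
  set.seed(9)
  p <- sample(20)
  expect_equal(permanova_pseudo_f(as.matrix(D)[p, p], g[p])$statistic,
               f_pkg, tolerance = 1e-10)
  # permutation p-value is in range and seeded
  r1 <- permanova_pseudo_f(D, g, n_permutations = 49, seed = 1)
  r2 <- permanova_pseudo_f(D, g, n_permutations = 49, seed = 1)
  expect_equal(r1$p_value, r2$p_value)
  expect_lte(r1$p_value, 1)
})

# direct textbook formula for squared distance covariance
dcov2_oracle <- function(Dx, Dy) {
  n <- nrow(Dx)
  s1 <- mean(Dx * Dy)
  s2 <- mean(Dx) * mean(Dy)
  s3 <- mean(rowMeans(Dx) * rowMeans(Dy))
  s1 + s2 - 2 * s3
}
dcor_oracle <- function(x, y) {
  Dx <- abs(outer(x, x, "-"))
  Dy <- abs(outer(y, y, "-"))
  v <- dcov2_oracle(Dx, Dy)
  vx <- dcov2_oracle(Dx, Dx)
  vy <- dcov2_oracle(Dy, Dy)
  sqrt(v / sqrt(vx * vy))
}

test_that("distance correlation matches the direct-formula oracle", {
  x <- c(0.0, 1.0, 2.5, 4.0)
  y <- c(2.0, -1.0, 0.5, 3.0)
  expect_equal(distance_correlation(x, y), dcor_oracle(x, y),
               tolerance = 1e-10)
  # affine dependence gives exactly one
  expect_equal(distance_correlation(x, 3 * x - 2), 1.0)
  expect_equal(distance_correlation(x, -0.5 * x + 7), 1.0)
  # constant input gives zero by convention
  expect_equal(distance_correlation(x, rep(2, 4)), 0)
  # symmetry and invariances
  set.seed(2)
  a <- stats::rnorm(15); b <- stats::rnorm(15)
  expect_equal(distance_correlation(a, b), distance_correlation(b, a))
  expect_equal(distance_correlation(2 * a + 1, b),
               distance_correlation(a, b), tolerance = 1e-10)
  expect_gte(distance_correlation(a, b), 0)
  expect_lte(distance_correlation(a, b), 1)
  # coordinate-matrix and distance-matrix inputs agree
  E <- rbind(a, b)
  expect_equal(distance_correlation(E, a),
               distance_correlation(as.matrix(stats::dist(t(E))), a))
})

test_that("corrected t-test applies the variance correction", {
  # all differences zero
  r0 <- corrected_t_test(rep(0, 25), k = 5, r = 5)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # hand formula on a toy vector
  d <- c(0.12, 0.05, -0.02, 0.08, 0.11, 0.03, 0.07, -0.01, 0.05, 0.09,
         0.02, 0.06, 0.04, 0.10, 0.01, 0.03, 0.08, 0.02, 0.06, 0.07,
         0.00, 0.04, 0.09, 0.05, 0.03)
  res <- corrected_t_test(d, k = 5, r = 5, test_fraction = 0.2)
  t_hand <- mean(d) / sqrt((1 / 25 + 0.25) * stats::var(d))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), 24),
               tolerance = 1e-10)
  expect_equal(res$df, 24)
  # as the test fraction vanishes it reduces to the resampled t-test
  res0 <- corrected_t_test(d, k = 5, r = 5, test_fraction = 1e-12)
  t_unc <- mean(d) / sqrt(stats::var(d) / 25)
  expect_equal(res0$statistic, t_unc, tolerance = 1e-6)
  # constant nonzero differences
  rc <- corrected_t_test(rep(0.1, 25), k = 5, r = 5)
  expect_true(is.infinite(rc$statistic))
  expect_equal(rc$p_value, 0)
  expect_error(corrected_t_test(rep(0, 10), k = 5, r = 5), "expected")
})

test_that("accuracy and AUC follow their standard definitions", {
  y <- factor(c("n", "n", "p", "p"), levels = c("n", "p"))
  perfect <- classification_metrics(y, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  # reversing the scores reverses the AUC
  rev_ <- classification_metrics(y, 1 - c(0.1, 0.2, 0.8, 0.9))
  expect_equal(rev_$auc, 0)
  # agreement with pROC on a random instance
  set.seed(4)
  yy <- factor(sample(c("n", "p"), 50, replace = TRUE), levels = c("n", "p"))
  ss <- stats::runif(50)
  expect_equal(classification_metrics(yy, ss)$auc,
               as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE,
                                              levels = c("n", "p"),
                                              direction = "<"))),
               tolerance = 1e-10)
  # random scores on balanced labels give AUC near one half
  set.seed(5)
  yb <- factor(rep(c("n", "p"), 500))
  expect_lt(abs(classification_metrics(yb, stats::runif(1000))$auc - 0.5),
            0.1)
  expect_error(classification_metrics(factor(rep("p", 4), levels = c("n", "p")),
                                      runif(4)), "one class")
})
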