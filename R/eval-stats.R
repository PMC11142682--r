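# Evaluation statistics: PERMANOVA pseudo-F, distance correlation, the
# corrected resampled t-test for cross-validated model comparison, and
# accuracy/ROC-AUC plumbing.

#' PERMANOVA pseudo-F statistic
#'
#' Anderson's decomposition on squared distances:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = ((SS_total - SS_within)/(g-1)) / (SS_within/(n-g))`. Higher values
#' indicate stronger clustering of the groups in the metric.
#'
#' @param d a distance matrix ([stats::dist] or square symmetric matrix).
#' @param groups a grouping factor (at least two groups, each with at
#'   least two members).
#' @param n_permutations optional number of label permutations for a
#'   p-value (0 = statistic only).
#' @param seed seed for the permutations.
#' @return a list with `statistic` (the pseudo-F; `Inf` with
#'   `degenerate = TRUE` when all within-group distances vanish), `ss_total`,
#'   `ss_within`, and `p_value` when permutations were requested.
#' @export
permanova_pseudo_f <- function(d, groups, n_permutations = 0, seed = NULL) {
  D <- as.matrix(d)
  groups <- factor(groups)
  n <- nrow(D)
  if (length(groups) != n) stop("groups are not aligned to the distances")
  cnt <- table(groups)
  if (length(cnt) < 2L) stop("need at least two groups")
  if (any(cnt < 2L))
    stop("group(s) of size one: ", paste(names(cnt)[cnt < 2L], collapse = ", "))
  D2 <- D * D
  f_of <- function(g) {
    ss_total <- sum(D2[upper.tri(D2)]) / n
    ss_within <- 0
    for (ix in split(seq_len(n), g)) {
      sub <- D2[ix, ix, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
    }
    g_n <- nlevels(g)
    if (ss_within <= 0) return(Inf)
    ((ss_total - ss_within) / (g_n - 1)) / (ss_within / (n - g_n))
  }
  f_obs <- f_of(groups)
  out <- list(statistic = f_obs, degenerate = !is.finite(f_obs))
  ss_total <- sum(D2[upper.tri(D2)]) / n
  out$ss_total <- ss_total
  out$ss_within <- if (is.finite(f_obs)) {
    g_n <- nlevels(groups)
    ss_total / (1 + f_obs * (g_n - 1) / (n - g_n))
  } else 0
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_permutations),
                   function(i) f_of(sample(groups)), numeric(1))
    out$p_value <- (1 + sum(perm >= f_obs)) / (1 + n_permutations)
  }
  out
}

# Coerce to a pairwise distance matrix: vectors use |y_i - y_j|, square
# symmetric zero-diagonal matrices pass through, other matrices are read
# as coordinates-by-samples.
as_dist_matrix <- function(x) {
  if (inherits(x, "dist")) return(as.matrix(x))
  if (is.matrix(x)) {
    if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-9 &&
        max(abs(diag(x))) < 1e-9) {
      return(x)
    }
    return(as.matrix(stats::dist(t(x))))
  }
  abs(outer(as.numeric(x), as.numeric(x), "-"))
}

#' Distance correlation
#'
#' Sample distance correlation (biased V-statistic, classical Székely
#' form) between two variables given as values, coordinate matrices
#' (coordinates by samples), or pairwise distance matrices. Zero when
#' either variable is constant; 1 for affinely dependent scalars.
#'
#' @param x,y numeric vectors, coordinate matrices, [stats::dist] objects
#'   or square distance matrices on the same `n` samples.
#' @return a scalar in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  Dx <- as_dist_matrix(x)
  Dy <- as_dist_matrix(y)
  n <- nrow(Dx)
  if (n != nrow(Dy)) stop("x and y have different sample counts")
  if (n < 2L) stop("need at least two samples")
  dc <- function(D) {
    D - rowMeans(D) - rep(colMeans(D), each = nrow(D)) + mean(D)
  }
  A <- dc(Dx)
  B <- dc(Dy)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= .Machine$double.eps || dvy <= .Machine$double.eps) return(0)
  dcov2 <- max(mean(A * B), 0)
  min(sqrt(dcov2 / sqrt(dvx * dvy)), 1)
}

#' Corrected resampled t-test for cross-validated differences
#'
#' The variance-corrected t statistic for per-split metric differences
#' from repeated k-fold cross-validation:
#' \eqn{t = \bar d / \sqrt{(1/(kr) + n_2/n_1)\,s_d^2}}, where
#' \eqn{n_2/n_1} is the test/train size ratio (0.25 for 80/20 splits),
#' with `k*r - 1` degrees of freedom. The correction compensates for the
#' dependence between overlapping training sets; as the test fraction
#' goes to zero it reduces to the uncorrected resampled t-test.
#'
#' @param d numeric vector of per-split differences (length `k * r`).
#' @param k number of folds.
#' @param r number of repeats.
#' @param test_fraction held-out fraction per split (default 0.2).
#' @return a list with `statistic`, `p_value` (two-sided), `df`. Zero
#'   variance yields `t = 0, p = 1` when the mean is also zero and
#'   `t = +/-Inf, p = 0` otherwise.
#' @export
corrected_t_test <- function(d, k, r, test_fraction = 0.2) {
  d <- as.numeric(d)
  if (length(d) != k * r)
    stop("expected ", k * r, " per-split differences, got ", length(d))
  ratio <- test_fraction / (1 - test_fraction)
  m <- mean(d)
  v <- stats::var(d)
  df <- k * r - 1
  if (v <= 0) {
    if (m == 0) return(list(statistic = 0, p_value = 1, df = df))
    return(list(statistic = sign(m) * Inf, p_value = 0, df = df))
  }
  t_stat <- m / sqrt((1 / (k * r) + ratio) * v)
  list(statistic = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = df),
       df = df)
}

#' Accuracy and ROC-AUC of binary scores
#'
#' AUC by the rank (Mann-Whitney) statistic with midranks for ties;
#' accuracy from scores thresholded at 0.5 unless explicit predictions
#' are given.
#'
#' @param y_true true labels; a factor (second level = positive class) or
#'   0/1 vector.
#' @param scores numeric scores for the positive class.
#' @param predicted optional predicted labels for the accuracy.
#' @return a list with `accuracy` and `auc`.
#' @export
classification_metrics <- function(y_true, scores, predicted = NULL) {
  if (is.factor(y_true)) {
    pos <- y_true == levels(y_true)[nlevels(y_true)]
  } else {
    pos <- y_true == max(y_true)
  }
  if (length(unique(pos)) < 2L)
    stop("AUC undefined: only one class present")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  rk <- rank(scores)
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  acc <- if (!is.null(predicted)) {
    mean(predicted == y_true)
  } else {
    mean((scores > 0.5) == pos)
  }
  list(accuracy = acc, auc = auc)
}
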