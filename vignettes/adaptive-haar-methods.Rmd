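---
title: "Methods: the adaptive Haar-like distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive Haar-like distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaphaar)
```

## The model

`adaphaar` treats a microbiome sample as a probability mass function $x$
on the leaves $L$ of a reference phylogeny $T$: abundances are
total-sum normalized, so all information is relative (compositional).
The tree is *out-rooted* — its root $\circ$ has a single child — and
binary below the root; every other internal node $v$ is a bifurcation
with left and right child clades $L(v_+)$ and $L(v_-)$.

Each bifurcation carries a Haar-like wavelet $\varphi_v$: constant
positive on $L(v_+)$, constant negative on $L(v_-)$, zero elsewhere,
scaled to unit norm and zero sum; the root carries the constant wavelet
$1/\sqrt{|L|}$. These $|I| = |L|$ wavelets form an orthonormal basis of
functions on the leaves, and the projection of a sample onto
$\varphi_v$ is

$$\langle x, \varphi_v\rangle
  = c_v\,\bigl(\mathrm{avg}(x; L(v_+)) - \mathrm{avg}(x; L(v_-))\bigr),
\qquad
c_v = \sqrt{\frac{|L(v_+)|\,|L(v_-)|}{|L(v_+)|+|L(v_-)|}}.$$

For compositional data the root coordinate is the constant
$1/\sqrt{|L|}$; it carries no information about differences between
samples and is excluded from every distance, dictionary and weight
vector in the package. The square-root form of $c_v$ is the unique
scaling consistent with unit-norm, zero-sum two-valued wavelets; the
test suite verifies it through the orthonormality of the basis rather
than assuming it.

A non-negative weight $w_v$ per bifurcation defines the adaptive
Haar-like kernel $K_w = H^\top \mathrm{diag}(w)\,H$ (with
$H = \Phi^\top X$ the coordinate matrix) and distance
$d_w(x_1,x_2) = \sqrt{\sum_v w_v \langle x_1-x_2,\varphi_v\rangle^2}$.
Two fixed choices recover classical metrics: unit weights give the
Euclidean distance between compositions, and the spectral weights
$\lambda_v = \varphi_v^\top C\,\varphi_v$ of the phylogenetic covariance
$C(i,j) = \sum_{e \in [i \wedge j,\, \circ]} \ell(e)$ give the Haar-like
distance, a near-diagonal proxy for DPCoA. We return the *square roots*
of the quadratic forms so that the metric axioms hold; squared variants
are available (`squared = TRUE`) since PERMANOVA decomposes squared
distances.

## Learning the weights

The supervision signal is a random forest trained on the labeled
samples (features = leaf abundances). Its affinity
$A(x_i,x_j)$ — the fraction of trees placing $i$ and $j$ in the same
terminal bin — is a kernel describing the geometry the forest actually
uses. The learning pipeline is:

1. **Gram extraction.** Classical MDS of the dissimilarity $D = 1 - A$:
   double-center $-\tfrac12 J (D \circ D) J$, clip negative eigenvalues
   to zero (the affinity is generally non-Euclidean), and set
   $G = Z^\top Z$ from the retained principal coordinates.
2. **Dictionary.** Column $v$ of the dictionary is
   $\mathrm{vec}(h_v h_v^\top)$ for $h_v$ the $v$-th coordinate row.
   Columns are never materialized: inner products with a symmetric $S$
   are computed as $h_v^\top S h_v$ and norms as $\|h_v\|^2$.
3. **Non-negative matching pursuit.** Iteratively select the atom with
   the largest normalized projection on the residual (only while a
   positive projection exists, so an empty solution is legal), remove
   its contribution, and stop after $s$ iterations. Repeated selections
   of the same node accumulate into a single weight.

### Numerical choices

* **Coefficient scaling.** The update uses the standard matching-pursuit
  coefficient $v = \langle R, M\rangle / \|M\|^2$. Under this scaling
  the removed energy $\|R_i - R_{i+1}\| = |v|\,\|M\|$ — reported as the
  *coordinate importance* — is provably non-increasing for this
  dictionary (rank-one PSD atoms have pairwise non-negative inner
  products), and the residual norm strictly decreases. A raw-inner-
  product update (`scaling = "printed"`) is provided for comparison; it
  overshoots whenever $\|M\| \neq 1$.
* **Ties** in the argmax break to the lowest post-order index, making
  runs bit-reproducible.
* **Zero-norm atoms** (nodes whose coordinate row is identically zero,
  e.g. clades with no observed mass) are skipped.
* **The root atom** is excluded a priori; because its coordinate row is
  constant and $G$ is doubly centered, its projection is exactly zero
  anyway (asserted on random instances in the tests).
* **Degenerate inputs.** Samples with zero total abundance are rejected
  at normalization; an all-nonpositive first iteration returns an empty
  weight vector with a warning downstream (`haar_embed`).

## The surrogate predictor

Distances between learned-embedding columns are thresholded at one and
converted to the affinity $A_{\mathrm{Haar}} = 1 - \min(D, 1)$; a
prediction is the affinity-weighted average of the $k$ nearest training
labels. We read the neighbour-count convention as
$k = \lfloor\sqrt{n}\rfloor$ — the usual KNN heuristic; $k = n$ would
make sparsification vacuous — and expose it as a parameter. Binary
classes are encoded 0/1 and thresholded at 0.5; multiclass predictions
take the argmax of one-vs-rest averages; a zero affinity denominator
falls back to the global training mean (majority class).

By default prediction is *transductive*: the weights are re-learned from
the joint train+test RF affinity, with training labels only entering the
local average. This mirrors the validation protocol of the method's
source and uses strictly no test labels; an *inductive* mode
(`mode = "inductive"`) reuses training-only weights for deployment
settings. The two agree on confidently-classified points but not in
general — re-learning on the joint affinity can reweight nodes.

Sparsity is tuned on an inner split of the training data (75/25,
stratified; the source protocol does not state the fraction) over the
default grid $s \in \{1,\dots,10\}$. Because matching pursuit is greedy,
the solution for budget $s$ is a prefix of the solution for the largest
budget, so one fit serves the whole grid. Model comparison uses
stratified 5-fold cross-validation repeated over 5 randomizations (25
splits), accuracy and rank-statistic ROC-AUC, and the corrected
resampled t-test with variance factor $1/(kr) + n_2/n_1$.

## The synthetic generator

`random_binary_tree()` draws coalescent-style topologies with
exponential(1) branch lengths. `planted_classification()` and
`planted_regression()` emulate the signal structure the method targets:
classes (or a continuous covariate) differ by a clade-level mass shift.
A dataset-level baseline composition $p_0$ is drawn from a symmetric
Dirichlet (concentration 1 — rough, realistic leaf-level heterogeneity);
the signal moves a fraction $\delta$ (default 0.5) of the mass under the
planted bifurcation from the right to the left child, proportionally
within each subtree, so totals above the node are untouched; each sample
is the mixture $(1-\varepsilon)\,p_{\mathrm{class}} + \varepsilon\,u$
with $u$ an independent Dirichlet draw and noise level
$\varepsilon = 0.1$ by default. The mixture form makes the zero-noise
regression case exactly monotone in the covariate, which pins down the
generator algebra in tests. The planted node defaults to the bifurcation
whose clade is closest to a quarter of the leaves with both children of
size at least two.

What the generator does *not* emulate: sequencing depth variation and
count noise, zero inflation, correlated multi-clade signals, tree
misspecification. Passing tests therefore certify the algebra and the
recovery behaviour under clean clade-level signal, not performance on
real surveys.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path while keeping a full run in seconds to a few
minutes: trees of 2–300 leaves for basis properties, 100-leaf trees with
200 samples for recovery and cross-validation, 10 fixed-seed replicates
for the recovery rate.

## Known limitations

* **Scale sensitivity of atom selection.** The dictionary atoms are
  outer products of *uncentered* coordinate rows, while the Gram target
  is centered. A coordinate with a large constant component (a strong
  baseline asymmetry between sibling clades) has most of its atom energy
  in a direction orthogonal to any centered target, which dilutes its
  normalized projection; conversely, atoms with tiny norms receive very
  large weights when selected ($v \propto \|M\|^{-2}$), and such
  selections can dominate the embedding with noise. In practice the
  inner sparsity tuning guards against this — budgets that admit
  noise atoms score worse and are not selected — but rankings past the
  first few selections should be read with care.
* The affinity of a forest with large terminal bins (regression) is
  coarsely quantized; with small $n$ the Gram target carries limited
  geometry.
* Weights are learned per dataset; no sampling distribution or test is
  provided for them, so selected nodes are hypotheses for follow-up, not
  inferences.

## Worked check

A miniature end-to-end run (kept small so the vignette builds quickly):

```{r example}
tree <- random_binary_tree(60, seed = 5)
sim <- planted_classification(tree, n_per_class = 40, seed = 5)
fit <- learn_weights(sim$x, sim$labels, tree, s = 3, seed = 5)
c(first_selected = fit$solution$nodes[1], planted = sim$nodes)
```
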