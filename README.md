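# adaphaar

Interpretable metric learning for comparative metagenomics: the adaptive
Haar-like distance.

## The problem

Phylogenetic β-diversity metrics (UniFrac, DPCoA, the Haar-like distance)
compare microbiome samples through a fixed reference phylogeny, but their
universal branch-length weights often fail to separate samples from
different environments. Random forests, in contrast, predict environmental
labels from microbial composition very well — and explain nothing.
`adaphaar` bridges the two: it learns, from a trained random forest, a
sparse non-negative weight `w_v` for each internal node (bifurcation) `v`
of the reference phylogeny, so that the resulting weighted wavelet metric
reproduces what the forest learned while every term of the metric remains
attached to a clade of the tree.

## The method in brief

Samples are compositional vectors `x` on the leaves of an out-rooted
binary phylogeny. Each bifurcation `v` carries a Haar-like wavelet — a
two-valued, zero-sum, unit-norm contrast between its child clades — and
the Haar-like coordinate of a sample is

    ⟨x, φ_v⟩ = c_v · (avg(x; L(v₊)) − avg(x; L(v₋))),
    c_v = √( |L(v₊)||L(v₋)| / (|L(v₊)|+|L(v₋)|) ),

a scaled difference of mean abundances between sibling clades. A
non-negative node weighting `w` defines the adaptive Haar-like kernel and
distance

    k_w(x₁, x₂) = Σ_v w_v ⟨x₁, φ_v⟩⟨x₂, φ_v⟩,
    d_w(x₁, x₂) = √( Σ_v w_v ⟨x₁ − x₂, φ_v⟩² ).

With `w_v = λ_v = φ_vᵀ C φ_v` (the spectral weights of the phylogenetic
covariance `C`) this is the fixed Haar-like distance, a proxy for DPCoA.

To adapt `w` to data, a random forest is trained on the labeled samples
and its affinity `A(x_i, x_j)` — the fraction of trees co-binning two
samples — is converted to a Gram target `G` by classical MDS of the
dissimilarity `1 − A`. Since `vec(K_w) = M w` for the dictionary whose
columns are outer products of coordinate rows, non-negative matching
pursuit greedily selects at most `s` nodes whose weighted kernel best
approximates `G`. The learned embedding `√w_v ⟨x, φ_v⟩` yields
interpretable ordinations, and a `⌊√n⌋`-nearest-neighbour local average
over the thresholded embedding affinity serves as a surrogate classifier
that tracks the forest's accuracy.

## Worked example

```r
library(adaphaar)

tree <- random_binary_tree(100, seed = 11)
sim  <- planted_classification(tree, delta = 0.5, n_per_class = 100, seed = 21)
fit  <- learn_weights(sim$x, sim$labels, tree, s = 5, seed = 21)
fit
#> Adaptive Haar-like metric fit
#> Non-negative matching pursuit solution: 2 iteration(s), 2 distinct node(s)
#>   nodes (selection order): 45, 39
#>   importances: 17.8, 0.5451
#>   residual norms: 49.7 -> 46.4 -> 46.4
sim$nodes   # the bifurcation carrying the planted signal
#> [1] 45
```

The learner's first selection is node 45 — exactly the bifurcation whose
child clades were given different mass between the two classes — and its
importance (the Gram-residual energy removed, 17.8) dwarfs the second
selection's (0.55). Matching pursuit stopped after two iterations because
no positive projection remained. Comparing group separation under the
fixed and the learned metric:

```r
d_fixed <- beta_diversity(sim$x, tree, "haar")
d_adapt <- beta_diversity(sim$x, tree, "adaptive", weights = fit$weights)
permanova_pseudo_f(d_fixed, sim$labels)$statistic
#> [1] 827.2724
permanova_pseudo_f(d_adapt, sim$labels)$statistic
#> [1] 5418.929
```

The adaptive metric separates the planted classes several times more
sharply than the fixed Haar-like distance. For prediction,
`surrogate_predict()` gives nearest-neighbour estimates in the learned
embedding and `cross_validate()` runs the repeated stratified 5×5-fold
protocol with inner sparsity tuning, reporting surrogate and forest
accuracy/AUC side by side.

Real data come in through `read_phylogeny()` (Newick),
`read_abundance()` (TSV or BIOM, aligned and renormalized against the
tree) and a per-sample label table; `exec/adaptive-haar` wraps the same
functions as a command-line tool (`tree-info`, `coords`, `beta`, `fit`,
`simulate`).

## Scope notes

The package implements the metric-learning pipeline and its evaluation
statistics (PERMANOVA pseudo-F, distance correlation, corrected resampled
t-test, ROC-AUC). UniFrac baselines, log-ratio methods and figure
rendering for external tree viewers are out of scope; learned node
rankings can be exported with `weight_table()` for annotation in any
viewer.
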