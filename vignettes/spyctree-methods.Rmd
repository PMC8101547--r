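---
title: "Semi-supervised oblique predictive clustering trees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised oblique predictive clustering trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spyctree)
```

## The model

`spyctree` learns binary trees whose internal nodes test oblique splits
`w · x + b ≥ 0` over standardized features. It is a *predictive
clustering* method: the heuristic that scores a candidate split is the
impurity of designated *clustering attributes*, which here are the
features and the targets jointly. That joint role is what makes the
method semi-supervised — an unlabeled example contributes feature
impurity even though it contributes no target impurity — and it is useful
exactly when the *cluster assumption* holds: examples that fall in the
same feature-space cluster tend to share target values. When the
assumption fails, unlabeled examples are at best useless, and the
supervision degree described below exists to protect against that case.

Notation: a node holds $L$ labeled and $U$ unlabeled examples with
feature matrix $X \in \mathbb{R}^{(L+U) \times D}$ (labeled rows first)
and encoded targets $Y \in \mathbb{R}^{L \times T}$ for the labeled rows.
A clustering-weight vector $p \in \mathbb{R}^{D+T}_{\ge 0}$ assigns a
priority to every clustering attribute.

### Supervision degree

The parameter $\omega \in [0, 1]$ rescales $p$ so that its feature block
sums to $1 - \omega$ and its target block to $\omega$, preserving
proportions within each block. The limits are exact, not approximate, and
the package treats them as contracts covered by tests:

* $\omega = 0$: target weights vanish, so tree *structure* is invariant
  to any permutation of the targets (growth is unsupervised; predictions
  still come from the labeled prototypes).
* $\omega = 1$: feature weights vanish and unlabeled rows are excluded
  from split learning altogether, so a fit on $L+U$ examples predicts
  bit-identically to a fit on the $L$ labeled examples alone. The
  exclusion matters: with weights alone, unlabeled rows would still be
  tie-assigned randomly during clustering and would perturb the learned
  separator, violating the "fully supervised" reading of this limit.

Within a block the priorities are uniform, except for hierarchical
multi-label targets, where label $j$ at depth $d_j$ receives $0.75^{d_j}$
so that mistakes high in the hierarchy dominate the impurity. Top-level
labels have depth 1 (the convention in the predictive-clustering
literature), and in a DAG a label's depth is the mean of its parents'
depths plus one.

### Split learners

**SVM variant.** Semi-supervised 2-means first partitions the node's
examples over the joint space: the distance of example $j$ to centroid
$c$ is
$\sum_k p_k (X_{jk} - c^x_k)^2 + \alpha \sum_k p_{D+k} (Y_{jk} - c^y_k)^2$
with $\alpha = 1$ for labeled and $\alpha = 0$ for unlabeled examples.
Centroids are seeded from two distinct labeled examples; feature parts
update as means over all members, target parts over labeled members only.
A cluster that loses all members — or all labeled members, which would
leave its target part undefined — is re-seeded from a random labeled
example. The final 0/1 assignment becomes $\pm 1$ labels for an
L1-regularized squared-hinge SVM over the features,
$\min_{w,b} \|w\|_1 + C \sum_k \max(0,\, 1 - y_k (X_{k\cdot} w + b))^2$,
solved by proximal gradient (ISTA) with a backtracking line search,
capped at `opt_iters` iterations and stopped early when the relative
objective change falls below `1e-4`. The $\pm 1$ mapping is deliberate: a
0/1 encoding would make one cluster's hinge terms constant, so only one
side of the partition would exert any force on the separator.

**Gradient variant.** The fuzzy membership $s = \sigma(Xw + b)$ gives the
differentiable fitness
$f(w, b) = S \cdot imp(s, p) + (L + U - S) \cdot imp(1 - s, p)$, where
$S = \sum_i s_i$ and $imp(a, p) = \sum_k p_k\, \mathrm{var}(X_{\cdot k}, a)
+ \sum_k p_{D+k}\, \mathrm{var}(Y_{\cdot k}, a_{1:L})$ uses weighted
variances ($\mathrm{var}(v, a) = \mathrm{mean}(v^2, a) -
\mathrm{mean}(v, a)^2$, population convention, defined as 0 when the
weights sum to 0). The size factors $S$ and $L + U - S$ push the search
towards balanced splits. The full objective
$\|w\|_{1/2} + C f(w, b)$ is minimized with Adam. The quasi-norm is
smoothed as $\sum_i \sqrt{|w_i| + 10^{-8}}$ to make it differentiable at
zero. The analytic gradient uses
$\partial \mathrm{var}(v, a) / \partial a_i = ((v_i - m)^2 -
\mathrm{var}) / A$ and is verified against central finite differences in
the test suite. Because Adam is not a descent method step-for-step, the
iterate with the lowest objective seen is returned, which also guarantees
the returned objective never exceeds the initial one.

### Growth, stopping, prediction

Features are standardized to mean 0 and standard deviation 1 at every
node (all rows when $\omega < 1$, labeled rows when $\omega = 1$), and
targets over the labeled rows, *before* the clustering weights apply —
so the weights alone control relative influence. Standard deviations use
the population convention, matching the variance in the impurity;
zero-variance columns standardize to zeros with $\sigma$ recorded as 1.
Sparse feature matrices are scaled but not centered, preserving sparsity.

A candidate split is accepted only if

1. each child receives at least `min_leaf_labeled` labeled examples
   (default 1 — a leaf must be able to form a prototype), and
2. the size-weighted pooled impurity of the children, measured in the
   parent's standardized space with hard all-ones membership, is at most
   `1 - imp_reduction` (default 5% reduction) of the parent's impurity.
   Pooling is per attribute block: feature variances pool over all child
   rows, target variances over labeled child rows, which keeps the
   $\omega = 1$ supervised-limit equivalence exact.

The pooled form of the gate is a deliberate design choice. The
alternative — accepting when *either* child alone clears the 5% bar —
is statistically degenerate: the population variance of a small child of
$k$ rows has expectation $(k-1)/k$ of the parent's and fluctuates with
standard deviation $\approx \sqrt{2/k}$, so a split that isolates any
small group passes by chance alone, and on targets *independent* of the
features trees grew to depth 10–14. With pooling, the reduction equals
the between-child variance share, which on structureless targets is the
overfitting capacity of a single oblique split — small when $D \ll n$ —
and the gate stops growth at the root, which is what a stopping rule is
for. A rejected or degenerate split immediately yields a leaf; there is
no retry with a fresh initialization, keeping growth deterministic.

Leaves store the column means of their labeled examples' raw
(unstandardized) targets. Prediction routes each row by the stored
per-node standardization and hyperplane (ties $w \cdot x + b = 0$ go to
the positive child), then decodes the prototype per task: identity for
regression, threshold 0.5 for binary and multi-label (configurable),
argmax for multi-class with ties broken to the lowest column index so
results are reproducible.

### Ensembles and feature importance

Bagging fits 50 trees by default, each on a stratified bootstrap: $L$
draws with replacement from the labeled rows and $U$ from the unlabeled
rows. Stratification guarantees every tree sees labeled examples (an
unstratified bootstrap could draw none at small $L$) and preserves the
labeled fraction. Scores are averaged over trees. Feature importance of a
tree is $\sum_{\text{split } s} (s_n / N)\, |s_w| / \|s_w\|_1$ — nodes
weighted by the number of training examples they affect — and ensembles
average per-tree vectors; the importance total equals
$\sum_s s_n / N$ exactly, a useful invariant for testing.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `variant` | `"grad"` | Split learner; the gradient variant is the stronger default in our experiments, the SVM variant is competitive at very few labels. |
| `omega` | `"auto"` | Supervision degree in $[0,1]$; `"auto"` selects from $\{0, 0.25, 0.5, 0.75, 1\}$ by 3-fold internal CV on the labeled rows (unlabeled rows join every training fold), scoring with the task's outer metric and breaking ties towards the *largest* $\omega$, i.e. towards trusting the labels when unlabeled data demonstrably adds nothing. |
| `C` | 10 | Regularization strength in both split objectives (larger = the data term dominates). |
| `opt_iters` | 100 | Hyperplane optimization iterations (both variants). |
| `clust_iters` | 10 | 2-means iterations (SVM variant), with early stop on an unchanged assignment. |
| `adam_lr` | 0.1 | Adam step size, constant; with standardized inputs and the bounded sigmoid this is stable across the problem sizes we test, and the best-iterate rule absorbs occasional overshoot. |
| `adam_beta1/2`, `adam_eps` | 0.9 / 0.999 / 1e-8 | Standard Adam constants. |
| `min_leaf_labeled` | 1 | Minimum labeled examples per leaf. |
| `max_depth` | unlimited | Cap on splits per root-to-leaf path. |
| `imp_reduction` | 0.05 | Required relative impurity reduction (pooled, see above). |
| `seed` | — | Single seed from which all randomness in a fit derives (centroid seeding, distance ties, weight initialization, per-tree bootstrap seeds). |

## What the synthetic generator does and does not emulate

`gen_clustered()` draws cluster centers at the vertices of a scaled
simplex so every pair of centers is `separation` apart in units of the
within-cluster standard deviation (identity covariance, uniform cluster
priors), and makes targets a deterministic function of the cluster:
class = cluster for BC/MCC, a fixed label subset per cluster for MLC, a
label-plus-ancestors path for HMLC, and a cluster-specific linear
response with noise for STR/MTR. This is the cluster assumption in its
purest form — precisely the structure the method is designed to exploit —
plus controls to break it: `separation = 0` removes the feature signal,
`noise_frac` adds signal-free features, `add_noise_features()` doubles
the feature set with standard normal noise for the importance protocol,
and `mask_labels()` implements the random label masking of the inductive
evaluation protocol.

What it does **not** emulate: correlated or heteroscedastic features,
unequal cluster sizes, label noise, targets that cut across clusters,
covariate shift. Passing tests on this generator therefore show that the
machinery is correct and that the method behaves as designed *when its
assumption holds*; they do not certify performance on real data, where
the gain from unlabeled examples can be smaller, absent, or negative —
which is exactly why $\omega$ is cross-validated per dataset rather than
fixed.

## Study conditions used by the tests and the acceptance script

All empirical checks run at sizes a single CPU handles in minutes, chosen
once as realistic small-benchmark conditions: the semi-supervised-benefit
experiment uses binary tasks with 2 clusters at separation 4, $n = 500$
training examples ($L = 10$ labeled) plus 200 test examples, 20 seeds,
comparing CV-selected $\omega$ against the supervised $\omega = 1$ fit;
the feature-importance study uses 50-tree ensembles at $L = 250$ of
$n = 500$ with 10 informative features doubled by 10 noise features, 20
repeats; the stopping-rule control uses $n = 500$, $D = 5$ with targets
independent of features, where a single split's overfitting capacity is
well below the 5% gate. The masking-protocol illustration runs 10-fold
with $L = 50$ of $n = 300$ on a 3-target regression.

## Numerical choices and degenerate inputs

* Population standard deviations throughout (standardization and
  variances divide by the weight total, not $n - 1$), so the two agree.
* Zero-variance columns: $\sigma := 1$, standardized values 0 — they
  contribute nothing to impurity and cannot produce NaNs.
* Empty fuzzy groups: weighted variance is defined as 0 when
  $\sum a = 0$, avoiding 0/0 in saturated sigmoid regimes; gradient
  contributions are likewise zeroed below a $10^{-12}$ weight total.
* 2-means distance ties are broken uniformly at random from the fit's
  seeded stream; k-means seeding retries up to 10 times for distinct
  labeled seeds, then scans adjacent rows, and declares the node
  unsplittable only if all labeled rows coincide in the joint space.
* A dataset with a single labeled example yields a depth-0 tree
  predicting that example's targets; all-identical features yield "no
  split" and hence a leaf.
* Rows without any positive label are skipped (with a warning) by the
  label-ranking metric, whose per-example normalization assumes at least
  one positive.
* Model JSON is written with 17 significant digits, so doubles
  round-trip bit-exactly: same seed ⇒ byte-identical files, and
  save/load ⇒ identical predictions.
* The compiled (C++) and R implementations of the gradient split agree
  to ~$10^{-12}$ per evaluation; over 100 Adam steps last-bit differences
  can drift visibly in $w$, so cross-implementation tests compare the
  achieved objective and the induced partition, not raw coefficients.

## Known limitations

* The 2-means step samples, and ties consume, the global R RNG stream;
  reproducibility is per-seed, not per-call-site.
* No pruning and no missing-feature handling; prediction requires the
  full feature vector.
* $\omega$ selection multiplies training cost by (grid size × folds);
  this is inherent to the method's protection against harmful unlabeled
  data, not an implementation artifact.
* With $\omega < 1$ and many approximately isotropic features, the
  pooled 5% gate can keep accepting unsupervised splits (each split
  removes a $\propto 1/D$ share of feature variance), producing large
  trees; `max_depth` is the practical control.
* Sparse inputs skip centering, so "standardized" sparse features retain
  their means; this trades statistical nicety for sparsity preservation
  and matters only when column means are large relative to scales.
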