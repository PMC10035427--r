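---
title: "Methods: node features for GCN-based brain network classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: node features for GCN-based brain network classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfnGCN)
```

## Overview

`bfnGCN` studies a deceptively simple question: when a graph
convolutional network classifies brain functional networks (BFNs), how
much does the *node feature matrix* matter? The adjacency matrix — the
estimated connectivity — is only half of a GCN's input; the other half,
the per-node feature matrix $X \in \mathbb{R}^{n \times d}$, can be
anything from raw signals to graph statistics, and the choice turns out
to move classification accuracy by tens of percentage points. The
package implements the full pipeline — connectivity estimation, feature
construction, the GCN, and a repeated-random-split evaluation protocol —
plus a synthetic cohort generator that makes every stage testable.

## Connectivity estimators

Each subject contributes an $n \times m$ matrix of ROI time series
$s_1, \dots, s_n \in \mathbb{R}^m$.

**Pearson correlation (PC).** The workhorse estimator,
$c_{ij} = \frac{(s_i-\bar s_i)^\top (s_j-\bar s_j)}
{\|s_i-\bar s_i\|\,\|s_j-\bar s_j\|}$, yields a dense signed matrix.
Constant (zero-variance) ROI rows are a hard error naming the ROI — they
indicate an extraction failure upstream.

**Sparse representation (SR).** Each ROI's standardized series is
regressed on all others with an L1 penalty,
$\min_w \tfrac12 \|s_i - S_{-i} w\|^2 + \lambda \|w\|_1$, giving a row
of a coefficient matrix $W$; the adjacency is the symmetrized magnitude
$(|W| + |W^\top|)/2$. The per-ROI lasso subproblems are solved by
coordinate descent via `glmnet` (the penalty is rescaled to glmnet's
$\frac{1}{2N}$-RSS objective, with a warm-start path ending at the
target $\lambda$ and a closed-form soft-threshold fallback when only one
predictor exists). Sparsity is monotonically nonincreasing in $\lambda$;
the default grid exposed in config spans $2^{-5}\dots2^{0}$.

**Low-rank representation (LR).** The exact low-rank formulation used in
the BFN literature varies; the package implements the simplest convex
estimator with a closed-form solution: nuclear-norm proximal denoising
of the PC matrix, $\min_W \tfrac12\|C - W\|_F^2 + \lambda \|W\|_*$,
solved by singular-value soft-thresholding. $\lambda \to 0$ recovers
$C$; $\lambda$ beyond the leading singular value gives the zero matrix;
rank is nonincreasing in $\lambda$.

**Normalization.** The spectral GCN consumes
$\hat A = D^{-1/2}(A + I)D^{-1/2}$ with $D_{ii} = \sum_j A_{ij}$.
Because PC produces negative weights and $D^{-1/2}$ must stay real, the
degree computation and propagation operate on the magnitude matrix
$|A|$; all eigenvalues of $\hat A$ then lie in $[0, 1]$. The signed
information is not lost — it is available to the classifier through the
CV feature block. An optional proportional thresholding (keep the
strongest 30% of edges by default, ties at the cut kept) can binarize
the adjacency first; BFN studies differ on whether matrices are
thresholded before a GCN, so this is a config switch rather than a fixed
truth.

## Node feature families

* **OS** (original signals): row $i$ is $s_i$ itself, $d = m$. Optional
  per-row z-scoring (off by default) removes amplitude differences.
* **OH** (one-hot): the identity matrix, $d = n$. Encodes node identity
  and nothing else — the natural "no information" control.
* **NS** (node statistics): eight per-node graph measures, $d = 8$:
  three local clustering coefficients, four centralities (degree,
  betweenness, closeness, eigenvector) and local efficiency.
* **CV** (correlation vectors): row $i$ of the PC matrix with unit
  diagonal, $d = n$. CV is defined on Pearson correlation only; asking
  for CV features from an SR/LR network is an error, and when SR or LR
  supplies the adjacency the CV block is still computed from the
  subject's PC matrix.

Blocks concatenate in the canonical order OS, OH, NS, CV whatever the
request order, so "OH + CV" and "CV + OH" name the same design.

The three clustering definitions are not canonical in the literature, so
the package fixes them explicitly: (i) the binary Watts–Strogatz
coefficient on the thresholded graph, (ii) Onnela's geometric-mean
weighted coefficient and (iii) the Zhang–Horvath weighted coefficient,
the three most-cited variants for weighted networks. Binary-graph
statistics (WS clustering, degree, betweenness, closeness, local
efficiency) are computed on the proportionally thresholded graph
(default keep fraction 0.3); weighted statistics (Onnela, Zhang–Horvath,
eigenvector centrality) on max-normalized absolute weights. Degree,
betweenness and closeness are normalized by the standard $(n-1)$-based
factors so features are comparable across graph sizes; closeness uses
the harmonic convention and local efficiency counts unreachable pairs as
zero, so disconnected graphs need no special-casing; eigenvector
centrality is the L2-normalized magnitude of the principal eigenvector.
Shortest-path and spectral machinery comes from `igraph`; the weighted
clustering coefficients are computed directly from their defining
formulas. All eight statistics are verified in the test suite against
brute-force oracles (explicit path enumeration, triangle counting,
shifted power iteration) on hundreds of small random graphs.

By default the final feature matrix is standardized per column across
nodes (constant columns become zero): OS, NS and CV blocks live on very
different scales, and unstandardized concatenations train poorly.

## The classifier

The embedding is the two-layer spectral GCN
$F = \mathrm{ReLU}(\hat A\,\mathrm{ReLU}(\hat A X W^0)\,W^1)$ with both
hidden widths equal to the embedding dimension $h$. The graph-level
representation concatenates average and maximum pooling,
$H^G = \frac1n \sum_i f_i \,\|\, \max_i f_i \in \mathbb{R}^{2h}$. The
architecture defines node embeddings only, so a minimal standard head is
added: a single linear layer $2h \to 2$ with softmax and cross-entropy.

Training uses Adam (the de-facto default for this architecture) with the
study's hyperparameters as defaults: embedding dimension 32, 100 epochs,
learning rate 0.001, weight decay $10^{-3}$ (applied as an L2 gradient
term on the three weight matrices, not the bias). Cohorts here are at
most a few hundred graphs, so training is full-batch by default;
`batchSize` is configurable. Weights are Glorot-uniform initialized from
a seeded RNG, and with full-batch training the whole fit is
deterministic given the seed — a reproducibility contract the test suite
enforces. No dropout, early stopping or validation split is enabled by
default. Forward, backpropagation (including the subgradient routing of
max-pooling to the first maximizing node, and the ReLU derivative taken
as zero at the kink) and Adam are implemented directly in R; gradients
are verified against central finite differences at $10^{-4}$ on small
toys. Per-sample products $\hat A X$ are precomputed once per training
run.

## Evaluation protocol

Each repeat draws a random split with a fixed training fraction (default
0.8; test size $\mathrm{round}(0.2N)$), trains on the training fold and
evaluates on the held-out fold. Splits are *not* stratified — matching
the plain "random 80%" protocol — so a draw can in principle leave one
class out of the training fold; such degenerate splits are redrawn from
a derived seed with a logged message. Metrics are computed from the
confusion counts exactly as defined (Accuracy, Sensitivity, Specificity,
Precision, F1), and AUC is the Mann–Whitney rank statistic with midranks
for ties — exact and oracle-testable, unlike a trapezoidal ROC
approximation. A metric with an empty denominator (e.g. precision with
no positive predictions) is reported as 0 and flagged rather than NaN,
so aggregation over 100 repeats never drops a cell. Aggregation reports
the mean and the *population* standard deviation over repeats (a
convention has to be fixed; the population form matches "std over the
100 observed runs"). Repeat $k$ uses split seed $\mathrm{seed}+k$ and a
training seed derived from the same master seed, making every grid cell
reproducible bit for bit.

## The synthetic generator

Real resting-state cohorts cannot ship with a package, so the generator
emulates their second-order structure — which is exactly what PC, SR and
LR consume. Each subject is $m$ i.i.d. draws from
$\mathcal{N}(0, \Sigma_g)$ plus i.i.d. observation noise
$\mathcal{N}(0, \sigma^2)$: $\Sigma_g$ has unit diagonal, zeros off the
designated effect block, and correlation $\rho_0$ (group 0) or
$\rho_0 + \delta$ (group 1) on the block pairs. Positive definiteness is
checked by eigendecomposition, with a logged diagonal-loading fallback
(the constraint $|\rho_0| + \delta < 1$ makes loading unnecessary for
valid specs). Default shapes mirror AAL-parcelled cohorts: $n = 116$,
$m = 135$.

The default effect is *sign-symmetric*: $\rho_0 = -0.2$, $\delta = 0.4$,
so block pairs flip from anticorrelation to correlation of equal
magnitude between groups. This choice is deliberate and worth spelling
out. A magnitude-changing effect (say $0.2 \to 0.6$) alters the absolute
edge weights and therefore the node degrees, so the group signal leaks
into $\hat A$ itself and even a one-hot-featured GCN classifies almost
perfectly — the feature ablation collapses. A sign-flip effect leaves
$|A|$, and hence $\hat A$, identically distributed across groups: node
identity alone is uninformative (OH sits at chance), while the signed
correlation pattern — visible to CV features — carries the full signal.
That is also the scientifically interesting regime: anticorrelation
reversals between resting-state networks are a real rs-fMRI phenomenon,
and second-order sign structure is precisely what magnitude-based graph
summaries miss. Observation noise ($\sigma = 0.5$ by default) attenuates
all observed correlations by $1/(1+\sigma^2)$ without breaking the
symmetry.

What the generator does **not** emulate: hemodynamic response,
autocorrelated BOLD noise, head motion, scanner effects, site
heterogeneity, or heterogeneous per-subject effect sizes. Passing tests
on synthetic cohorts therefore demonstrates that the pipeline recovers
controlled second-order group structure — not that any particular
accuracy level transfers to clinical data, where effects are far weaker
and less homogeneous (accuracies there are typically in the 0.55–0.80
range rather than the near-perfect recovery seen on clean simulations).

## Numerical and design choices

* Eigen-decompositions treat matrices as symmetric
  (`eigen(symmetric = TRUE)`); raw estimator output is re-symmetrized
  against floating-point asymmetry.
* Proportional thresholding keeps ties at the cut weight, so the kept
  fraction can slightly exceed the request; the rule is deterministic.
* Max-pooling gradients follow the first maximizing node on ties
  (column-wise `which.max` order).
* Softmax is computed with the max-logit shift; cross-entropy clips
  probabilities at $10^{-12}$.
* Grid CSVs are written with 17 significant digits so a write/read round
  trip is lossless and reruns are byte-identical.
* The per-ROI lasso uses `glmnet` at `thresh = 1e-10` with a short
  warm-start path; its solutions are checked against the closed-form
  soft-threshold solution on orthonormal designs.

## Problem sizes used in the shipped experiments

The packaged experiments and the reproduction script run at a reduced
scale chosen to make the full study convenient on a laptop while leaving
the qualitative conclusions intact: cohorts of 30 ROIs × 150 time
points × 40 subjects per group, 20 evaluation repeats, and the default
training hyperparameters. The unit and property tests use still smaller
cohorts (6–12 ROIs) and brute-force oracles on graphs of up to 6 nodes,
where exhaustive path enumeration is feasible.

## Known limitations

* SR/LR hyperparameters for clinical data are genuinely unknown; the
  defaults are reasonable grid midpoints, not tuned values.
* Which three clustering-coefficient definitions and which efficiency
  normalization "the" node-statistics feature should use is a
  convention; other choices would shift NS-based results somewhat.
* The GCN is CPU-only R; it is fast for cohort-scale graph counts
  (hundreds of graphs, ≤ 200 nodes) but not intended for large graph
  corpora.
* Exact reproduction of published clinical-cohort tables is out of
  reach by design: split seeds and estimator settings of such studies
  are underdetermined, which is why evaluation here is property-based
  on controlled synthetic cohorts.
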