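# bfnGCN

Node features for GCN-based classification of brain functional networks.

## The problem

A brain functional network (BFN) describes one subject's resting-state
fMRI scan as a graph: nodes are atlas regions of interest (ROIs), edges
encode the statistical dependence between the regions' BOLD time series.
Classifying such graphs (patient vs control) with a graph convolutional
network (GCN) requires two inputs per subject — the adjacency matrix *A*
and a node feature matrix *X* — and while the adjacency is the object of
intense methodological attention, the choice of *X* is usually an
afterthought. `bfnGCN` is a pipeline for studying that choice
systematically. It is aimed at researchers in network neuroscience and
graph machine learning who want a controlled, reproducible testbed for
node-feature ablations.

## What it implements

**Network estimation.** From each subject's ROI × time matrix, the
adjacency is estimated by

- *PC* — Pearson's correlation,
  `c_ij = (s_i − s̄_i)ᵀ(s_j − s̄_j) / (‖s_i − s̄_i‖ ‖s_j − s̄_j‖)`;
- *SR* — sparse representation: per-ROI lasso regressions
  `min_w ½‖s_i − S_{−i}w‖² + λ‖w‖₁`, symmetrized;
- *LR* — low-rank representation: nuclear-norm proximal denoising of the
  correlation matrix by singular-value soft-thresholding.

**Node features.** Four families, individually or concatenated: *OS*
(the raw signals, d = m), *OH* (one-hot node indicators, d = n), *NS*
(eight node statistics — three local clustering coefficients, four
centralities, local efficiency; d = 8) and *CV* (each node's row of the
correlation matrix, d = n).

**Classifier.** The two-layer spectral GCN

```
F = ReLU( Â · ReLU( Â X W⁰ ) · W¹ ),   Â = D^(−1/2) (A + I) D^(−1/2)
```

with a mean‖max readout `H_G = (1/n) Σ f_i ‖ max_i f_i`, a linear softmax
head, and Adam training (embedding 32, 100 epochs, learning rate 0.001,
weight decay 1e−3 by default).

**Evaluation.** Repeated random 80/20 train/test splits (100 by default)
reporting mean ± std of Accuracy, Sensitivity, Specificity, Precision,
F1 and rank-statistic AUC, assembled into an estimator × feature-set
grid.

**Synthetic cohorts.** A generator draws two labelled groups of subjects
from multivariate normal models whose latent correlation differs on a
designated ROI block, so the whole pipeline is testable without any
clinical data.

## Worked example

```r
library(bfnGCN)

spec <- cohortSpec(nRois = 30, nTimepoints = 150, nSubjectsPerGroup = 40,
                   effectBlock = roiBlockPairs(1:5), effectDelta = 0.4,
                   seed = 11)
cohort  <- sampleCohort(spec)
samples <- buildGraphSamples(cohort, "pc", "CV")
res     <- runExperiment(samples, trainConfig(), nRepeats = 20, seed = 42)
round(res$mean, 3)
#>   acc   sen   spe   pre    f1   auc
#> 0.981 0.975 0.989 0.986 0.979 0.998
```

The cohort has 80 subjects whose groups differ only in the sign of the
latent correlation on the 10 ROI pairs of a 5-ROI block. With
correlation-vector (CV) node features the GCN recovers that group signal
almost perfectly; rerunning the same experiment with one-hot features
(`"OH"`) yields mean accuracy near 0.45 — chance level — because the
effect was designed to leave edge magnitudes, and hence the normalized
adjacency, uninformative.

The full ablation grid (12 feature rows × chosen estimators) is driven
by a YAML config:

```r
runConfig("experiment.yaml", outDir = "results")
```

which writes `grid.csv` / `grid.md`, a per-repeat JSONL log, the
resolved config and the seed list. A thin command-line front end with
`simulate` / `estimate` / `featurize` / `run` subcommands ships in
`inst/scripts/bfngcn.R`.

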