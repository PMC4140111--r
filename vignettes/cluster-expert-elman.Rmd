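---
title: "Cluster-wise Elman networks with PLS feature reduction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-wise Elman networks with PLS feature reduction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmanet)
library(dplyr)
```

## The problem

Small tabular datasets with many correlated covariates — a few decades of
yearly weather summaries against a pest-outbreak degree, say — are awkward
for neural networks twice over. Redundant features inflate the input layer
and slow or destabilize training, and heterogeneous samples (years that
belong to distinct regimes) force a single network to fit a multimodal
mapping. `elmanet` attacks both at once:

* **feature ("longitudinal") reduction** — partial least squares compresses
  the p features to l latent components chosen by cross-validated PRESS,
  keeping only directions that covary with the response;
* **sample ("horizontal") reduction** — UPGMA hierarchical clustering on
  Mahalanobis distances partitions the training samples into K subclasses,
  and one small Elman network expert is trained per subclass;
* **routing** — a new sample is standardized, projected onto the latent
  components, assigned to the nearest subclass centre (Mahalanobis), and
  recognized by that subclass's expert.

The pipeline and five baselines (plain BP and Elman networks, PCA- or
PLS-reduced single networks, clustering without reduction) share one
benchmark harness, `plsca_benchmark()`.

## Model components

### Standardization

Features are centred and scaled to `(x - mean) / sd_pop` with the
*population* (1/n) standard deviation; the clustering covariance (below)
uses the n−1 convention. The two denominators are deliberately not unified:
each is implemented exactly as conventionally written for its role. A
constant feature is an error naming the column.

### NIPALS partial least squares

`pls_fit()` extracts components one at a time: the weight vector `w`
maximizes covariance between the X-score `t = Xw` and the current Y
residual; Y is regressed on `t`; both matrices are deflated. The stored
factors give the projection `R = W(PᵀW)⁻¹` (so scores of new data are
`XR`, reproducing the training scores exactly) and the coefficient matrix
`B = W(PᵀW)⁻¹Qᵀ`. Two properties anchor the test suite: scores are
mutually orthogonal, and with all `min(n-1, p)` components on a full-rank
tall X the fitted values equal ordinary least squares. Unlike OLS the fit
survives p ≥ n and collinearity — the reason PLS rather than PCA backs the
default pipeline: a subclass can easily have fewer members than features.

The component count is chosen by `pls_select_ncomp()`: K-fold
cross-validated PRESS, global minimum, ties to the smaller count. Folds
are contiguous blocks by default — deterministic, and the natural choice
for chronologically ordered records; shuffled folds sit behind a seed
flag. K defaults to 10 (the literature's conventional default; the method
description leaves K open). A first-local-minimum rule is available via
`rule = "first_local_min"`.

### Mahalanobis UPGMA clustering

Distances between training samples are `d(x, y) = sqrt((x-y)ᵀ V⁻¹ (x-y))`
with V the pooled sample covariance of the working space; when V is
singular (small subclasses, p ≥ n, redundant features) a Moore–Penrose
pseudo-inverse is used, with a ridge option (`V + εI`, ε relative to the
mean eigenvalue) behind a config switch. `upgma()` merges the two nearest
clusters repeatedly; the between-cluster measure is the square root of the
arithmetic mean of squared cross-pair distances, maintained by the
size-weighted Lance–Williams update on squared distances
`D²ₖᵣ = (nₚ/nᵣ)D²ₖₚ + (n_q/nᵣ)D²ₖ_q`. (The common shorthand that mixes a
squared and an unsquared term in this update is treated as a typo: only
the squared form reproduces the class-average definition, which the tests
verify against a naive recompute-from-scratch oracle.) Ties break to the
smallest index pair, making trees fully deterministic. Partitions come
from `cut_upgma()` by either a subclass count k or a dendrogram height
cutoff λ; 3–6 subclasses is the recommended range and k = 3 the default.
Subclasses smaller than `min_subclass` (default 3) are merged into the
nearest-centre subclass before training, since a 1–2 sample subclass
cannot train a network.

### Elman network experts

Each expert is a sigmoid-hidden, linear-output network whose hidden layer
also receives the previous hidden activation through a context
("undertake") layer of equal size:
`x(k) = f(w₂ x_c(k) + w₁ u(k−1) + b₁)`, `x_c(k) = x(k−1)`,
`y(k) = w₃ x(k) + b₂`. Biases are included — the classical equations omit
them, but a zero-bias sigmoid layer cannot shift its activation; this is a
documented addition. The hidden size is the empirical formula
`s = round(sqrt(0.43nm + 0.12m² + 2.54n + 0.77m + 0.35) + 0.51)` with
n = the expert's input count (l after reduction) and m = 1 output
(nearest-class decoding of a single linear output; one-hot multi-output is
supported by the same code).

**Static classification with a recurrent net.** The samples here are not a
sequence, so order-dependent predictions would be indefensible. The
default `context_mode = "reset"` re-seeds the context per sample: pass 1
runs with zero context and its hidden activation becomes the context for
pass 2, which produces the output. The recurrence therefore participates
(setting w₂ = 0 changes predictions) without introducing order
dependence; `"carry"` mode is available for genuinely sequential data.

**Training.** `elman_train_lm()` is batch Levenberg–Marquardt: the
Jacobian of per-sample residuals w.r.t. all weights and biases is built
analytically with the context treated as a constant (the truncated Elman
gradient — the original simplification that makes batch Gauss–Newton well
defined), the step solves `(JᵀJ + μI)Δ = Jᵀe`, and a step is accepted only
if the *full* two-pass SSE decreases, so the accepted-step error trace is
non-increasing by construction. Defaults: μ₀ = 10⁻³, ×10 on rejection,
×0.1 on acceptance, stop at SSE ≤ 10⁻³, 2000 epochs, or μ > 10¹⁰.
`elman_train_gdm()` implements the classical gradient-descent-with-
momentum rule on the same gradient. Training effort is counted in
*epochs* (accepted weight updates); whether "steps" means epochs or
individual updates is ambiguous in common usage, so the convention is
stated here once.

The feedforward baseline (`recurrent = FALSE`, variant `"bp"`) freezes
w₂ at zero, excludes it from training, and draws w₁/w₃ identically to the
recurrent net under the same seed, which the collapse tests exploit.

### Pipeline variants and alternative stage orderings

`plsca_fit()` composes the stages in the shipped order: reduce globally →
cluster the training set → train per-subclass experts → route test
samples. `fit_thought()` exposes the three alternative orderings mainly
for their failure modes: clustering training and test samples jointly
(orderings 1 and 3) can isolate a subclass with no trainable members —
an error, deliberately; per-subclass PLS (orderings 1 and 2) can select
different component counts per subclass, reported as a warning. With
K = 1 the default pipeline collapses exactly onto the PLS-only variant —
a tested identity.

## The synthetic-data generator

`simulate_dataset()` draws a Gaussian mixture in a low-dimensional latent
space (cluster centres at pairwise distance ≥ `separation`, in units of
the unit within-cluster sd), lifts it through a random full-rank loading
to the feature space, and appends `redundancy` noisy copies of existing
columns. This reproduces exactly the two pathologies the pipeline targets
— latent low rank with redundant correlated features, and cluster
substructure — while remaining fully controlled: the generating partition
and latent coordinates are returned for recovery tests.

Three frozen presets fix the study conditions. `midge_like` (60 × 14,
3 latent dimensions, 3 clusters, separation 8, 4 redundant columns,
noise sd 0.1, ordinal labels = cluster id, split 45/15) mirrors the shape
of a 60-season weather/occurrence-degree record; `ionosphere_like`
(351 × 34, binary labels, split 300/51) mirrors the classic radar-return
benchmark; `separable_benchmark` (120 × 14, otherwise midge-shaped, split
90/30) is the end-to-end fixture, sized so a held-out accuracy is
estimated on 30 rather than 15 samples. Redundancy noise sd 0.1 makes the
copied columns correlate above 0.9 with their sources. What the generator
does *not* emulate: real covariate marginals (weather variables are not
Gaussian), label noise, and class imbalance — so passing tests show the
machinery is correct and the pipeline's relative ordering holds under its
own assumptions, not that the field results transfer to any particular
real dataset.

## Numerical choices

* NIPALS: tolerance 10⁻¹⁰ on the score change, 500 inner iterations
  (exceeding them is an error), rank exhaustion declared when the X
  residual drops below 10⁻⁸ of its initial norm — PRESS is flat beyond
  that point and the smallest-count tie-break applies.
* A constant response within a PLS fit (a single-label subclass, routine
  for the per-subclass orderings) standardizes with unit scale and yields
  ~zero coefficients rather than erroring; constant *features* still
  error.
* Pseudo-inverse vs ridge: `safe_inverse()` uses `solve()` when well
  conditioned (reciprocal condition ≥ 10⁻¹⁰), otherwise MASS::ginv;
  `inverse = "ridge"` uses ε = 10⁻⁸ · trace(V)/p.
* Merge ties and equidistant routing both break to the lowest index, so
  every result is reproducible bit-for-bit from (data, config, seed); the
  fitted model records all of these.

## A known limitation, quantified

Clustering with Mahalanobis distance under the *total* sample covariance
has a structural weakness on strongly clustered data: the whitening
shrinks precisely the directions that separate the clusters (their
between-cluster variance dominates the total), so the whitened
between-centre distance saturates near a constant as the raw separation
grows, while any latent direction carrying no between-cluster variance
keeps unit whitened scale. With 3 clusters — whose centres span only a
plane — a 3-dimensional latent space always contains such a direction. In
package experiments the UPGMA partition of `midge_like` training blocks
recovers the generating partition perfectly in only roughly half to
three-quarters of seeds (raw feature space is worst; the PLS score space,
which suppresses response-uncorrelated directions, is best), and raising
the separation from 8 to 30 does not help, exactly as the saturation
argument predicts. Euclidean UPGMA recovers the same partitions
essentially always. The package keeps the Mahalanobis metric because it
is the method as defined — the tests report recovery honestly rather than
substituting a friendlier metric — and end-to-end accuracy is robust to
imperfect partitions anyway: experts are trained on the partition that
routing also uses, so a "wrong" but consistent partition still classifies
well, which is why held-out accuracy on `separable_benchmark` sits at
95–100% across seeds for the full pipeline.

## Problem sizes used in the checks

The automated checks run at deliberately modest sizes: 50 random 30 × 5
instances for the least-squares identity, 100 random n ≤ 12 matrices for
the UPGMA oracle, 10 seeds each for PRESS recovery (100 × 14), partition
recovery (45 × 14), and the end-to-end benchmark (90/30 split, six
variants). These sizes were chosen as the smallest at which the
properties under test are non-trivial; every one is regenerated
programmatically at run time.
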