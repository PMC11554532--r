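---
title: "Methods: residual CNN feature fusion for ultrasound plane classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual CNN feature fusion for ultrasound plane classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(planefusion)
```

# The pipeline

The package implements a five-stage framework for classifying fetal
ultrasound standard planes: (1) train two compact residual CNNs on a
50/50 stratified split of a folder-per-class image dataset; (2) extract
deep features from each model's global-average-pooling (GAP) layer,
giving two N × 2048 blocks; (3) select a subset of each block's columns
with a wrapper metaheuristic (IGNDO); (4) fuse the two selected blocks
by serial (columnwise) concatenation; (5) score shallow neural-network
classifiers on each of the five feature sets (two raw blocks, two
selected blocks, the fusion) by stratified 10-fold cross-validation, and
compare a high- and a low-accuracy classifier with a paired t-test on
their per-experiment accuracies.

The underlying assumption is the usual transfer-by-features one: a CNN
trained for plane classification concentrates class-relevant information
in its penultimate pooled activations, parts of which are redundant or
irrelevant, so a selection step can shrink the representation (and
classifier cost) without losing — and sometimes improving — downstream
accuracy, while fusing the two models' complementary views recovers
information either one misses.

# Architectures

`build_three_residual_model()` and `build_four_residual_model()` emit
explicit layer graphs: ordered layer descriptors plus directed edges,
with skip connections expressed as ordinary edges into 2-input `add`
layers. `infer_shapes()` walks the graph, checks that both inputs of
every addition agree, and counts parameters
(k²·c_in·depth + depth per conv, 2·c per batchnorm, in·out + out per
fully connected layer).

Design choices a reader should know:

- **Width scaling.** The narrative depth profile of these models
  (interior widths 512/1024/2048) is kept as a *relative* profile but
  scaled by a divisor (default 8 → 64/128/256). Taken literally those
  widths contradict the models' own headline parameter budgets — one
  1024→1024 3×3 convolution alone costs 9.4M parameters, more than the
  whole 3-block model is supposed to have. With the default divisor the
  3-block model has ≈7.4M parameters and the 4-block model ≈5.4M, both
  comfortably below the ResNet-18 (11.7M) and ResNet-50 (23.5M)
  reference budgets they are meant to undercut. The conv feeding GAP
  always keeps depth 2048: that is what fixes the published N × 2048
  feature width. `width_divisor = 1` recovers the literal profile.
- **Padding.** All layers use same-style padding with ceiling division
  of spatial dims under stride; this is the only convention under which
  long stacks of stride-2 3×3 convolutions keep positive spatial extent
  down to GAP. Spatial dims therefore never collapse below 1; instead
  the builders require input spatial dims ≥ 32 up front.
- **Shortcuts.** When a block's output shape disagrees with its input,
  a 1×1 projection convolution (with matching stride) is inserted on
  the shortcut path — standard residual-network practice; with the
  default profiles all shortcuts are identity.
- **Activation bookkeeping.** Narratively doubled relu layers are
  recorded once (relu∘relu = relu; a test verifies the forward pass is
  unchanged by collapsing them). The 3-block model carries no batch
  normalization; the 4-block model has one batchnorm per residual
  block.
- **Desk scale.** `micro_cnn_graph()` is a one-block residual network
  (with batchnorm, which makes small-data SGDM training robust across
  learning rates) used by the test suite and the synthetic pipeline; it
  is the programmatic form of a hand-written graph document, which the
  JSON loader accepts anyway.

# Training engine

Graphs are executed by a small built-in engine (im2col gather + BLAS
matrix products; exact analytic gradients, verified numerically in
development). The optimizer is SGDM: v ← m·v − lr·(∇ + λw), w ← w + v,
with L2 decay applied to weight matrices only. Defaults in
`train_config()` are the Bayesian-optimization-selected settings:
learning rate 0.000274, mini-batch 128 (clamped to the dataset size),
momentum 0.699, L2 weight 1e-6. The epoch budget is not part of those
settings; the default is 50 epochs with early stopping on a stratified
10% validation slice (patience 10). Desk-scale runs on synthetic images
use a larger learning rate (0.04) because the micro networks are
batch-normalized and the images tiny; the published rate is tuned to
GPU-scale training and merely crawls here.

Initialization is He-normal for conv and hidden fc weights; the fc
layer feeding softmax uses a deliberately small scale so an untrained
classifier starts at the uniform-prediction cross-entropy ln k (a test
asserts ln 4 ± 0.1 for four balanced classes). Non-finite training loss
aborts with a divergence error suggesting a lower learning rate.

# Bayesian hyperparameter optimization

`bo_search()` is generic minimization over a boxed space: a Latin
hypercube initial design, then a Gaussian-process surrogate (Matérn 5/2
with per-dimension lengthscales, hyperparameters by marginal-likelihood
maximization, small jitter for stability) and the closed-form expected
improvement for minimization, EI = σ·(z·Φ(z) + φ(z)), maximized over a
2048-point random pool plus a local L-BFGS-B refinement. Learning rate
is searched on a log scale over [1e-5, 0.999] — wide enough to represent
the published optimum 0.000274 despite the nominally narrower printed
range — and integer parameters are rounded at evaluation time. The full
training objective of the original study is GPU-scale; the package
demonstrates and tests BO on analytic objectives and exposes it for
tiny training runs.

# GNDO and the selection variant

GNDO keeps a population of N positions in box bounds. Per iteration each
individual draws α ~ U(0,1) and takes local exploitation (α > 0.5) or
global exploration, then greedy screening accepts a (bounds-clamped)
trial only on strict fitness improvement, which makes the best-so-far
trace monotone. The penalty factor η = √(−log λ₁)·cos(2πλ₂) (phase
shifted by π when a > b) is drawn with scalar (a, b) and per-dimension
(λ₁, λ₂), following the algorithm's reference implementation; a scalar η
moves all coordinates in lockstep and measurably stalls in higher
dimensions (it fails the package's own sphere benchmark, which requires
beating equal-budget random search by ≥ 10×). Defaults are the study
settings N = 20, T_max = 200. One shared RNG stream per run with a
documented draw order makes traces bitwise reproducible under a seed.

For feature selection, positions live in [−4, 4] per feature — wide
enough for logistic scores to approach 0/1 without flat saturation —
and are mapped to scores by `position_to_scores()` (logistic, clipped
to (1e-12, 1 − 1e-12)). A position's fitness is

  f = (1 − w)·err + w·mean(scores),  w = 0.01,

where `err` is the hold-out error of a nearest-centroid classifier (on
standardized features, stratified 30% hold-out fixed per run) restricted
to columns with score ≥ 0.5. The sparsity term uses the *mean score*
rather than the binary mask width: the error term only changes when the
mask changes, so a smooth surrogate keeps pressure on redundant columns
even between mask flips. The weight 0.01 keeps a single informative
column's error contribution an order of magnitude above the largest
possible sparsity gain, so relevance always dominates parsimony.

At termination the best position's scores are thresholded by their own
binary cross-entropy: CE = −(1/D)·Σ[bⱼ log pⱼ + (1−bⱼ) log(1−pⱼ)] with
bⱼ = [pⱼ ≥ 0.5], and column j is selected iff pⱼ ≥ CE. Two things are
worth knowing about this scalar-threshold rule. First, an all-zero mask
falls back to the 0.5 threshold (with a warning) and, as a last resort,
to the single best-scoring column — the result is never empty. Second,
because CE sits well below 0.5 once scores are partially polarized, the
rule re-admits middling-score columns: on the planted 300 × 100
benchmark the optimizer's own 0.5-mask is typically ~35–40 columns wide
while the CE mask lands around 45–55. That behavior is inherent to the
scalar reading of the threshold (the alternative — comparing each score
to its own entropy — collapses to a fixed ≈0.567 cutoff and was not
adopted). The recovery property that matters — planted informative
columns selected with high recall — holds robustly (median recall 1.0
over the five test seeds).

# Evaluation

The five classifier families follow common classification-app layouts:
narrow (10), medium (25), wide (100), bilayered (10, 10), trilayered
(10, 10, 10) hidden relu units, softmax output, trained with the same
SGDM engine on standardized features. Metrics come from the pooled
confusion matrix of stratified k-fold cross-validation (predictions
pooled, scored once): accuracy, macro precision/recall/F1 (macro over
classes present in truth; a class never predicted contributes precision
0, logged), macro one-vs-rest AUC (via pROC), FNR = 100 − macro recall,
generalized (Gorodkin) multiclass MCC, and Cohen's kappa. `k = n` gives
leave-one-out; otherwise k is reduced to the smallest class size with a
warning.

The paired t-test takes the per-experiment accuracies of a high- and a
low-accuracy classifier: diffs = |high − low|, μ their mean, σ the
sample SD (N − 1), t = √N·μ/σ against the two-tailed critical value at
df = N − 1. Because such tables are usually printed at four decimals,
the report carries both the full-precision chain and a chain with μ and
σ rounded to 4 decimals before forming t. Degenerate inputs are explicit:
identical vectors give t = 0 ("no difference"), a perfectly constant
positive difference gives t = +∞ with a flag.

# Synthetic data: what it does and does not emulate

`generate_plane_images()` draws one geometric motif per class — filled
ellipse (abdominal circumference), elliptical ring (biparietal skull
outline), thin bright bar (femur), plain background ("no plane") — under
a fan-shaped insonation mask, multiplied by Rayleigh speckle (scale 1,
normalized to unit mean) and clipped to [0, 1], with ±10% position and
±15% scale jitter so the task is not template matching. This reproduces
the two properties the pipeline's tests need: class-conditional
structure a small CNN can learn, and ultrasound-like multiplicative
texture. It does *not* attempt real fetal anatomy, acoustic shadowing,
attenuation, or clinical calibration — passing tests say the machinery
works, not that it meets clinical performance.

`generate_feature_matrix()` plants informative columns: class c shifts
column j by ±effect/2 under a cyclic sign pattern, so every informative
column separates the classes into two groups and distinct classes have
distinct patterns; remaining columns are standard normal. Effect size 2
(within-class SD units) at n = 300 makes the planted set recoverable by
a per-column one-way F-test, which is the independent oracle the
selection tests are checked against.

# Problem sizes in the test suite

The suite exercises every stage at sizes chosen to keep a full run
around two minutes on one CPU: CNN smoke training on 32–48 px images
with tens of images per class; GNDO benchmarks on the 10-D sphere with
the study's N = 20, T = 200; selection recovery on 300 × 100 planted
matrices over five seeds; and an end-to-end pipeline run with 40 images
per class at 32 px, 15 epochs, micro models with 32- and 48-wide GAP
layers. The full 224 × 224 architectures are constructed, shape-checked
and serialized in the tests, but trained only in miniature form — their
full-scale training is exactly the GPU-sized computation this package
deliberately does not reproduce.

# Known limitations

- The built-in engine is single-threaded R + BLAS, fine for micro
  networks and shallow classifiers, far too slow for the full 224 px
  architectures.
- Exact parameter counts of the two builders depend on conventions
  (width divisor, biases, projection shortcuts) the source narrative
  does not fix; the package treats the published bounds, not the point
  counts, as the testable surface.
- The scalar cross-entropy threshold admits middling-score columns (see
  above); selected widths should be read as "roughly half the block",
  not as a sharply tuned subset size.
- BO assumes a smooth objective; noisy training objectives at tiny n
  can mislead the GP surrogate.
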