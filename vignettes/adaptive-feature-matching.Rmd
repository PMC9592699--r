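---
title: "Adaptive feature-matching dual-source transfer learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive feature-matching dual-source transfer learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(afmtl)
```

## The problem

Small medical-imaging cohorts overfit deep networks. A standard remedy is
transfer learning, but wholesale transfer (fine-tuning from one large source
task) imports whatever the source learned, relevant or not, and when the
semantic gap between source and target is large the irrelevant features
actively hurt — *negative transfer*. The method implemented here addresses
binary classification of solitary pulmonary solid nodules on CT (granuloma
vs adenocarcinoma, per-patient) and replaces wholesale transfer with
*selective* transfer from **two** heterogeneous sources at once: a
natural-image network and a histopathology-tile network. Nothing is copied
into the target network; instead the target is trained to *match* those
source feature maps that demonstrably help its own task, while a separate
classifier half turns the trained convolution kernels into per-patient
features and classifies them with a sparse Bayesian ELM ensemble.

`afmtl` implements the full method at desk scale: every computation of the
original is present, but the networks are small CNNs and the cohorts are
synthetic, so the whole pipeline runs on one CPU in minutes.

## Feature matching between heterogeneous networks

Let $S_k^m(x)$ be the feature map of layer $m$ of frozen source network
$k \in \{1, 2\}$, and $T_\theta^n(x)$ the target network's map at layer $n$.
Three learned pieces mediate the transfer for every candidate pair $(m, n)$:

* **Adapters** $r_{\upsilon_k}$ — pointwise (1×1) convolutions mapping the
  target map's channels onto the source map's channel count. They exist only
  during training. One adapter per (source, $m$, $n$) pair; a single adapter
  per source cannot satisfy the channel contracts when stages have different
  widths.
* **Channel weights** $w_c^{m,n} = f_{\phi}(\mathrm{GAP}(S_k^m(x)))$ — a
  one-layer softmax head on the source map's global mean pooling. The
  weights are per input image, positive, and sum to one over channels:
  *which* source feature maps deserve matching.
* **Pair weights** $\lambda_k^{m,n} = g_{\Phi}(\mathrm{GAP}(S_k^m(x)))$ — a
  one-layer head through ReLU6, so $\lambda \in [0, 6]$: *where* transfer
  should flow, with useless layer pairs drivable to exactly zero.

The weighted matching loss for one pair is the channel-weighted mean squared
distance between the adapted target map and the source map, normalized by
the spatial size $H \times W$ and averaged over the batch; the total
transfer loss sums $\lambda$-weighted pair losses over both sources and all
candidate pairs, and the training objective is

$$L_{total} = L_{org} + \varsigma\, L_{wfm}, \qquad \varsigma = 0.5 .$$

Design points the original leaves open, decided here:

* **Candidate pair set** $P_k$: all stage-by-stage combinations (4 source
  stages × 4 target stages by default). The pair weights are meant to prune
  this set adaptively, and the exported weight grids show they do.
* **Spatial mismatch**: the source map is bilinearly resized to the target
  map's spatial size before the distance, preserving target-side geometry.
* **$\lambda$ is not normalized across pairs** — the published weight grids
  show raw per-pair values, and normalization would couple unrelated pairs.
* **Head initialization**: the channel heads start at zero (uniform softmax
  weights). The pair heads start with zero weights but bias 1: at a zero
  pre-activation ReLU6 has zero gradient, so an all-zero start could never
  turn transfer on; bias 1 starts every pair at $\lambda = 1$ inside the
  linear region.
* Per-image $\lambda$ and $w$ (they are functions of the input) are used in
  the loss; exported grids report batch means.

## The diverse-branch-block target network

Every main-path convolution of the target network is, at training time, a
sum of four batch-normalized branches: a $K\times K$ convolution, a
$1\times1$ convolution, a $1\times1\to K\times K$ sequence, and a
$1\times1\to K\times K$-average-pool sequence. The differing receptive
fields and path complexities enrich the features the kernels learn. Because
convolution is homogeneous and additive, the whole block collapses — once
batch-norm statistics are frozen — into one $K\times K$ kernel plus bias:
batch norm folds into a per-channel kernel scale and bias, the sequential
branches merge by tensor contraction of the pointwise into the spatial
kernel, and average pooling is itself a convolution with $1/K^2$ on the
channel diagonal.

Two implementation details make the collapse *exact* rather than
approximate at the borders:

* In both sequential branches the block's zero padding is applied by the
  **first** ($1\times1$) stage and the second stage runs unpadded. Padding
  the second stage instead would surround the intermediate map with zeros
  where the merged kernel implies the fused bias value.
* The equivalence is defined in inference mode: the multi-branch forward
  with running statistics equals the collapsed convolution for every input
  (`dbb_equivalence_check()` verifies `< 1e-4` over random configurations;
  in double precision the observed deviations are at the 1e-13 level).

Shortcut 1×1 projections of the resnet18-style backbone stay plain
convolutions; only main-path convolutions carry blocks. Counting collapsed
kernels over the main path of the resnet18-style target gives
$64 + 2\cdot2\cdot(64+128+256+512) = 3904$, which is the per-patient
feature dimension at full scale. The desk-scale default target is a
4-stage, 8-unit CNN with widths (8, 8, 16, 16, 32, 32, 64, 64), giving
$L = 240$ features. Even kernel sizes, dilation, and grouped convolution are
unsupported by design.

## Four-stage training

Each step reuses one mini-batch across four stages (reusing the batch is an
interpretation; the stages are described as operating "under the samples
used in the first three stages"):

1. one SGD-momentum step on $(\theta, \upsilon)$ minimizing $L_{total}$;
2. $T$ steps (default $T = 2$) on $(\theta, \upsilon)$ minimizing $L_{wfm}$
   alone — the target selectively imitates source features;
3. one step on $(\theta, \upsilon)$ minimizing $L_{org}$;
4. one Adam step on the matching heads $(\phi, \Phi)$, rewarding weight
   settings under which stages 2–3 lower the task loss quickly.

Stage 4 is stated in the original only as "measured according to the change
in $L_{org}$"; here it is a first-order hypergradient. With
$\theta' = \theta - \eta \nabla_\theta L_{wfm}(\theta; \phi, \Phi)$,

$$\nabla_{\phi,\Phi} L_{org}(\theta') =
  -\eta\, \nabla^2_{(\phi,\Phi),\theta} L_{wfm} \cdot \nabla_{\theta'} L_{org},$$

and the mixed second derivative is approximated by a symmetric finite
difference of $\nabla_{\phi,\Phi} L_{wfm}$ at $\theta \pm \varepsilon v$
with $v = \nabla_\theta L_{org}$ (reused from stage 3) and
$\varepsilon = 0.01 / \lVert v \rVert$, $\eta = T \cdot lr$. The head
gradients at a probed $\theta$ are exact and cheap because the heads' inputs
— pooled maps of the *frozen* sources — do not depend on $\theta$.

Setting $\varsigma = 0$ disables stages 2 and 4 entirely; this is the
no-transfer baseline used in the paired comparison, identical in every other
respect (initialization, batch order, step counts of stages 1 and 3).

Optimizer settings follow the original's choices in kind — SGD with momentum
0.9 and weight decay $10^{-5}$ for $(\theta, \upsilon)$, Adam with weight
decay $10^{-4}$ for the heads — but the learning rates are desk-scale
choices: $10^{-2}$ and $5\times10^{-2}$. The original's $10^{-4}$ rates
belong to 200-epoch runs over hundreds of batches; with tiny cohorts the
whole training is a few dozen steps and those rates cannot move the
parameters measurably. Convergence is a fixed epoch budget (default 10);
sources are trained until their task accuracy saturates (they are separable
by construction) and then frozen — `train_target()` verifies at the end that
no source parameter changed.

## Feature extraction and screening

After training, the target network is collapsed and used as a feature
extractor: each patient's slice images pass through the reparameterized
network; every collapsed kernel contributes the global mean pooling of its
output map (pre-activation); the patient's $L$-vector is the arithmetic
mean over that patient's slices. Slice order is irrelevant by construction.

Features are screened with a two-sided Mann–Whitney U test at $p < 0.05$,
computed with midrank ties; the p-value is exact (full enumeration) for
pooled sizes up to 12 and otherwise uses the normal approximation with
tie-corrected variance and continuity correction. Following the original,
**no multiple-testing correction** is applied by default (a
Benjamini–Hochberg flag exists). Screening uses the training cohort only —
the original does not say, but screening on test labels would leak.
Screened deep features are concatenated with the clinical/CT-finding
columns (categoricals one-indicator-per-level, with the training cohort's
level map reused on test data) and z-scored with training-cohort statistics.

## Sparse Bayesian ELM ensemble

The classifier half is an extreme learning machine — a single hidden layer
whose input weights and biases are standard-normal draws fixed at
initialization — whose output weights $w$ are fitted by sparse Bayesian
regression with an automatic-relevance-determination prior:

$$\Sigma = (A + \beta X^\top X)^{-1}, \quad m = \beta \Sigma X^\top t,
  \quad A = \mathrm{diag}(\alpha),$$

alternated with the evidence-maximizing re-estimates
$\gamma_i = 1 - \alpha_i \Sigma_{ii}$, $\alpha_i \leftarrow \gamma_i/m_i^2$,
$\beta^{-1} \leftarrow \lVert t - Xm\rVert^2 / (N - \sum_i \gamma_i)$.
Precisions reaching $\alpha_{max} = 10^8$ prune their weight to exactly
zero. Numerical choices: $\alpha$ starts at 1, $\beta$ at $1/\mathrm{var}(t)$,
$\beta$ capped at $10^{12}$, at most 300 iterations, convergence when the
max absolute weight change falls below $10^{-6}$; the posterior solve is a
Cholesky factorization of the (symmetric positive definite) precision.
Two printed re-estimation formulas in the source material are typographically
inconsistent (a spurious extra factor of $A$ in the $\alpha$ update; an
$\ell_1$ coefficient $\rho$ that is introduced and never valued): the
classical ARD fixed point is implemented, validated by the evidence-ascent
property and by the closed-form marginal-likelihood cross-check, and $\rho$
is superseded by the ARD prior.

Binary labels are handled as regression on $\{0, 1\}$ with a 0.5 decision
threshold — the Gaussian likelihood implies exactly this. The ensemble
bootstrap-samples $M = 10$ subsets (fraction 1.0, with replacement,
single-class draws retried), fits one base machine per subset, and then —
the distinctive construction — uses the $N \times M$ matrix of base
*continuous scores* as the hidden-layer output of one further sparse Bayes
ELM, the combiner, which can prune entire base classifiers the way ARD
prunes weights.

## Evaluation

Per-patient scores are assessed with the rank-based AUC (half credit for
ties, so AUC $= U/(n_1 n_0)$ — a cross-module identity that is tested),
precision, sensitivity, specificity, accuracy, and F1 at threshold 0.5, and
a stratified percentile-bootstrap 95% CI for the AUC (2000 resamples by
default; the original does not state its CI method).

## What the synthetic data emulates — and what it does not

The real cohorts (two-center CT with radiologist ROIs, TCGA whole-slide
tiles, ImageNet) are not available, so generators stand in:

* `gen_task()` — class-conditional oriented band-pass gratings plus
  per-class blob counts; the two source presets emulate a natural-texture
  task and a purple-tinted microscopy-tile task. Classes are separable by
  construction (a linear probe exceeds 0.9 accuracy).
* `gen_patient_cohort()` — per patient, 3–6 grayscale 224×224 slices with a
  smooth background and a nodule region carrying a class-dependent texture
  orientation (the same family as source task 1, making that source
  informative by construction), stacked into 3-channel images by the same
  sliding-window code real CT slices would use.
* `gen_synthetic_wsi()` — a textured slide with a chosen fraction of blank
  (near-white) 224-tiles, for the tiling/blank-discard path.
* `gen_sparse_regression()` — the ARD support-recovery bed.

Passing tests on these data show the *computations* are right and that the
training dynamics behave (selective transfer helps a small cohort; pair
weights prune), not that the method attains any particular clinical
accuracy: the synthetic textures are far easier than CT appearance, have no
scanner effects, no inter-reader ROI variability, no label noise, and the
desk-scale networks are orders of magnitude smaller than the full-scale
ones. The published cohort AUCs are therefore not reproduction targets.

Desk-scale study sizes (the package defaults): source tasks 24 images per
class at 32×32; training cohorts of 8–14 patients and test cohorts of
20 patients with 3–5 slices each; target input resized to 32×32; 10
training epochs, batch 16. These were chosen once as the smallest sizes at
which source pretraining saturates and the transfer comparison is
informative.

## Preprocessing conventions

Coordinates are 0-based and half-open. ROI crops are resized (bilinear,
half-pixel centres, edge clamping) to 224×224 regardless of aspect ratio —
whether the original squared its boxes first is unstated. Slice stacking
uses stride 1 (all consecutive triples), so $n$ slices give $n-2$ images.
Tiling uses the ceiling grid $K = \lceil X/224\rceil \times \lceil
Y/224\rceil$ with right/bottom zero padding, so tiling partitions the
source pixels. "Blank" is a mean intensity of at least 0.95 on $[0,1]$
images — the original gives no criterion; this is the simplest reproducible
one, and it is configurable. A lung-window transform (width 1500 HU, level
−600 HU) is provided for real CT input and never applied to synthetic data.

## Known limitations

* Backpropagation (and therefore target training) is implemented for the
  sequential toy backbone; the resnet18-style network supports construction,
  forward passes, collapse, and kernel counting.
* The Gaussian-likelihood treatment of binary labels is faithful to the
  source but is not a calibrated probability model; scores can leave
  $[0, 1]$.
* The stage-4 hypergradient is first-order with a finite-difference mixed
  derivative; exact second-order differentiation through $T$ inner steps is
  deliberately out of scope.
* Bootstrap CIs are percentile intervals; a DeLong alternative is not
  provided.
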