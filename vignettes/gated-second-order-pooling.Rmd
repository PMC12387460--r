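---
title: "Gated second-order pooling for lung CT classification: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated second-order pooling for lung CT classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungsop)
```

## The problem and the model

`lungsop` implements a three-class (benign / malignant / normal) lung CT
slice classifier whose central statistical idea is to replace first-order
spatial pooling with **second-order (covariance) pooling**. Given a feature
map $X \in \mathbb{R}^{C \times H \times W}$, flattened to
$F \in \mathbb{R}^{d \times N}$ with $d = C$, $N = HW$, the pooled
descriptor is the matrix square root of the channel covariance

$$C = \frac{1}{N}\sum_{j=1}^{N}(f_j - \mu)(f_j - \mu)^\top
    = F \bar{I} F^\top,\qquad
  \bar{I} = \tfrac{1}{N}\left(I - \tfrac{1}{N}JJ^\top\right),$$

which captures pairwise channel correlations (second-order texture
statistics) that mean/max pooling discards. The square root
$C^{1/2} = U\,\mathrm{diag}(\lambda_i^{1/2})\,U^\top$ compresses the
eigenvalue spread; 0.5 is the standard and fixed exponent. Instead of an
eigendecomposition, the square root is computed by the coupled
**Newton-Schulz iteration**

$$Y_n = \tfrac{1}{2} Y_{n-1}(3I - M_{n-1}Y_{n-1}),\qquad
  M_n = \tfrac{1}{2}(3I - M_{n-1}Y_{n-1})M_{n-1},$$

with $Y_0 = \hat C = C/\mathrm{tr}(C)$, $M_0 = I$, run for five iterations.
Trace pre-normalization places the spectrum inside the iteration's
convergence region; the output is post-compensated as
$M = \sqrt{\mathrm{tr}(C)}\,Y_5$, because
$\hat C^{1/2} = C^{1/2}/\sqrt{\mathrm{tr}\,C}$ — only the *square root* of
the trace restores the original scale. $Y_n \to \hat C^{1/2}$ and
$M_n \to \hat C^{-1/2}$; both limits are used (see the Gram route below).

Around this core sit three further components:

* a **squeeze-and-excitation (SE) block**: channel descriptor
  $z_c = \frac{1}{HW}\sum_{i,j} X_c(i,j)$, excitation
  $s = \sigma(W_2\,\delta(W_1 z))$ with a reduction-$r$ bottleneck, and
  multiplicative recalibration $\tilde X_c = s_c X_c$;
* an **adaptive gate** ("dynamic feature enhancement"): a learned scalar
  $\alpha = \sigma(\mathrm{mean}(W_d s_c + b_d)) \in (0,1)$ per sample that
  selects (hard mode, threshold $\tau = 0.5$, strict inequality) or blends
  (soft mode) the second-order branch against the SE branch, with the
  balance penalty $R = (\alpha - \tfrac12)^2 \le \tfrac14$ added to the
  loss as $\lambda \bar R$;
* a **ResNet-50 bottleneck backbone** (7×7 stem, max pooling, bottleneck
  stages) assembled as: stem → gate #1 → stages → gate #2 → SE attention →
  second-order head fused with the excitation-weighted global descriptor →
  fully connected softmax classifier.

## Design choices where the design was genuinely open

**Backbone depth.** The architecture description names *three* hierarchical
stages (3, 4, 6 blocks) while also naming ResNet50 — which canonically has
four stages (3, 4, 6, 3) and whose published 25.6 M parameter count only
holds with all four. The default keeps the canonical four-stage backbone;
`model_config(three_stage = TRUE)` builds the literal three-stage variant.
The package's own CPU-scale tests use the three-stage form at 32 px input
because the four-stage net reduces a 32 px image to a 1×1 final map, whose
covariance is identically zero (a degenerate second-order head).

**Scalar gate.** The gating recipe produces a vector
$z \in \mathbb{R}^C$ yet compares a scalar against $\tau$. We reduce by the
arithmetic mean *before* the sigmoid, giving one gate per sample per
instance. A per-channel gate variant is deliberately not implemented.

**Gate application across shapes.** The flattened square root is a
length-$C^2$ vector while the gated feature map is $[C, H, W]$; the two
cannot be combined literally. At *intermediate* placements the second-order
branch contributes per-channel energies $\mathrm{diag}(S^{1/2})$ broadcast
as channel scales, $F = \alpha\,(\mathrm{diag}(S^{1/2}) \odot H) +
(1-\alpha) H$, which preserves shape and recovers the stated limits
($\alpha \to 0$: untouched map / SE map; $\alpha \to 1$: pure second-order
rescaling). At the *head*, the literal vector form is used: the flattened
$S^{1/2}$ (computed on a 1×1-convolution channel reduction to `sop_dim`
channels, batch-normalized and rectified) is convexly combined with a
learned linear lift of the excitation-weighted global descriptor
$e \odot s_c$ to the same length.

**Hard vs soft placement.** The branch-selection (hard) recipe is written
for "a feature map from a ResNet stage", so the two intermediate gates
default to hard mode; the head fusion uses the soft convex combination,
which is exactly the head-level formula, and keeps the second-order branch
differentiable at all times. Both modes are selectable per instance.

**Regularizer placement.** The literal pseudocode returns
$F_{\text{enhanced}} \cdot R$, which would *annihilate* the features
exactly when $\alpha = 0.5$ — the balanced regime the penalty's own comment
says it promotes. $R$ is therefore treated as an additive loss penalty
$\lambda \cdot \mathrm{mean}(R)$ (default $\lambda = 0.01$), never as an
output multiplier.

**Zero-initialized gates.** $W_d = 0, b_d = 0$ gives $\alpha = 0.5$
exactly: training starts from the deterministic balanced blend and the gate
learns to move away from it. This also yields the reference network used in
the bypass-consistency test.

## Numerical choices

* **Degenerate covariance** (zero trace, e.g. a constant feature map or a
  1×1 map): the pooled path returns the zero matrix with a typed warning
  rather than erroring mid-training; the gradient through that sample's
  second-order branch is zero.
* **Gram route.** When the number of spatial positions $N$ is smaller than
  the channel count $d$, the covariance has rank $\le N$ and the $d \times
  d$ iteration wastes $O(d^3)$ work. The network-internal layers then
  iterate on the trace-normalized $N \times N$ Gram matrix $\hat G =
  \hat B^\top \hat B$ (where $\hat B = F_c / \sqrt{N\,\mathrm{tr}\,C}$) and
  reconstruct $S^{1/2} = \sqrt{\mathrm{tr}\,C}\; \hat B \hat G^{-1/2}
  \hat B^\top$ using the $M$-iterate. The public `covpool` API always runs
  the direct $d \times d$ form. Both routes' hand-derived backward passes
  are validated against central finite differences to ~1e-9 relative error.
* **Five iterations resolve large eigenvalues only.** An eigenvalue holding
  trace share $t$ is approximated after five multiplication-only iterations
  by $\approx (3/2)^5\,t$ when $t$ is small, i.e. it converges linearly at
  rate 3/2 and needs roughly $\log_{1.5}(1/t)$ iterations. Since
  $\lVert\hat C^{1/2}\rVert_F = 1$, the relative error is approximately the
  square root of the total trace share of unresolved eigenvalues. Five
  iterations therefore agree with the eigendecomposition oracle to 1e-2
  only while every eigenvalue keeps at least ~5% of the trace (near-uniform
  spectra at $d \lesssim 8$, or strongly top-heavy spectra with negligible
  tails). For $d = 64$ with condition number $\le 10^3$ **no** admissible
  matrix meets 1e-2 (error floor ≈ 3e-2; typical samplers give 0.05–0.25,
  and $\hat C = I/64$ gives ≈ 0.23). The acceptance criterion that asserts
  1e-2 over that domain is implemented literally and is expected to fail;
  the monotone-refinement half holds. In training this inaccuracy is
  immaterial — the approximate square root is a fixed, differentiable
  feature transform, which is precisely how it is used.
* **Saturation guard.** $\alpha$ is clamped to
  $[10^{-12}, 1 - 10^{-12}]$ so that extreme pre-activations cannot emit
  exactly 0 or 1 past double precision.
* **Numerics of batch norm in evaluation.** Running statistics use momentum
  0.1, which lags the weights badly when an epoch has only a handful of
  batches (the first epochs would evaluate near chance). Before each
  validation pass the trainer therefore recalibrates the running statistics
  as the exact average of per-batch statistics over up to 256 training
  images ("precise BN"), so evaluation-mode inference always reflects the
  current weights; inference itself stays deterministic.
* **Ties and rounding.** The hard gate uses strict `alpha > tau`;
  stratified splitting uses largest-remainder apportionment with ties going
  to train, then validation; parameter counts in millions round half-up.

## Training protocol

Adam with initial learning rate $10^{-3}$, divided by ten every 20 epochs
over 50 epochs (so $10^{-3} \to 10^{-4} \to 10^{-5}$), batch size 32,
cross-entropy plus $\lambda \bar R$, weight decay $10^{-4}$ by default (the
published account states both $10^{-4}$ in prose and $10^{-3}$ in its
parameter table; the field is configurable), seeded shuffling, and
best-validation-accuracy checkpointing (early stopping is not used). The
logged total loss equals logged cross-entropy plus $\lambda$ times the
logged penalty at every epoch by construction, and two runs with the same
seed are bit-identical on CPU.

The generalization protocol splits *raw* images first (70/15/15 stratified),
augments only the training partition by default, and evaluates the trained
model on both the augmented and the raw test split with a paired two-tailed
t-test over matched per-class recalls. Balancing the full set *before*
splitting — which reproduces the published 1344/1344/1328 counts from
251/547/392 — is available but leaks near-duplicates across splits and is
kept only for comparability.

## What the synthetic phantoms do and do not establish

The generator emulates the published dataset's *structure*, not its
content: three visually separable classes (no nodule / smooth bright disc /
larger irregular star-convex blob with positive-mean internal texture) on
two bright elliptical "lung fields" over a dark background, with additive
Gaussian noise, seeded and bit-reproducible; class counts and image sizes
are configurable (251/547/392 and 512→224 px mirror the published corpus,
64 px mirrors the CPU-scale tests). Separability is by construction — mean
lung-field intensity orders normal < benign < malignant — so a green
learnability test establishes that *the implementation can fit a separable
three-class image problem end to end* (gradients flow through every branch,
the schedule and checkpointing work), not that the architecture reaches any
particular accuracy on real CT data. Radiological realism (Hounsfield
calibration, 3-D structure, scanner noise, inter-patient variability) is
explicitly out of scope, as is reproducing the published headline accuracy,
which would require the real dataset and GPU-scale training.

Augmentation parameter ranges are not specified in the published account;
the defaults (rotation ±15°, brightness ±20%, zoom 0.9–1.1, shifts ±10%,
flip, Gaussian σ = 0.01, salt-and-pepper density 0.002) are conventional
medical-imaging choices and are all configurable. Shearing and cropping are
implemented but disabled by default, since the applied-technique list names
six techniques without them.

## Evaluation

The report computes the confusion matrix (rows = truth), one-vs-rest
per-class precision/recall/F1 and one-vs-rest accuracy (the published
per-class "accuracy" is interpreted this way; the report emits recall
alongside to avoid ambiguity), threshold-swept ROC with trapezoid AUC
(verified against the Mann-Whitney rank statistic), and stratified
percentile-bootstrap confidence intervals (2000 resamples by default for
publication-grade intervals; the method is a package choice — the published
account never states one — selected because it is distribution-free and
matches asymmetric printed intervals). Zero denominators yield 0 with an
explicit flag. An "IoU-threshold" metric sweep reported alongside the
published classification results is undefined for whole-image
classification (no localization output exists) and is not implemented.

## Known limitations

* The five-iteration square root is an approximation with the spectrum
  -dependent error analysed above; raise `ns_iterations` if oracle-grade
  accuracy matters more than speed.
* The pure-R layer stack is CPU-bound: the full-width 224 px network is
  buildable and countable, but training at that scale is out of reach;
  `width_multiplier` exists precisely to keep the whole pipeline testable.
* The published 28.2 M parameter count for the full proposed model is not
  reproducible from the published description (SE ratios and gate/lift
  widths are unstated) and is deliberately not a target.
* Per-channel gating, Gumbel-style discrete gate training, spatial
  attention variants and compact bilinear approximations are non-goals.
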