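---
title: "Rotation-invariant vision transformers for tumor image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant vision transformers for tumor image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvit)
```

## The model

A vision transformer (ViT) classifies an image $X \in \mathbb{R}^{H \times W
\times C}$ by cutting it into $N = (H/P)^2$ non-overlapping $P \times P$
patches, flattening each patch $R_i$ into a row vector of length $P^2 C$,
projecting it with a shared embedding matrix $E \in \mathbb{R}^{(P^2 C) \times
D}$, prepending a learnable class token, adding position embeddings, and
running the token sequence through $L$ pre-norm encoder layers of multi-head
self-attention and a GELU MLP. The class prediction is a softmax over a linear
map of the final class-token state.

Plain ViTs are not rotation invariant: rotating the input permutes *and
rotates* the patches, the position embeddings no longer match their content,
and the logits change. The model family implemented here restores exact
invariance to quarter turns architecturally. For $k \in \{1, 2, 4\}$ rotations
the input is expanded into the set $X^{(j)}$, $j = 0, \dots, k - 1$, of copies
rotated by $j \cdot (4/k)$ quarter turns; each copy is patch-embedded with the
*same* projector,

$$Z_i^{(j)} = R_i^{(j)} E,$$

and the embeddings are averaged element-wise before the encoder:

$$Z_i = \frac{1}{k} \sum_{j=0}^{k-1} Z_i^{(j)}.$$

Because a quarter turn of $X$ merely permutes the set $\{X^{(j)}\}$ cyclically
(quarter-turn rotation is an exact pixel permutation, so no interpolation
noise enters), the average — and everything downstream, including the logits —
is unchanged up to floating-point summation order. The package's tests observe
deviations at the $10^{-15}$ level against a nominal tolerance of $10^{-4}$.
The invariance holds for *every* weight setting, trained or random, and it
costs no parameters: the projector is shared across the $k$ copies.

An optional stem applies a depth-wise $3 \times 3$ convolution (one kernel
per channel) followed by a pointwise $1 \times 1$ channel mix to each rotated
copy before patch extraction. The stem is linear and spatial-size preserving;
applying it inside the rotation loop keeps the invariance argument intact
(the set of stemmed rotated copies is still permuted as a set). Keeping it
linear means an identity-initialised stem is exactly the identity map, which
pins down its semantics and makes the ablation clean; its value is the local
spatial mixing across patch boundaries that the patch projector alone cannot
express.

## The architecture family

Four presets assemble the family; the two published hyperparameter tables are
reproduced exactly by `model_config()`:

| preset | D | L | heads | MLP | rotation averaging | depth-wise stem |
|---|---|---|---|---|---|---|
| `rvit` | 142 | 10 | 10 | 480 | yes (k = 4) | yes |
| `base_vit` | 768 | 12 | 12 | 1024 | no | no |
| `rvit_variant1` | 142 | 10 | 10 | 480 | no | yes |
| `rvit_variant2` | 142 | 10 | 10 | 480 | yes (k = 4) | no |

All presets use 224 px inputs, patch size 16, attention dropout 0.1, and a
two-class head (non-tumor, tumor). Table 1's 142-dimensional embedding with
10 heads does not divide evenly; we set the per-head dimension to
$\lfloor D/h \rfloor = 14$, an inner attention width of 140, and an output
projection mapping 140 back to 142. As a consequence (and because the source
tables do not locate or size the depth-wise convolution layers), absolute
parameter counts of the published models are not reproducible and are treated
as descriptive; the *relations* are contractual and tested: rotation averaging
adds no parameters (`rvit` and `rvit_variant1` always count equal, for any
configuration and any k), and removing the stem strictly reduces the count.

## Training recipe and numerical choices

* **Optimiser.** Adam, learning rate $10^{-3}$, weight decay $10^{-2}$, batch
  size 32, 25 epochs by default; cross-entropy on the softmax output (the
  natural loss for a two-class softmax head). Weight decay is implemented
  *decoupled* (AdamW-style) and applied only to weight matrices — not biases,
  layer-norm parameters, the class token or position table — the mainstream
  reading of "Adam with weight decay" in modern vision-transformer code.
* **Initialisation.** All affine maps use fan-in scaled uniform weights
  ($U(\pm 1/\sqrt{\text{fan-in}})$, the default affine initialisation in
  mainstream deep-learning frameworks), zero biases; class token and position
  table are normal with sd 0.02; layer-norm scales start at 1. With much
  smaller weight scales the class-token logit is almost independent of the
  image and nothing useful happens within a short training budget.
* **Input normalisation.** Inputs arrive in $[0, 1]$ and are centred to
  $[-1, 1]$ inside the model (mean 0.5 / std 0.5, the usual image-pipeline
  transform). Uncentred patches share a large constant component that makes
  all tokens nearly collinear — especially after rotation averaging — and
  slows early training badly. Centring is pointwise, so it commutes with
  rotation and does not disturb the invariance.
* **Block order.** Pre-norm residual blocks (layer norm, attention, residual;
  layer norm, MLP, residual) with a final layer norm before the head; the
  pre-norm order is the one that trains stably at small scale in the ViT
  lineage. Layer-norm uses population variance with $\varepsilon = 10^{-6}$
  inside the square root. GELU uses the exact $x\,\Phi(x)$ form.
* **Dropout.** Only on attention weights (rate from the configuration),
  active only in training mode; evaluation is deterministic.
* **Splits and reproducibility.** `split_train_val()` stratifies by class
  (80/20 by default) and is a pure function of its seed; training randomness
  (shuffling, dropout) derives from the training seed, so runs are
  reproducible on one machine. The epoch history records train/validation
  loss and accuracy; the best-validation parameters are retained (ties keep
  the earlier epoch) alongside the final-epoch model.
* **Metrics.** Sensitivity, specificity, per-class precision and F1, MCC and
  accuracy from integer confusion-matrix counts; zero-denominator metrics are
  reported as `NA`, never silently 0. Printed values use half-up rounding at
  three decimals, the convention of published results tables.
  `confusion_from_rates()` reconstructs integer counts from a test
  composition and reported sensitivity/specificity, which is exact whenever
  the rates came from integer counts.

## The phantom generator

`phantom_spec()` / `generate_dataset()` produce MRI-like phantoms so that the
whole pipeline is testable without downloads: a soft-edged bright disk (the
"brain") on a dark background, low-frequency cosine texture, two to four
bright circular "anatomical" bumps in **every** image, Gaussian pixel noise,
and — in positives only — one elongated bright elliptical lesion (compact
support, so a positive differs from its seed-matched negative only inside the
lesion ellipse). Ground-truth lesion masks and a parameter manifest are
retained. The generator is a pure function of (spec, seed).

The defaults (64 px, 500 images, lesion semi-major 11–15 px at aspect 2.5,
intensity lift 0.6, one to three distractor bumps at 0.42 of the lesion lift,
texture 0.03, noise 0.02) were fixed once after pilot runs so that a scaled-down
rotation-averaged model (64 px, patch 8, D = 64, L = 4, h = 4, k = 4) learns
the task within 10 epochs under the published optimiser recipe. The circular
distractors are what make the task more than a brightness threshold: local
brightness alone no longer separates the classes, so classifiers must also
use the lesion's elongated *shape* — and a shape detector trained on
orientation-biased lesions (`orientation_range = c(-10, 10)`) degrades on
quarter-rotated inputs unless the architecture is invariant. That is the
orientation-shift scenario the rotation benchmark measures:
`rotation_benchmark()` evaluates a model on the dataset rotated by 0/90/180/
270 degrees and reports the four accuracies, their range, and per-image
predictions (for an invariant model the predictions — not just the
accuracies — are identical across angles).

What the phantoms deliberately do **not** emulate: anatomical structure,
scanner physics, intensity inhomogeneity, 3-D geometry, or the class overlap
of real MRI. Passing the desk-scale suite therefore demonstrates the
*architectural* claims (exact invariance, parameter relations, trainability,
orientation-shift sensitivity of non-invariant ablations), not clinical
performance; published full-dataset accuracy figures are outside what a
synthetic desk-scale run can or should reproduce.

## Grad-CAM over the token grid

`gradcam()` adapts Grad-CAM to the transformer by treating the embedding
dimensions as channels and the patch-token grid as spatial locations.
Activations and gradients are taken at the **input** of the last encoder
layer: only the class token feeds the head, so the gradient of the logit with
respect to the last layer's *output* patch tokens is identically zero, while
at the layer's input the class token still attends to every patch token.
Each patch token is scored by the rectified inner product of its gradient and
its activation — its first-order (Taylor) contribution to the target logit.
(The CNN convention of average-pooling the gradient over spatial positions
into per-channel weights transfers poorly to transformer tokens, whose large
shared residual-stream component dominates such a projection and washes out
localisation; the per-token score keeps the spatial information the token
grid actually carries.) Scores are reshaped to the $(H/P) \times (W/P)$ grid,
normalised to $[0, 1]$, and bilinearly upsampled. Attribution flows through
the unrotated ($j = 0$) branch by default; for a rotation-averaged model the
*logit being explained* is identical across the four rotations of the input,
but the unrotated-branch map need not be, so an `"averaged"` option computes
each branch's map in its own frame, rotates it back, and averages.

## Problem sizes used by the tests and the acceptance script

Unit tests run on 16–64 px configurations built in code. The two heavier
suites, chosen as the package's desk-scale study conditions, are: (i) exact
invariance at the published 224 px model sizes with randomly initialised
weights, and (ii) the 500-phantom, 10-epoch training study at 64 px (batch 32)
with its rotation benchmark and Grad-CAM localisation check. The acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from scratch
under a caller-supplied seed.

## Known limitations

* Quarter turns only: arbitrary-angle rotation requires interpolation, which
  breaks exactness and is out of scope by design.
* The published absolute parameter counts and full-dataset accuracy table are
  not reproducible from the information available (head-dimension conflict,
  unlocated convolution layers, external training data); relations and
  properties are tested instead.
* One published prose line mentions per-rotation "unique rotation
  embeddings"; no equation defines them, and equal parameter counts between
  the rotation-averaged model and its no-rotation ablation contradict extra
  per-rotation parameters, so the equations (shared projector, plain average)
  are what is implemented.
* The pure-R engine favours clarity and exactness over speed; it is adequate
  for the desk-scale studies (minutes, one CPU) but not for full-dataset
  training.
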