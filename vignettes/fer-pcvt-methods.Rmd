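---
title: "FER-PCVT methods: model, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FER-PCVT methods: model, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferpcvt)
```

## The problem

During early stroke rehabilitation, physicians gauge whether training
intensity suits a patient largely by watching the patient's face. FER-PCVT
automates this reading: it classifies face images into eight emotions — four
*basic* ones that index concentration and motivation (happy, sad, surprised,
angry) and four *special* ones that index training intensity (painful,
strained, tired, neutral). Because the model is meant to run inside
rehabilitation equipment, it is deliberately small: the backbone holds
2.46 M parameters and needs 0.12 GFLOPs per forward pass; the full
classifier is 4.10 M parameters.

`ferpcvt` implements the complete pipeline natively in R: geometric face
alignment, FACS-based labeling, the network with its training loop, the
evaluation metrics, a profiler, and a synthetic face generator that stands
in for clinical data (which cannot be shipped).

## Face alignment

Given detector eye landmarks $(x_l, y_l)$, $(x_r, y_r)$ with a confidence
score, images below a confidence threshold (default 0.5; the filtering rule
is fixed but the threshold is this package's choice) are dropped. The
remainder are rotated so the inter-ocular line is horizontal, about the
line's midpoint $(x_c, y_c)$:

$$\theta = \arctan\frac{y_r - y_l}{x_r - x_l}, \qquad
A = \begin{bmatrix}\cos\theta & \sin\theta\\ -\sin\theta &
\cos\theta\end{bmatrix}, \qquad
B = \begin{bmatrix}(1-\cos\theta)x_c - \sin\theta\, y_c\\
\sin\theta\, x_c + (1-\cos\theta) y_c\end{bmatrix},$$

with pixels mapped by $[x', y']^T = A[x, y]^T + B = M [x, y, 1]^T$.
Coordinates are 0-based, $x$ rightward, $y$ downward, so the sign of
$\theta$ follows the image convention; the invariants that matter —
levelling ($|y'_l - y'_r| < 10^{-6}$), rigidity (inter-ocular distance
preserved), and invertibility (composing $\theta$ and $-\theta$ is the
identity) — are tested directly. Warping uses bilinear interpolation with
border replication (smooth, no black wedges; the choice is ours), and the
full rotated frame is resized to $128 \times 128$ — nothing in the method
description crops to a face box, so we do not.

## FACS labeling

Emotions are defined as conjunctions of action-unit clauses, `+` joining
clauses and `/` marking within-clause alternatives:

| emotion   | rule                                  |
|-----------|---------------------------------------|
| painful   | AU4 + (AU6/AU7) + (AU9/AU10) + AU43   |
| strained  | AU4 + AU6 + (AU23/AU24/AU28)          |
| tired     | AU43 + AU54                           |
| neutral   | no action units                       |
| happy     | AU6 + AU12                            |
| sad       | AU1 + AU4 + AU15                      |
| surprised | AU1 + AU2 + AU5 + AU26                |
| angry     | AU4 + AU5 + AU7 + AU23                |

Two decisions are ours because the rule table alone does not determine them.
First, **priority**: an AU set can satisfy several rules; we resolve to the
clinically most alarming label (painful > strained > tired > surprised >
angry > sad > happy > neutral), because missing pain has the highest cost in
this application. Second, **unmatched non-empty sets** map to neutral with a
warning rather than erroring — annotator AU sets are noisy, and a hard error
in the middle of a labeling run helps no one. We also take the painful rule
literally (AU43 required); pain-scoring conventions elsewhere treat eye
closure as optional, but the rule table here does not.

`dataset_stats()` reports class counts, proportions and the min/max sample
ratio that summarizes imbalance (0.0281 for FER+, 0.0596 for RAF-DB, 0.0864
for the clinical collection — reproduced in the tests from the printed
counts).

## Architecture

The network is a hybrid of convolution (local features, built-in position
information) and a vision transformer (global features), arranged as a
pyramid so that token count shrinks and channel width grows with depth.

**Convolutional Patch Embedding (CPE).** The published description fixes
the interfaces (3 × 128 × 128 in, 64 × 16 × 16 out, patch size 8) but not
every stem detail; our stem is a 3×3/stride-2 convolution to 64 channels,
GeLU, 3×3/stride-2 max pooling (padding 1), then `r = 1` Block Scaling
repeat — a 2×2/stride-2 convolution followed by a 1×1 convolution — so the
side shrinks by $4 \cdot 2^r = 8$, the patch size. Convolution carries the
position information; there is no positional-embedding table anywhere.

**Pyramid Transformer (PTF).** Each stage runs `l` encoder blocks and one
Block Combined Pooling. An encoder block computes Q, K, V by *convolutional*
projection, runs multi-head self-attention over the `h·w` token grid, and
applies a bottleneck feed-forward (1×1 convolutions to `d/2` and back, GeLU
between, the exact-erf form $\tfrac{x}{2}(1+\mathrm{erf}(x/\sqrt2))$);
residual connections join each sub-module's input and output, and layer
normalization (over channels at each position, post-norm) follows each
residual. Block Combined Pooling is a 3×3 convolution to the stage width
`d0`, 3×3/stride-2 max pooling, and batch normalization, taking
$d_i \times h \times w$ to $d_0 \times h/2 \times w/2$. The reference model
has two stages (`l=2, d0=192, heads=8`; `l=4, d0=576, heads=4`), giving
64×16×16 → 192×8×8 → 576×4×4.

**The Q/K/V projection is depthwise.** The description says "convolutional
mapping instead of the linear mapping" without fixing the kernel's channel
structure. A dense 3×3 projection yields a ~5.5 M-parameter backbone and a
dense 1×1 projection ~1.8 M — neither is compatible with the published
2.46 M at 0.12 GFLOPs. A channel-preserving *depthwise* 3×3 convolution per
role (the lightest convolutional mapping, spatial mixing only) is the one
reading that reproduces both printed budget figures once the head is sized
(below), so the package adopts it. No output projection follows the head
concatenation, and there is no dropout — neither appears in the method
description.

**Valence-Arousal-Like Classifier (V-ALC).** The final 576×4×4 map is
pixel-shuffled 12-fold per side (a pure permutation) to 4×48×48, condensed
by a 12×12/stride-12 convolution back to the 4×4 token grid with
`condense_channels` channels, and reduced to two one-dimensional features:

$$\text{ChannelMean}(x_b) = \frac1c \sum_{i=1}^{c} x_{bi}, \qquad
\text{BatchSharing}(x) = \frac1{bc} \sum_{j=1}^{b}\sum_{i=1}^{c} x_{ij},$$

the per-sample V-A-like feature and the batch-shared neutral feature. The
classifier output is the sigmoid of a linear map of
$\text{combined} = \text{V-A-like} + w_{AD}\cdot\text{neutral}$, where
$w_{AD}$ is a learnable scalar (initialized to 1; no initialization is
published). Sigmoid rather than softmax is used for the reported
confidences because emotions may be composite states; training nevertheless
minimizes standard multi-class cross-entropy on the raw scores, which names
the published loss and leaves the argmax unchanged (sigmoid and softmax are
both monotone in the logits).

**Neutral feature at inference.** Batch Sharing is batch-dependent, which
would make single-image prediction depend on its companions. The package
keeps an exponential running average of the batch-shared neutral feature
(momentum 0.1, updated every training step, stored in checkpoints) and uses
it in eval mode. This makes prediction well-defined for a single image and
exactly batch-size independent — a property the tests check — at the cost
of a train/eval asymmetry identical in kind to batch normalization's.

## Sizing the heads: the parameter-budget derivation

The structural core fixed by the method description counts

| piece | parameters |
|-------|-----------:|
| CPE (conv 3→64, Block Scaling pair) | 22,400 |
| stage 1: 2 blocks at 64 channels | 12,736 |
| stage 1 pooling 64→192 + BN | 111,168 |
| stage 2: 4 blocks at 192 channels | 174,720 |
| stage 2 pooling 192→576 + BN | 997,056 |
| **core total** | **1,318,080** |

Two published totals then pin down the free widths:

* **Backbone, 2.46 M.** The backbone-only model (evaluated on the 7-class
  public task) needs a small classification head. With
  flatten(9216) → hidden → GeLU → 7, the hidden width 124 gives
  1,143,783 head parameters and a total of **2,461,863 → 2.46 M**. The same
  model profiles at 119.2 M MACs → **0.12 GFLOPs** (convention below).
* **Full model, 4.10 M.** The V-ALC structure (shuffle → 12×12/12 condense
  → channel mean → 16-feature linear) has one free width,
  `condense_channels`. The value 4820 gives 2,781,140 condense parameters
  and, with $w_{AD}$ and the 16→8 linear, a total of
  **4,099,357 → 4.10 M** for the 8-class clinical configuration.

Both counts are verified two ways in the tests: the analytic profiler
against a direct count of every trainable array in the built model.

**FLOP convention.** `profile_model()` counts multiply–accumulates (1 MAC =
1 FLOP) of convolution and linear layers — the quantity module-walking
profilers report, and the published figure is tool-reported. The attention
matrix products $QK^T$ and $AV$, which such profilers do not see, are
excluded by default and available via `include_attention = TRUE` (adding
23.1 M MACs, 0.14 GFLOPs total, for the reference backbone). Activations,
normalizations, poolings and bias additions are not counted.

## Training and evaluation

The published recipe is the default `train_config()`: AdamW, cross-entropy,
batch size 120, 200 epochs, learning rate $3\times10^{-4}$ with exponential
per-epoch decay 0.99 (so the rate after $k$ epochs is
$3\times10^{-4}\cdot 0.99^k$). Choices the recipe leaves open, fixed here:
decoupled weight decay 0.01 (the AdamW default), a stratified 80/20
train/validation split, pixel scaling to $[0,1]$ then per-channel
standardization with mean and SD 0.5, bilinear upscaling of smaller inputs,
and no data augmentation (none is described; a horizontal-flip flag exists
but defaults off). Training is seeded end to end — initialization and data
order — and bit-reproducible on CPU.

Evaluation derives, per class from the one-vs-rest confusion counts,
Precision $\frac{TP}{TP+FP}$, Specificity $\frac{TN}{TN+FP}$, Sensitivity
$\frac{TP}{TP+FN}$, F1 (harmonic mean of precision and recall) and G-mean
$\sqrt{\text{Recall}\cdot\text{Specificity}}$, with zero-denominator cells
reported as 0 (matching how absent classes are printed in the source
tables). Because it is unstated whether published confusion matrices are
counts or row percentages, reports carry both forms.

## Attention rollout

For visualization, head-averaged attention matrices are identity-added
($\hat A = \tfrac12(A + I)$, rows renormalized) and multiplied in depth
order. Between stages the token grid halves; the product is chained through
a row-stochastic operator built from the 3×3/stride-2 pooling geometry
(each coarse token averages its window's fine tokens). The column means of
the rolled matrix — the attention each input token *receives* — are
reshaped to the token grid, bilinearly upsampled to the input resolution
and min-max normalized to $[0,1]$. A 4-token hand computation and the
uniform-attention case pin the construction down in the tests.

## The synthetic face generator

The clinical dataset cannot be distributed, so `generate_dataset()` renders
schematic faces whose geometry is driven by the same action units the
labeling rules use: brow raise/lower (AU1/2/4, band position and tilt plus
a glabella shadow), eye openness (AU5/7/43, ellipse height; closure shades
the socket), cheek raise (AU6, crescents), nose wrinkle (AU9), upper-lip
raise (AU10), mouth curvature and corner action (AU12/15, including corner
dimples and droop blobs), lip thinning (AU23/24/28), jaw drop (AU26) and
head pitch (AU54). Labels are turned into AU intensities by boosting the
label's required AUs into $[0.6, 1]$ ("/" alternatives chosen uniformly)
over a residual floor of $[0, 0.15]$.

Nuisance factors emulate the structure of a clinical collection: a subject
pool with per-subject face aspect, skin tone and feature offsets (subjects
recur across classes, as patients contribute several emotions), head roll
drawn from ±0.17 rad (recorded true eye landmarks exercise the alignment
module), a linear illumination gradient, Gaussian pixel noise (SD 0.02) and
a mid-gray backdrop. A `table1-private` preset reproduces the published
class imbalance (509 neutral down to 44 angry; min/max ratio 0.0864).

The generator is designed so the classes are genuinely separable — a
pixel-space nearest-centroid classifier reaches >80% leave-one-out accuracy
at 20 images per class under the default nuisances — which is what makes
the training smoke test meaningful. During development this invariant drove
the rendering toward area-based AU cues (shaded sockets, crescents, blobs)
rather than thin strokes, which small rotations destroy in pixel distance.

What the generator does **not** emulate: photorealistic appearance and
texture, the facial asymmetry of hemiplegic patients, occlusions, pose
changes beyond roll, and video dynamics. Tests passing on synthetic data
therefore demonstrate that the pipeline's geometry, labeling, optimization
and bookkeeping are correct and that the architecture can fit a learnable
8-class signal — not that clinical accuracy figures transfer.

## Numerical choices and degenerate inputs

Convolution/pooling output sizes follow the floor convention
$\lfloor (n + 2p - k)/s \rfloor + 1$; all 3×3/stride-2 poolings use padding
1 so sides halve exactly (16 → 8 → 4). Weights draw from He-normal
initialization under the model seed; norm scales start at 1, offsets at 0.
Layer/batch normalization use $\varepsilon = 10^{-5}$; attention softmax
subtracts the row maximum. Degenerate inputs fail loudly and specifically:
coincident or vertical eye landmarks, non-finite images, channel/head
indivisibility, empty manifests, eval-mode prediction before any training
step (no neutral baseline yet), and unknown AU codes or config keys each
carry their own message. Unreadable images in a manifest skip the row with
a warning instead of aborting a long alignment run.

## Problem sizes in the test suite

The shipped `tiny.yaml` (64-pixel input, one stage with `l=1, d0=32`,
shuffle factor 4, ~21 k parameters, lr $10^{-3}$, batch 20) is the
configuration used for CPU-scale training demonstrations: on 160 synthetic
images (20 per class, rendered at 64 px, seed 11) it reaches ≥95% training
accuracy within 60 epochs with monotone loss decrease over the first five
epochs across seeds. Unit and property tests run on still smaller tensors;
the full reference architecture is exercised for construction, shape
contracts, profiling and single forward passes.

## Known limitations

* The backbone/head width reconstruction (hidden 124, condense 4820) is
  the unique solution under our structural reading, but other unpublished
  internals could redistribute the same totals.
* The depthwise Q/K/V reading is inferred from the parameter/FLOP budget,
  not stated explicitly in the method description.
* Sigmoid confidences are not calibrated probabilities; they are monotone
  scores.
* The running neutral baseline assumes training batches are reasonably
  class-mixed; heavily skewed batches bias the stored baseline — the same
  sensitivity to imbalance the method's authors observe.
* Pure-R execution is CPU-bound: the reference model trains at toy scale
  only; the package targets correctness, profiling and small-scale
  experimentation, not GPU-scale reproduction of dataset accuracies.
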