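---
title: "Quantitative HER2 scoring from IHC tiles: model, fusion algebra and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative HER2 scoring from IHC tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2quant)
```

## The problem

HER2 status guides targeted therapy in gastric cancer. On an
immunohistochemistry (IHC) slide, pathologists grade HER2 expression
0, 1+, 2+ or 3+ from the intensity and completeness of brown (DAB)
membrane staining in tumor cells, with the clinical groups negative
(0/1+), equivocal (2+, resolved by FISH) and positive (3+). The grade
depends on whether the relevant staining pattern appears in more than
10% of tumor cells. Manual scoring of gigapixel whole-slide images
(WSIs) is slow and subjective; `her2quant` implements an automatic
two-stage pipeline that outputs both a slide-level score and the
quantitative evidence behind it.

## Pipeline

1. **Tiling.** A slide is cropped by a non-overlapping 256 x 256
   sliding window (`tileSlide()`); partial edge windows are dropped.
   No tissue mask is used: blank or artifact regions are expected to be
   absorbed by the classifier's `noise` class, which exists for that
   purpose.
2. **Tile classification.** Each tile is classified into six classes —
   `0`, `1+`, `2+`, `3+`, `normal`, `noise` — by a convolutional
   network (`trainTLCN()`, `predictTiles()`).
3. **Aggregation.** The proportions of `0/1+/2+/3+` among tiles
   predicted as one of those four classes form a 4-dimensional
   category vector (`aggregateTiles()`); `normal` and `noise` tiles are
   excluded from numerator and denominator. A slide with no tumor-class
   tiles is flagged unscorable rather than scored.
4. **Slide scoring.** A small model maps the category vector to the
   slide-level score (`trainWHSPN()`, `predictWHSPN()`): either a
   polynomial-kernel SVM (gamma 10, cost 2, degree 3) or a four-layer
   MLP (4-32-16-8-4, ReLU after the hidden layers). Learning the
   mapping avoids hand-set proportion thresholds. The three-class
   clinical group is always *derived* from the four-class score via
   `mergeClasses()`, never predicted separately.

## The tile classifier

The classifier is a plain chain of 3x3 convolutions in five stages
(depths 1/2/4/14/1, widths 48/48/96/192/1280 by default; 22 layers),
stride 2 on the first layer of each stage, global average pooling and
one linear head. A 256 x 256 input reaches an 8 x 8 feature map before
pooling. Inputs in [0, 1] are mapped to [-1, 1] by a fixed affine
transform before the first convolution; since the transform is
identical in training and deployment it does not interact with the
fusion algebra below.

**Multi-branch training blocks.** In training mode every layer is an
enhanced convolution block: a bias-free 3x3 convolution + batch norm,
a parallel bias-free 1x1 convolution + batch norm, and — when stride
is 1 and the channel count is preserved — an identity branch with its
own batch norm. The branch outputs are summed, passed through optional
channel attention, then ReLU. The multi-branch structure improves
trainability; the deployment network removes it exactly.

**Structural re-parameterization.** For one branch with kernel $K$,
bias $b$, and batch-norm statistics $\mu, \sigma$ and affine
$\gamma, \beta$ (per output channel, $\sigma = \sqrt{v + \varepsilon}$
with running variance $v$ and $\varepsilon = 10^{-5}$):

$$K' = K\frac{\gamma}{\sigma}, \qquad
  b' = (b - \mu)\frac{\gamma}{\sigma} + \beta,$$

so convolution-then-BN equals a single biased convolution
(`fuseConvBN()`). The 1x1 kernel embeds at the center of a zero 3x3
kernel (`pad1x1To3x3()`), the identity branch is a Dirac kernel fused
with its own BN (`identityTo3x3()`), and the three branches merge by
elementwise addition because convolution is linear in its kernel
(`mergeBranches()`). `reparameterizeModel()` applies this per block and
yields a deploy network of plain biased 3x3 convolutions whose logits
agree with the training network (in inference mode) to floating-point
accumulation error; the test suite asserts a max-abs deviation below
1e-9 in double precision. Fusion uses the *running* statistics, i.e.
inference semantics. Attention sits outside the branch sum and passes
through fusion untouched.

**Channel attention.** Two options follow each block, applied to the
branch sum before ReLU (their placement relative to ReLU is a design
choice; before ReLU keeps the fused branch algebra self-contained):

- *Gated channel transformation (GCT)*: per sample, an l2 channel
  embedding $s_c = \alpha_c\sqrt{\sum_{h,w} x_{chw}^2 + \varepsilon}$,
  channel normalization
  $\hat s_c = s_c\sqrt{C}/\sqrt{\sum_c s_c^2 + \varepsilon}$, and gate
  $1 + \tanh(\gamma_c \hat s_c + \beta_c)$. With the initialization
  $\alpha = 1, \gamma = \beta = 0$ the module is an exact identity,
  which the tests assert bit-for-bit.
- *Squeeze-and-excitation (SE)*: global average pooling, a bottleneck
  with reduction 16 (both transforms biased), and a sigmoid gate, so
  gates lie strictly in (0, 1).

**Parameter accounting.** `countParams()` enumerates learnable arrays:
kernels; conv biases (deploy mode only); BN scale and shift (training
mode; running statistics are not learnable); attention parameters
(3 per channel for GCT; $2C^2/r + C/r + C$ per SE block); head weights
and bias. Under the default architecture the counts are, in millions:
baseline chain 7.031574, baseline+GCT 7.045062, multi-branch training
net 7.835654 (with GCT 7.849142), fused deployment net 7.036070 (with
GCT 7.049558), deployment+SE 7.315631. These exact integers are pinned
in the tests against an independent closed-form sum, and
`scripts/acceptance.R` recomputes them from freshly built models.

**Training.** SGD with momentum 0.9, initial learning rate 0.1,
weight decay 0.001 on convolution and linear weights, batch size 256,
200 epochs, softmax cross-entropy, cosine learning-rate decay to zero;
the returned checkpoint is the epoch with the best validation
accuracy. Batch norm uses biased batch moments for normalization and
exponential running statistics (momentum 0.1) for inference. Momentum
and the cosine schedule are the de-facto companions of this optimizer
family; whether best-epoch or final-epoch selection is used upstream is
not documented, so best-validation was chosen and is recorded in the
training log. All randomness funnels through one integer seed.

The network engine (im2col + GEMM convolutions with analytic
backward passes, fused batch-norm/attention kernels) is implemented in
the package via Rcpp/RcppArmadillo in double precision; analytic
gradients are validated against central finite differences for every
layer family in the test suite.

## The synthetic data generator

No public HER2 gastric IHC dataset exists, so `generateTile()`,
`generateDataset()` and `generateSlide()` synthesize the study
conditions:

- tiles render cells (hematoxylin-like nuclei, cytoplasm washes) on an
  eosin-pink field; tumor cells carry a membrane ring whose DAB-brown
  intensity and arc completeness rise with the class — intensity ~0
  for `0`, 0.10-0.25 for `1+`, 0.35-0.55 for `2+`, 0.70-0.95 for `3+`
  (disjoint ranges), completeness rising from partial to complete;
- unstained tumor membrane is neutral gray, so only DAB staining has
  the brown hue ordering R > G > B that `dabProxy()` measures;
- `normal` tiles show smaller, sparser cells without membrane rings;
  `noise` tiles are blank fields, defocused washes or fold-like dark
  streaks;
- slides are grids of tiles with a chosen class mixture; the stored
  ground truth applies the >10%-of-tumor-tiles rule: the score is the
  highest of 3+, 2+, 1+ whose proportion among tumor tiles exceeds
  0.10, else 0 (`her2RuleScore()`), with tiles standing in for the
  guideline's cells. Slide-scorer training data are rule-labeled
  proportion vectors drawn from a flat Dirichlet, stratified over the
  four scores (`generateCategoryVectors()`).

What passing tests on these data do and do not show: they demonstrate
that the architecture trains, that fusion is exact, that the
aggregation and scoring rules are implemented correctly, and that the
two-stage design recovers a threshold rule it was never told — but the
tiles are far easier than real histology (no stain variation between
labs, no magnification ambiguity, no partially-stained heterogeneous
regions), so accuracy numbers on synthetic data say nothing about
clinical performance.

## Scaled problem sizes

The packaged experiments run at desk scale, chosen once as the sizes a
single-CPU analysis of the synthetic task needs: the study
configuration trains on 600 tiles (100 per class, split 8:1:1 at tile
level) with stage widths 8/8/16/32/64 and depths 2/2/2/2/1 — the
extra high-resolution layers are what a 256-px tile with thin, faintly
stained membrane arcs requires — batch 32, 15 epochs, seed 7, and must
reach at least 0.90 validation accuracy;
the slide scorer trains on 220 rule-labeled vectors and must reach at
least 0.90 accuracy on 100 fresh vectors with both schemes. The
command-line chain check uses a miniature 2-epoch configuration, since
it verifies pipeline wiring and exit codes rather than accuracy.
Monte-Carlo cross-validation (`mcCrossValidate()`) redraws an 8:1:1
split per round (tile-level, as the upstream patches were pooled
before splitting; source-slide ids are retained so stricter slide-level
splits remain possible) and reports mean and population standard
deviation per metric; its unit tests run two tiny rounds.

## Numerical choices and edge cases

- Batch-norm epsilon 1e-5 inside the fused standard deviation; fusion
  refuses non-positive variances.
- Fusion equivalence tolerance: 1e-9 on double-precision logits
  (accumulation-order differences are the only source of deviation).
- Argmax ties in `predictTiles()` and `predictWHSPN()` resolve to the
  lowest class index in the fixed order 0, 1+, 2+, 3+, normal, noise.
- Zero-denominator metrics (e.g. precision with no positive calls)
  return 0 with a warning rather than NaN, so repeated-split summaries
  stay finite.
- `aggregateTiles()` with no tumor-class tiles raises a typed no-tumor
  condition; `scoreSlide()` converts it into an unscorable record.
- Images are 8-bit-quantized at generation so PNG round-trips are
  bit-exact; slide mixtures are apportioned to tile counts by largest
  remainder.
- The SVM polynomial degree (3) and coef0 (0) follow the standard
  parameterization of the poly kernel; they are not documented
  upstream.

## Known limitations

- The engine is CPU-only and double-precision; it is sized for the
  desk-scale experiments above, not for training on clinical archives.
- Proportions are computed over all tiles of the slide (with
  normal/noise excluded by classification) rather than within a
  pathologist-outlined tumor region; on slides dominated by artifacts
  the category vector rests on few tiles, and `nTumorTiles` should be
  inspected.
- FISH resolution of equivocal 2+ cases is a clinical step outside the
  software.
- Pyramidal/proprietary WSI formats are not read directly; slides are
  accepted as plain raster images (PNG/TIFF) or pre-tiled directories
  with a manifest.
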