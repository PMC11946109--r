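---
title: "Class-aware Wise-IoU training of anchor-free fish detectors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-aware Wise-IoU training of anchor-free fish detectors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishdet)
```

## Scope and problem setting

`fishdet` studies how a single-stage anchor-free detector should be
trained when the species distribution is heavily long-tailed and the
imagery is low-contrast — the regime of automated reef-fish video surveys,
where a handful of common species dominate the annotations and most
species have tens of instances. The package implements the full
computational chain at desk scale: loss functions, detector architecture
with exact parameter accounting, target assignment and SGD training,
COCO-style evaluation, and a synthetic scene generator that stands in for
real survey data. Everything runs on one CPU; the aim is controlled
experimentation on the *training objective*, not competitive large-scale
accuracy.

## The detection model

The detector follows the standard CSP anchor-free layout. A convolutional
stem and four backbone stages (each a stride-2 convolution followed by a
C2f block with $n$ serial bottlenecks feeding a concatenation) produce
feature maps at strides 8, 16 and 32; an SPPF block terminates the
backbone; a PAN-FPN neck runs a top-down and a bottom-up fusion pass; and
a decoupled head predicts, per grid location, $C$ class logits and four
side-offset distributions over $r+1$ bins ($r$ = `reg_max` = 16). A box is
decoded from the softmax expectation of each side distribution, in stride
units from the location's cell centre.

The study configuration deepens the backbone from the large baseline's
3-6-6-3 bottleneck counts to 6-12-12-6 and replaces (i) the final backbone
stage and (ii) all four neck fusion blocks with transformer stacks. Each
transformer block flattens the $h\times w\times d$ feature map into $hw$
tokens, adds a learnable linear positional embedding (a $d$-vector scaled
by the normalized token index plus a bias — the "1-D positional embedding
through a linear layer" reading), and applies pre-norm multi-head
self-attention and a SiLU feed-forward sublayer, both with residual sums.

### Width calibration

The published table of model budgets pins the baselines near 11.2 M
(small), 25.9 M (medium) and 43.7 M (large) parameters at 121 classes, and
the proposed configuration at 30.56 M with its transformer-free ablation
at 26.87 M. Stage depths 6-12-12-6 with medium widths (0.75, cap 768)
would give 36.8 M — far above the printed budget — so the proposed model's
channel widths must be narrower than medium. We therefore calibrated the
committed presets once against the printed budgets:
`width_multiple = 0.703125`, `max_channels = 512`, neck C2f depth 2,
6 transformer blocks in the final backbone stage and 2 per neck fusion,
4 heads, feed-forward ratio 1.85. This lands `tf-depth-only` at 26.90 M
(+0.10 %) and `tf-full` at 30.64 M (+0.28 %), with the three baselines
within 0.3 % of their printed budgets. The calibration constants are part
of the preset definitions and are not free parameters of any experiment.

```{r params}
sapply(c("v8s", "v8m", "v8l", "tf-depth-only", "tf-full"),
       function(p) round(count_parameters(p, num_classes = 121) / 1e6, 2))
```

## The training objective

The total loss is $L = \alpha_1 L_{cls} + \alpha_2 L_{DF} +
\alpha_3 L_{box}$ with gains $\alpha_1 = 0.5$, $\alpha_2 = 1.5$,
$\alpha_3 = 7.5$ (the conventional classification / distribution-focal /
box split). $\alpha_3$ multiplies the box term in **all** configurations,
including Wise-IoU: the alternative reading (no gain on the Wise-IoU term)
would make the box objective twenty times weaker than its CIoU baseline
and is rejected.

**Wise-IoU v1** scales the IoU loss by an exponential centre-distance
penalty,
$L_{v1} = (1 - \mathrm{IoU}) \exp\!\big(d^2 / (W^2 + H^2)^{*}\big)$.
The normalizer uses the smallest box enclosing prediction and target
(option `wiou_normalizer = "pred"` selects the predicted box's own
diagonal instead; the enclosing-box form is the default because it is
bounded and stable when predictions are poor). The star marks
*detachment*: the normalizer is a constant under differentiation, so the
penalty rescales the gradient without redirecting it. The package's
analytic gradients honour this contract and the test suite verifies it by
finite differences — the full numeric derivative (which lets the
normalizer vary) provably disagrees with the implemented gradient, while a
detach-frozen oracle agrees to 1e-6.

**Wise-IoU v3** multiplies $L_{v1}$ by a non-monotonic gain
$\kappa = \theta / (\tau \beta^{\theta-\tau})$, $\beta = 1.8$, $\tau = 3$,
where the outlier degree $\theta$ is the box's detached IoU loss divided
by an exponential running mean of IoU losses over training
(momentum 0.99, initialized at 1; the momentum is a convention of this
loss family, kept configurable). $\kappa$ rises to a single interior
maximum at $\theta = 1/\ln\beta$ and falls beyond it. Two modes are
exposed: the dynamic per-box $\theta$ (training default) and a fixed
$\theta$ (e.g. the reported static operating point $\theta = 2$, where
$\kappa = 1.2$ exactly), which makes unit tests exact. The running mean is
updated once per batch on detached values.

**Class-aware weighting.** With $n_s$ instances of a species among $n$
total, each loss term of that species is multiplied by
$w = (1 - n_s/n) / (1 - (n_s/n)^\eta)$. The typeset source formula is
ambiguous about the grouping; this reading is adopted because it uniquely
satisfies three anchors simultaneously: $w \equiv 1$ at $\eta = 1$ (the
documented neutral starting point), $w \to 1$ as $n_s/n \to 0$, and
$w \to 1/\eta$ as $n_s/n \to 1$ — so rarer classes always carry strictly
larger weights than common ones, which is the stated intent. The prose
claim that the multiplier *increases* with $\eta$ cannot hold together
with minority amplification under any candidate algebra (for small
$n_s/n$ the multiplier is essentially 1 for every $\eta$); we keep the
monotone-decreasing-in-$n_s$ behaviour and treat the weight function as a
single swappable component. Granularity: the classification matrix has
each class column of its foreground rows scaled by that class's weight
(background rows unweighted); each assigned target's box and
distribution-focal contributions are scaled by its ground-truth class's
weight. A single-class dataset has $n_s = n$ by necessity and gets
$w = 1$; with more than one class $n_s = n$ is rejected as a count
violation. Counts are over annotated instances of the training split, not
images.

**Normalization.** Every term is divided by the total assigned
target-score mass $\max(\sum_i t_i, 1)$, and box/DFL contributions are
additionally weighted per anchor by the assignment score $t_i$ — the
standard normalization for this detector family, held fixed for
reproducibility.

## Assignment and training

Targets come from task-aligned assignment: candidate locations are those
whose cell centre lies inside a ground-truth box, scored by
$s^{0.5}\,\mathrm{IoU}^{6}$ (predicted score of the target's class times
decoded-box IoU); the top 10 per ground truth are kept; a location claimed
twice goes to the ground truth with the higher IoU, ties to the lower
index, candidate ties to the higher IoU then lower location index — fully
deterministic. Soft classification targets are the usual
alignment-normalized scores.

Training is plain SGD (momentum 0.937, weight decay 5e-4 on weight
matrices only, linear warmup then cosine decay from `lr0 = 0.01` to 1 % of
it). These follow common practice for this detector family; none are
stated by the study. No pretrained weights are used anywhere. A single
integer seed controls weight initialization and data order; identical
seeds give bit-identical training trajectories.

One initialization choice matters at desk scale: the head's box-branch
bias is set to a decreasing ramp over the bins (`seq(2, -3)` per side), so
initial decoded boxes are roughly anchor-sized rather than
half-image-sized. With a uniform bias the initial IoU between decoded
boxes and ground truth is ~0.01, the alignment scores (and hence the
score-weighted box gradients) start near zero, and short runs can stall in
this cold-start regime; the small-box prior removes the stall without
affecting what the model can express.

## Evaluation

Detections are matched greedily in descending confidence; each matches the
highest-IoU unmatched ground truth at or above the threshold (ties: lowest
ground-truth index; equal confidences: stable by detection index). AP uses
all-points interpolation — the monotone precision envelope integrated
exactly over recall — rather than 11-point sampling; mAP@0.5:0.95 averages
the ten COCO thresholds. A class with ground truths and no detections
scores 0; a class with detections and no ground truths scores 0; a class
with neither is excluded. The stratified report ranks scoreable classes by
frequency and averages AP@0.5 within the head/middle/tail thirds of the
ranking. Evaluation applies no confidence floor by default; NMS uses
IoU 0.7 and at most 300 detections per image.

## The synthetic generator

Real survey data cannot ship with the package, so experiments run on
procedurally generated scenes that emulate the regime's stated
difficulties, not its appearance: a blue-green vertical-gradient
background with smooth colour noise (low contrast), Gaussian blur
(turbidity), bright Gaussian particles (marine snow), and fish-like
objects — a rotated ellipse body with a triangular tail, hue/aspect/
striping deterministic per class — alpha-blended into the background at a
configurable contrast. Instance classes follow a rank-frequency power law
$p_k \propto k^{-\gamma}$ (multinomial draw, then every class topped up to
at least one instance); $\gamma = 1.5$ gives head/tail count ratios above
an order of magnitude for 12 classes, qualitatively matching a heavily
imbalanced survey. Boxes are computed from the rendered foreground mask,
so labels are tight by construction. Placement rejects positions
overlapping an existing instance above IoU 0.3 (bounded retries).

What passing tests on this generator do **not** show: robustness to real
water-column appearance, camera artefacts, fish pose variation, or
fine-grained species similarity. The generator's role is to make the
*relative* behaviour of training objectives measurable (e.g. class-aware
on vs off under a controlled tail), not to predict absolute field
accuracy.

Datasets are written in the YOLO directory layout (normalized center-size
labels, 6-decimal text) with a 70/15/15 train/val/test split stratified so
every class appears in training, plus optional COCO JSON export.
Coordinates are 0-based half-open pixel boxes internally.

## Problem sizes used by the test suite

All suite experiments are sized for a single CPU: the overfit sanity check
trains the `micro` preset (width 0.25, depths 1-1-1-1, 64 px input,
2.9 M parameters) on 8 images and reaches mAP@0.5 ≥ 0.95 well inside
200 epochs; the imbalance experiment uses 12 classes, $\gamma = 1.5$,
100 images with 2–5 instances each, 40 epochs, three seeds per setting.
These sizes are the package's chosen study conditions for desk-scale
verification; the qualitative contrasts they probe (class-aware on/off)
are direction-only claims, with magnitudes expected to differ from
full-scale training.

## Numerical choices and degenerate inputs

IoU of two zero-area boxes is rejected rather than defined; the Wise-IoU
exponential normalizer of a zero-diagonal reference box likewise.
Probabilities are clamped at 1e-12 before logs; batch norm uses eps 1e-5
and running-statistics momentum 0.1; layer norm eps 1e-5. DFL targets are
clamped to $[0, r - 0.01]$ so the right bracketing bin always exists.
The CIoU aspect term's trade-off coefficient is treated as a constant
under differentiation, as is conventional. Equal-confidence detections are
ordered stably by index everywhere ties can arise.

## Known limitations

Training is CPU-bound and single-threaded beyond BLAS; image sizes beyond
~160 px and the full-width presets are practical for parameter accounting
and forward passes but not for training. The transformer path supports
training, but the suite's training experiments use the convolutional micro
preset for speed. Batch-norm statistics are computed over whatever batch
is given; very small batches give noisy inference statistics. The
evaluator implements the continuous all-points convention only — numbers
from 11-point or 101-point implementations differ in the third decimal.
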