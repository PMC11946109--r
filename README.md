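# fishdet

Desk-scale tools for studying **class-imbalance-aware training of
anchor-free fish-species detectors**. Automated reef-fish surveys produce
long-tailed data — a few common species dominate the annotations while most
species are rare — and underwater imagery is low-contrast, blurry and
littered with bright suspended particles. `fishdet` implements, in pure R
(with a few Rcpp kernels), the computational pieces needed to study this
setting end to end: the loss functions, a configurable CSP/transformer
detector with exact parameter accounting, a task-aligned training loop,
COCO-style evaluation, and a reproducible synthetic scene generator that
emulates the long-tailed underwater regime.

## The model and losses

The detector is a single-stage anchor-free network: a convolutional
backbone of C2f (split-transform-concat) stages, a PAN-FPN neck fusing the
stride-8/16/32 feature maps, and a decoupled head that predicts, per
location, `C` class logits and four side-offset *distributions* over
`reg_max + 1` bins (trained with the distribution-focal loss, DFL). The
study configuration rescales the backbone stage depths from 3-6-6-3 to
6-12-12-6 and replaces the final backbone stage and the neck fusion blocks
with transformer blocks (multi-head self-attention with learnable 1-D
positional embeddings).

Training minimizes

```
L = α₁·L_cls + α₂·L_DFL + α₃·L_box ,    α₁ = 0.5, α₂ = 1.5, α₃ = 7.5
```

where `L_cls` is binary cross-entropy and `L_box` is **Wise-IoU v3**:

```
L_WIoUv1 = (1 − IoU) · exp( ((x_p−x_g)² + (y_p−y_g)²) / (W²+H²)* )
L_WIoUv3 = κ(θ) · L_WIoUv1 ,   κ = θ / (τ·β^(θ−τ)) ,  β = 1.8, τ = 3
```

with `θ` the *outlier degree* — the detached IoU loss of the box divided by
its running mean over training — and the starred normalizer (smallest
enclosing box diagonal) treated as a constant under differentiation. The
gain `κ` is non-monotonic in `θ`: ordinary boxes get the largest gradients,
trivially easy and hopeless boxes are damped.

For long-tailed data every loss term is **class-aware** reweighted: a class
with `n_s` of the `n` training instances is weighted

```
w = (1 − n_s/n) / (1 − (n_s/n)^η) ,   η = 8
```

which is exactly 1 for every class at `η = 1`, tends to 1 for vanishing
`n_s/n`, and decreases to `1/η` as `n_s/n → 1` — rare species are amplified
relative to common ones.

## Worked example

```r
library(fishdet)

## exact parameter accounting of the model family
count_parameters("tf-full", num_classes = 121) / 1e6
#> [1] 30.64473

## class-aware weights on a long-tailed draw
set.seed(1)
counts <- sample_class_counts(num_classes = 6, gamma = 1.5, total = 400)
class_weight_table(class_distribution(counts), eta = 8)
#>       class  ns   frac weight
#> 1 class_000 218 0.5450  0.459
#> 2 class_001  72 0.1800  0.820
#> 3 class_002  54 0.1350  0.865
#> 4 class_003  26 0.0650  0.935
#> 5 class_004  21 0.0525  0.948
#> 6 class_005   9 0.0225  0.978
```

The head class (54.5 % of instances) is down-weighted to 0.46 while the
rarest class keeps weight 0.98 — a ~2× relative amplification of the tail.

```r
## train a micro detector on 8 synthetic underwater scenes
ds <- synthetic_dataset(num_classes = 4, num_images = 8,
                        instances_per_image = c(1, 3), gamma = 1,
                        image_size = 64, seed = 42)
fit <- fit_detector(ds, model = "micro", epochs = 80, batch_size = 8,
                    seed = 1)
fit
#> Anchor-free fish-species detector
#>   classes: 4   input: 64px   parameters: 2,909,608 (2.91 M)
#>   box loss: Wise-IoU v3, class-aware: on (eta = 8)
#>   trained 80 epochs, final loss 1.0432

predict(fit, ds$images[[1]], conf = 0.25)[[1]]
#>   class  conf   x1 y1   x2   y2
#> 1     1 0.989 17.7 20 39.6 30.9
ds$labels[[1]]           # ground truth (normalized center-size)
#>   class    cx    cy     w     h
#> 1     1 0.453 0.398 0.344 0.172
```

The detector recovers the annotated instance (class 1, ground-truth box
(18, 20, 40, 31) px) with confidence 0.99 and sub-pixel box error.
`plot(fit)` draws the loss curves, `summary(fit)` adds the class-weight
table, and `evaluate_detections()` / `map_summary()` score detections with
COCO-style mAP@0.5 and mAP@0.5:0.95, including head/middle/tail
frequency-stratified AP.

A command-line interface covering dataset generation, parameter counting,
class-weight tables, evaluation and training is installed at
`inst/cli/fishdet` (see `?cli_main`).

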