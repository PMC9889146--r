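---
title: "Detecting fetal-heart standard planes: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal-heart standard planes: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prenatal screening for congenital heart defects relies on five standard
2-D ultrasound planes of the fetal heart: the four-chamber view (4CH),
the left and right ventricular outflow tracts (LVOT, RVOT), the
three-vessel view (3VV) and the three-vessel-trachea view (3VT).  A
plane is *standard* when all the anatomical structures that define it
are present and identifiable.  `echoplane` implements this as a
two-stage pipeline:

1. an anchor-based single-stage convolutional detector localizes ten
   anatomical structure classes (4CH, LV, LA, AO, RV, AA, SVC, PA, MPA,
   T) as bounding boxes with confidence scores;
2. a rule-based classifier maps the detected structure set to one of the
   five planes, or to *nonstandard* when a required structure is
   missing.

The required structure sets are: 4CH = {4CH}; LVOT = {LA, LV, RV, AO};
RVOT = {RV, AA, SVC}; 3VV = {PA, AO}; 3VT = {AO, MPA, SVC, T}.  When
several templates are fully present, the larger set wins (more
anatomical evidence), remaining ties falling to the fixed priority
order 4CH, 3VT, LVOT, RVOT, 3VV.  The rule stage is a pure function of
the `(class, score)` multiset, so it is checked exhaustively against a
reference implementation over all $2^{10}$ structure subsets.

## The composite detection loss

Training minimizes $L = a\,L_{CLS} + b\,L_{OBJ} + c\,L_{BOX}$.

**Classification** $L_{CLS}$ is independent per-class binary
cross-entropy of the logistic sigmoid of the class logits against one-hot
indicators, summed over the positive matches and divided by the
positive-sample count $N_{pos}$.

**Objectness** $L_{OBJ}$ is binary cross-entropy of each prediction's
objectness logit against a *soft* target: the IoU between the currently
decoded prediction box and its matched ground-truth box (zero at
negatives), averaged over all $N$ predictions.  The IoU target is
treated as a constant during backpropagation.

**Box regression** $L_{BOX}$ is the SIoU loss
$$ L_{BOX} = 1 - IoU + \tfrac{1}{2}(\Delta + \Omega), $$
whose penalty decomposes into three coupled costs between the predicted
box and the ground truth:

* *angle cost* $\Lambda = 1 - 2\sin^2(\arcsin(c_h/\sigma) - \pi/4)$,
  where $c_h$ is the vertical gap between the box centers and $\sigma$
  their Euclidean distance.  We evaluate the algebraically identical
  closed form $\Lambda = \sin 2\alpha = 2\,c_h c_w/\sigma^2$, which is
  exact (not merely within rounding) at the axis-aligned and
  45-degree landmarks.  Coincident centers ($\sigma \le 10^{-9}$)
  return 0;
* *distance cost*
  $\Delta = (1 - e^{-\gamma p_x}) + (1 - e^{-\gamma p_y})$ with
  $p_x = ((b^{gt}_{cx} - b_{cx})/c_w)^2$, $p_y$ analogous, $c_w, c_h$
  the enclosing-rectangle dimensions, and $\gamma = 2 - \Lambda$: the
  closer the centers sit to a 45-degree arrangement, the milder the
  center-distance penalty.  We define $\gamma$ in terms of the angle
  cost because a definition in terms of $\Delta$ itself would be
  circular;
* *shape cost* $\Omega = (1-e^{-w_w})^\theta + (1-e^{-w_h})^\theta$ with
  $w_w = |w - w^{gt}|/\max(w, w^{gt})$.  The attention exponent
  $\theta$ lives in $[2, 6]$ with default 4; larger values relax the
  penalty for near-matching shapes.  Of the two readings the loss
  notation admits, the exponent is placed *outside* the parenthesis,
  which is the reading under which $\theta$ controls the degree of
  attention to shape mismatch.

Both BCE losses use the overflow-free form
$\max(x,0) - xy + \log(1+e^{-|x|})$ and are exercised across logits in
$[-100, 100]$.

### Gradients

All layer gradients (convolution, batch norm, SiLU, pooling, the focus
rearrangement) are hand-derived and verified against central finite
differences.  The gradient of the SIoU term in the four predicted box
parameters is itself computed by central finite differences of the
vectorized loss (8 vectorized evaluations per batch, step scaled to box
size).  At this problem scale the cost is negligible, the kinks of the
loss (`max`, `abs`, enclosing-box switches) are measure-zero, and it
removes an entire class of hand-derivation errors; the chain through
the box decoder is analytic.

## Detector architecture

The network follows the compact single-stage pattern: a focus slice
(lossless space-to-depth, verified bijective) feeding a CSPDarknet-style
backbone of conv+BN+SiLU blocks with residual CSP stages at strides
8/16/32 and an SPP stage (parallel 3/5/7 max pools) at stride 64; an
FPN top-down path and a PAN bottom-up path aggregate the four scales;
each scale has a 1x1 head emitting, per anchor and cell, 4 box offsets,
an objectness logit and 10 class logits.  Detection grids live at 1/8,
1/16, 1/32 and 1/64 of the input, so the input side must be divisible
by 64.  `depth_multiple` and `width_multiple` scale bottleneck counts
and channel widths; the test configuration (width 0.125, input 128)
has under a million parameters and trains on a single CPU.

Boxes are decoded as $b_{x} = (2s(t_x) - 0.5 + g_x)\,\textrm{stride}$
and $b_w = (2s(t_w))^2\, a_w$ (sigmoid-bounded offsets around the cell
and anchor), which keeps every prediction finite and the codec
invertible to under a pixel.

**Positive matching** (unspecified upstream; our rule): an anchor is
compatible with a ground-truth box when
$\max(w/a_w, a_w/w, h/a_h, a_h/h) < 4$; each compatible (scale, anchor)
produces positives at the cell containing the center plus the two
nearest neighbor cells, as the decoder's half-cell center range allows.
Conflicts for one (scale, anchor, cell) slot resolve to the box nearest
the cell center, with a canonical coordinate sort breaking exact ties,
so the assignment is invariant to ground-truth ordering.  Anchors are
fitted per dataset by k-means on box dimensions (3 per scale, assigned
by ascending area), with fixed fallback priors.

**Training** is plain SGD with momentum 0.9, a 3-epoch linear warmup
into cosine decay, seeded shuffling, and no augmentation — cardiac
anatomy is chiral, so mirror flips would corrupt anatomical labels.
Batch norm uses batch statistics while training; at the end of training
the running estimates are *recalibrated* by averaging batch statistics
over a seeded sample of training batches.  This matters: during SGD the
activation scale drifts, the exponentially weighted running estimates
lag, and the mismatch compounds multiplicatively through the ~40
normalization layers — calibrating on a section-stratified sample keeps
inference-mode behavior aligned with training-mode behavior.  The
calibration sample is drawn across the whole dataset because files on
disk are grouped by section.

**Inference** letterboxes to the input size, decodes all predictions,
scores them as objectness times best class probability, applies greedy
per-class NMS (defaults IoU 0.45, score 0.25; both configurable) and
maps boxes back to source pixels.  For deployment the batch-norm layers
are folded into their convolutions; fusion preserves outputs to 1e-5
and is only legal in inference mode.

### Default loss weights

The package defaults are $a = 0.5$, $b = 1.0$, $c = 0.05$, the
conventional single-stage operating point for large-scale training.
The reference experiment (below) uses $c = 0.5$: with only 200 images
and 40 epochs, the box-regression signal at $c = 0.05$ is too weak to
converge within the run, while classification and objectness are
unaffected by the stronger setting.  Both are plain configuration
values.

## The synthetic generator

Clinical fetal echocardiograms are not redistributable, so the package
ships a seeded generator of *schematic* ultrasound images that emulates
the statistical structure the detector and classifier assume: a
transducer fan mask (apex above the image, ±35°), a mid-gray tissue
background, one filled ellipse per structure of the section's template,
multiplicative uniform speckle ($U(1 \pm 0.08)$ by default) followed by
a 0.8-px Gaussian blur.  Chambers render bright (0.70–0.97) and vessels
dark (0.02–0.42) on an evenly spaced gray ladder, with class-specific
sizes (0.11–0.42 of the image side); placements are Gaussian around
per-section nominal layouts, resampled on fan violations or overlaps.
Annotations are the ellipses' tight boxes (within 1 px of the rendered
extent), written in darknet text format (normalized center/size, 6
decimals).  Nonstandard variants drop required structures with a
configurable probability and are labeled by running the section rules
on the ground-truth structure set.

What the generator does *not* emulate: real speckle statistics
(Rayleigh/Rician envelopes), shadowing and attenuation, anatomically
correct shapes and adjacency, probe/instrument variability, or the
image-quality gating of clinical inclusion criteria.  Passing the
end-to-end tests therefore demonstrates that the pipeline — losses,
assignment, training dynamics, decoding, evaluation, section rules — is
implemented correctly and can be learned end to end; it makes no claim
about clinical-image performance.

## The reference experiment and problem sizes

`run_benchmark_experiment()` generates 50 images per section at 128 px
(easy preset), splits 80/20 into 200 training and 50 held-out images,
fits anchors, trains the width-0.125 detector for 40 epochs (batch 8,
peak learning rate 0.05), and reports held-out mAP@0.5, per-class
AP/PPV/S/F1/specificity, and the fraction of held-out images whose
section label is recovered from the detector's own structure sets.
These sizes were chosen as the smallest round configuration at which
the easy preset trains reliably on a single CPU; the same function is
what `scripts/acceptance.R` runs.

Evaluation details worth noting: AP uses all-point interpolation (the
exact area under the precision-recall envelope), greedy one-to-one
matching by descending score at IoU ≥ 0.5 — deterministic and
oracle-checkable, as opposed to 11-point sampling; mAP averages the
defined per-class APs; classes without ground truth are excluded with a
warning rather than silently scored 0.  Rates with zero denominators
are reported as `NA`, never as 0.  The McNemar comparison reports the
continuity-corrected $\chi^2 = (\max(|b-c|-1,0))^2/(b+c)$ and takes its
p-value from the exact two-sided binomial when the discordant count is
below 25, where the asymptotic approximation is poor (per-section case
counts in rater studies are routinely that small).

## Numerical choices and degenerate inputs

* $\sigma \le 10^{-9}$ (coincident centers): angle cost 0, no angular
  preference; zero-size enclosing rectangles give distance cost 0.
* Boxes must have strictly positive width and height; violations are
  validation errors, not silent fixes.
* $N_{pos} = 0$ (no positives in a batch): classification and box terms
  are 0 with a warning; the objectness term still trains on negatives.
* Head objectness biases initialize to $-4.6$ (a ~1% prior) so early
  training is not dominated by the negative sea.
* `theta` outside $[2, 6]$ is clamped with a warning.
* Ground-truth boxes reaching outside the image are clipped with a
  warning before assignment.

## Known limitations

* The detector is a CPU-scale reimplementation for method validation;
  it has no GPU path and is not meant to train at clinical resolution.
* The section rules use structure presence only; geometric plausibility
  (vessel arrangement, symmetry, the trachea behind the SVC) is out of
  scope.
* Specificity for detection classes uses image-level absence agreement
  (an image with neither a ground-truth box nor a detection of a class
  counts as a true negative), the natural denominator in a detection
  setting; it is not comparable to pixel- or case-level specificity.
* The synthetic easy preset is deliberately separable; harder presets
  (more noise, smaller structures) train more slowly and are not part
  of the acceptance battery.
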