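---
title: "Explainable mixture-of-experts segmentation of vascular cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable mixture-of-experts segmentation of vascular cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moeseg)
```

## The problem

Delineating the lumen and the outer wall of an abdominal aortic aneurysm
(AAA) on axial contrast-enhanced CT angiography slices is the basis for
every downstream clinical quantity: neck lumen area, common iliac areas,
and the maximum diameter of the outer wall that drives repair decisions.
A single segmentation network struggles with the heterogeneity of this
anatomy — thin walls a pixel or two wide, intraluminal thrombus with
intensity between lumen and wall, low-contrast acquisitions, streak
artifacts. `moeseg` implements a mixture-of-experts (MoE) answer to this
heterogeneity, with every routing decision exposed as an inspectable map.

## The model

**Experts.** Three U-Nets share one architecture — an encoder that halves
the spatial resolution per stage through paired 3x3 convolutions, ReLU and
max pooling; a bottleneck without further downsampling; a decoder that
upsamples and concatenates the matching encoder map through skip
connections; and a 1x1 convolution with sigmoid producing a per-pixel
foreground probability. Decoder upsampling is nearest-neighbor interpolation followed by
convolution — interpolation is the mechanism the architecture calls for,
and a transposed-convolution variant would add parameters without benefit
at this scale. They are specialized by their training recipes:

* Expert 1 — BCE + Dice loss (pixel accuracy balanced with region overlap),
* Expert 2 — Focal loss (`alpha = 0.25`, `gamma = 2`), which concentrates
  gradient on hard pixels,
* Expert 3 — BCE + Dice again, but with a different initialization seed and
  a different data partition, so it converges to distinct features.

**Error maps and routing.** During training, each expert's signed error
map `E_i = P_i - Y` locates its failures. An *error learner* (a small CNN,
channels 4→16→16→8) reads the concatenation `[image, E1, E2, E3]` and
produces an 8-channel error-feature stack; the *robust weight router*
(9→16→3 plus a per-pixel softmax) turns `[image, features]` into a weight
map `w_i(x, y)` on the 3-simplex at every pixel. The fused prediction is
the exact per-pixel convex combination

$$P_\text{final}(x,y) = \sum_{i=1}^{3} w_i(x,y)\, P_i(x,y).$$

**Inference-time inputs.** `E_i` needs ground truth, which does not exist
at inference. The router therefore consumes *disagreement maps*
`D_i = P_i - \bar P` (deviation from the ensemble mean), which preserve the
channel layout and scale of the error maps. The package can train the
router on true error maps (teacher forcing) or on disagreement maps; the
default is disagreement, so the router sees the same input distribution at
training and inference. This substitute is a design choice of this
package, documented here because the choice is genuinely open.

**Gate regularization.** Per-pixel softmax gates tend to collapse onto one
globally good expert: the softmax saturates, gradients vanish, and the
mixture degenerates to a single model. Stage-2 training therefore applies
a small L2 decay to the gate logits (`router_config(logit_decay = 0.01)`),
a standard anti-collapse device in mixture-of-experts training. With it,
weights stay soft and per-pixel specialization can emerge; setting it to 0
restores the unregularized gate.

**Diversity objective.** The package also implements the inter-expert
diversity penalty `L_div = sum_{i<j} ||theta_i - theta_j||^2` over
flattened parameter vectors (whole-vector, not per-layer — an assumption,
since either reading is defensible), its sampled approximation (mean over
uniformly drawn pairs, unbiased for the pair mean), and the total
objective `L_total = L_seg - lambda_reg * L_div`. Because the minus sign
*rewards* parameter distance, `L_total` is used only in the optional joint
fine-tuning stage (`train_schedule(epochs_joint > 0)`, default off), with
the diversity term capped in magnitude (`loss_config(div_cap)`) so the
reward cannot diverge; `lambda_reg` defaults to `1e-4` since no reference
value exists.

**Attention maps.** For a scalar head `Z` — by default the spatial mean of
the fused foreground probability, since the classifier head is otherwise
unspecified — the attention map is
`A(x) = Z * (dZ/dX) / ||dZ/dX||_1`, computed by exact backpropagation
through experts, error learner, router and fusion to the input pixels. A
vanishing gradient yields an all-zero map with a warning.

**Training stages.** Stage 1 trains each expert independently on its own
partition with its own loss (per-sample Adam, `lr = 1e-3`). Stage 2
freezes the experts and trains the error learner and router end-to-end by
minimizing the BCE of the fused prediction. Stage 3 optionally fine-tunes
everything jointly with `L_total`. This ordering reconciles "individually
trained experts" with a joint objective: specialization first, then
fusion.

## The phantom generator

Clinical CTA data cannot ship with a package, so `moeseg` generates
seeded vascular phantoms that emulate the *statistical structure* of
axial AAA slices: a bright elliptical lumen (intensity 0.85) inside a
soft-tissue wall annulus (0.45) on a darker background (0.15), optional
intraluminal thrombus band at intermediate intensity (0.60), additive
Gaussian noise (`noise_sigma = 0.05` by default), low-contrast variants
(wall/background gap shrunk to at most `2 * noise_sigma` — the failure
mode that motivates manual correction), and streak artifacts. Geometry
defaults scale with resolution (lumen semi-axis 5–16% of the image side,
wall thickness from 1 px — thin-wall cases — to 3% of the side), and the
default 256 px image matches the router's native feature resolution.
Intensity levels are free parameters: no public reference distribution
exists for the clinical data, so they are chosen for realistic contrast
ordering, not calibrated.

Multi-slice exams add a proximal neck, a single fusiform bulge (a
Gaussian radius profile peaking at a configurable slice) and a distal
bifurcation into two iliac lumens, with circular cross-sections so the
analytic per-slice geometry (areas, hydraulic diameters) is known exactly
and recovery can be tested.

What the phantoms deliberately do **not** model: partial-volume blur at
boundaries, anisotropic CT noise texture, neighboring organs with
confusable intensities, or anatomical curvature along the exam axis.
Passing tests on phantoms therefore demonstrate that the *mechanisms*
(routing, fusion, correction, measurement) work as specified — not that
clinical-grade accuracy transfers to real CTA.

## Numerical choices

* **Binarization** of probability maps at 0.5.
* **HD95**: boundary pixels are foreground pixels with a background
  4-neighbor (the image border counts as background); the percentile is
  the linear-interpolation percentile of sorted directed distances; the
  symmetric maximum of both directed values is scaled to mm by the pixel
  spacing. Both masks empty ⇒ overlap metrics are 1 (vacuous agreement),
  HD95 undefined.
* **Zero denominators** in confusion-derived rates are reported as `NaN`
  with a warning, never silently 0.
* **Hydraulic diameter** `D_h = 4A/P` is measured on a periodic cubic
  B-spline fit through a subsample of the marching-squares 0.5-level
  contour. The raw pixel-level contour zigzags at pixel scale and inflates
  perimeters by roughly 7% on smooth anatomy; the smoothed contour brings
  a disk's `D_h` within about 1% of its true diameter. Left and right
  iliac areas are assigned by centroid x-order; neck and bifurcation
  slice indices come from exam metadata or a user-supplied labels file.
* **Contour correction** uses non-rational periodic B-splines (degree 3 by
  default, all weights 1): the correction procedure is an interpolating
  spline fit through user control points, so rational weights add nothing
  here. With zero smoothing the curve interpolates every control point
  (the coefficients solve the periodic interpolation system on the uniform
  knot vector). Rasterization uses an even-odd scanline fill;
  self-intersecting curves are rejected with the crossing location;
  "interactive" editing is realized as a pure, replayable edit-list API,
  so a recorded session reproduces a bit-identical mask.
* **Determinism**: every stochastic step (phantom drawing, partitioning,
  initialization, shuffling, pair sampling) derives from explicit seeds;
  identical seeds on one machine reproduce identical artifacts, including
  the metric CSVs of a full pipeline run.

## Problem sizes used by tests and the acceptance study

The training-behavior checks use a 200-slice, 128 px dataset (100
thick-wall, 100 thin-wall slices), depth-4 U-Nets with 8 base channels, 4
epochs per stage — enough for each expert to exceed 0.90 held-out Dice on
noiseless phantoms and for the router to weight the thin-wall expert
higher on thin-wall anatomy. `scripts/acceptance.R` runs a slightly
smaller end-to-end study (96 px, 120 slices, 3 epochs, both tasks) plus an
18-slice exam for geometric recovery; both sizes are the package's chosen
desk-scale study conditions. At the smaller script scale the router weight
gap is near zero — per-pixel specialization needs the larger study to
emerge, which is why the specialization property is asserted at the
200-slice scale.

## Known limitations

* CPU-scale studies only: the networks are intentionally small (tens of
  thousands of parameters), so absolute accuracy is bounded by capacity,
  not by the method.
* The disagreement-map substitute for inference-time error maps is an
  assumption; nothing guarantees disagreement localizes true error when
  all experts fail identically.
* Phantoms are 2D; no 3D surface reconstruction or centerline-based
  diameters.
* The hydraulic-diameter contour smoothing assumes a largest component
  with a roughly smooth boundary; deeply concave or fragmented masks fall
  back to the raw traced contour.

## A worked example

```{r example, eval = FALSE}
library(moeseg)

cfg <- experiment_config(image_size = 96, depth = 4, base_channels = 8,
                         n_samples = 80, epochs_experts = 3,
                         epochs_router = 3, seed = 1)
ds <- run_generate(cfg, "study/data")
fw <- run_train(cfg, ds, "study/checkpoints")
pr <- run_predict(cfg, fw, ds$test, "study/predictions")
ev <- run_evaluate(cfg, lapply(pr, function(p) p$wall$fused_mask),
                   lapply(ds$test, `[[`, "wall_mask"), "study/metrics")
ev$summary

# explainability artifacts for one slice
one <- moe_predict(fw$wall, ds$test[[1]]$image, truth = ds$test[[1]]$wall_mask)
str(one$weights)      # per-pixel expert weights on the simplex
str(one$error_maps)   # signed per-expert error maps
att <- attention_map(fw$wall, ds$test[[1]]$image)
```
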