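---
title: "Weakly supervised chalkiness phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised chalkiness phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotyping problem

Chalkiness — the opaque portion of a rice grain caused by loosely packed
starch granules — is a key grain-quality defect, intensified by high night
temperature during grain filling. Scoring it by eye is slow and subjective,
and pixel-level annotation of chalky regions (10–100 polygon clicks per
grain) is too expensive to scale to the thousands of grains a mapping
population produces.

`chalkcam` takes the weakly supervised route: only image-level labels
(*chalky* / *non-chalky*) are needed for training. A convolutional
classifier learns the binary distinction, and class-activation mapping then
recovers *where* in the grain the chalky evidence lies, giving pixel-level
localization and continuous per-grain chalkiness phenotypes without any
pixel-level supervision.

## Pipeline

1. **Cropping.** Plate scans holding ~25–30 grains are converted to
   grayscale (Rec. 601 weights), edges are detected (Gaussian smoothing,
   Sobel magnitude, two-level hysteresis with thresholds defaulting to
   0.67/1.33 × the median gray value), contours are closed morphologically
   (3×3 box, 2 iterations), and each connected component of at least
   `min_area` pixels (default 200) yields one bounding box. Because the
   smoothed edge halo overshoots the grain outline by a few pixels, each
   box is tightened to the Otsu foreground it contains. Boxes touching the
   plate border are counted and dropped by default — a truncated grain
   cannot be phenotyped reliably.
2. **Classification.** Crops are resized to the model input by direct
   bilinear resize (no aspect preservation) and classified chalky vs
   non-chalky.
3. **Localization.** A class-activation heatmap for the chalky class is
   computed at a chosen convolutional layer, upsampled to input
   resolution, and binarized at a threshold `T` expressed as a percentage
   of the heatmap's per-image maximum.
4. **Quantification.** The binary mask and the normalized heatmap are
   summarized over the grain foreground as the chalk-area percentage and
   the ChalkyScore.

## The classifier

The packaged backbone (`"tiny"`) is a three-block network — 3×3
convolution, ReLU, 2×2 max-pool, with 8/16/32 channels — followed by global
average pooling and a two-logit linear head. For 64×64 input its
inspectable feature stacks are 32×32×8 (`block1`), 16×16×16 (`block2`) and
8×8×32 (`block3`). It is deliberately small enough to train on a CPU in
minutes, and it is written with exact backpropagation because the
CAM engine needs true logit gradients at arbitrary layers, not a framework's
opaque autograd.

Training is minibatch SGD with momentum 0.9 on the softmax cross-entropy
loss (batch 32, learning rate 0.05, both configurable). Inputs are scaled
to `[0, 1]` and centered at 0.5; with strictly positive inputs the
first-layer weight gradients are heavily correlated across filters and
convergence crawls, whereas with centering the synthetic task converges in
a few epochs. The checkpoint retained is the epoch with the best
development-set chalky F1. With a fixed `rng_seed` the full training
trajectory is reproducible.

Prediction ties (exactly equal logits) break toward non-chalky, the lower
class index, so downstream gating is deterministic.

## Class-activation mapping

Let $f^k$ ($k = 1,\dots,K$) be the feature maps of a chosen layer with $N$
spatial positions each, and $y^c$ the *logit* (pre-softmax score) of the
class of interest $c$ (chalky throughout). Grad-CAM weights each map by the
spatial mean of the exact gradient

$$w^c_k = \frac{1}{N}\sum_{i,j} \frac{\partial y^c}{\partial f^k_{i,j}},$$

and forms the heatmap $H^c = \mathrm{ReLU}\big(\sum_k w^c_k f^k\big)$,
which is then upsampled to the input resolution. Gradients are taken with
respect to the logit, never the softmax output: the softmax couples the
two classes and distorts the attribution. Positive rescaling of the logits
rescales the heatmap exactly; everything downstream is scale-invariant.

Two variants are provided for comparison:

* **Grad-CAM++** uses pixel-wise coefficients
  $\alpha_{ij} = g_{ij}^2 / (2 g_{ij}^2 + \sum_{ab} f_{ab}\, g_{ij}^3)$
  (with $g$ the logit gradient and 0/0 treated as 0) and weights
  $w_k = \sum_{ij} \alpha_{ij}\,\mathrm{ReLU}(g_{ij})$ — designed to
  spread credit over larger or repeated class regions.
* **Score-CAM** is gradient-free: each map is upsampled, min–max
  normalized, used to mask the input, and scored by the class logit of the
  masked image; scores are softmax-normalized across maps. A spatially
  constant map is ill-defined under min–max normalization and receives
  weight zero by convention.

**Upsampling convention.** "Linear interpolation" is implemented as
bilinear resampling with *corner-aligned* sampling (output corners coincide
with input corners), chosen so the operation has a closed form that tests
can check bit-for-bit. Binarization is defined relative to the per-image
maximum, so this choice (and any normalization before colormapping) cannot
change the masks or scores.

## Phenotypes

With $Z$ the number of grain-foreground pixels (Otsu threshold, largest
connected component, holes filled):

* **ChalkyScore** $= \frac{1}{Z} \sum_{(i,j)\,\in\,\text{GrainArea}}
  \tilde H_{ij}$, where $\tilde H$ is the final heatmap divided by its
  per-image maximum. The normalization is what pins the score to
  $[0, 1]$ — 0 means no chalkiness, 1 means severe chalkiness over the
  whole surface; raw ReLU magnitudes are model-scale-dependent and could
  not guarantee that range. (The defining formula leaves the
  normalization implicit; this package makes it explicit rather than
  assuming it silently.)
* **Chalk-area percentage** $= 100\,|M \cap \text{GrainArea}|/Z$ with $M$
  the binarized heatmap.

By default grains *predicted* non-chalky are gated to score 0, area 0 and
an empty mask, mirroring how the pipeline is used: heatmaps quantify grains
flagged chalky. Gating can be disabled (`gate_on_prediction = FALSE`), and
evaluation metrics handle the distinction explicitly instead.

## Evaluation

Localization is scored on chalky ground-truth images by
intersection-over-union between the binarized heatmap and the
polygon-derived truth mask. Two accuracies are reported: **GT-known
localization accuracy** (fraction with IoU ≥ 0.5, classifier ignored) and
**localization accuracy** (label correct *and* IoU ≥ 0.5); the former
bounds the latter. The 0.5 cutoff is applied *inclusively* in both — the
two informal phrasings ("0.5 or more", "more than 50%") differ only on
exact ties, and one convention is fixed and documented. All reported
percentages round half-up to 2 decimals; undefined precision/recall/F1
ratios (0/0) report as 0.00.

The layer and threshold are selected by grid search on the development
set: default thresholds 10–80% in steps of 10 over the inspectable layers,
with ties broken toward the lower layer then the lower threshold. On real
polished-rice data this class of models selects a lower-intermediate layer
at T = 60%, which is why `block2` and `T = 60` are the package defaults
for quantification; both are arguments everywhere they appear.

Group aggregation (`aggregate_by_group()`) reports per-group mean ± SEM
(sd/√n; NA for singleton groups) of both phenotypes for downstream
genotype × panicle × treatment comparisons. Significance testing is out of
scope.

## The synthetic generator

Real scans cannot ship with a package, so every stage is exercised against
a generator whose ground truth is exact by construction:

* **Grains** are ellipses (major axis ~70–90 px, minor ~36–46 px) at gray
  level 130–150 on a background of 10, so Otsu separation and edge
  detection are well-posed — the same contrast regime as a transparent
  Petri plate on a flatbed scanner.
* **Chalk** is one blurred bright elliptical blob per grain (peak 50–70
  gray levels, Gaussian σ = 2 px), geometrically similar to the grain and
  scaled by $\sqrt{\text{fraction}}$ so large blobs still fit inside. A
  soft-boundary object has no canonical binary outline, so the truth mask
  is defined at *half the blurred peak* — unambiguous, and consistent with
  how a human annotator clicks the visible rim of a fuzzy patch. The
  polygon ground truth is the marching-squares contour of that mask,
  decimated to ≤ 100 vertices like a manual annotation.
* **Plates** hold non-touching grains (≥ 12 px gaps); optionally one grain
  straddles the border to exercise truncation handling. Pixel noise
  (σ = 3) is added plate-wide; images are quantized to 8 bits.
* **Datasets** are written as PNG crops plus a CSV manifest and a VIA v2
  JSON of chalk polygons, split 2:1:1 into train/dev/test with no grain in
  two splits.

Default generator parameters are the package's study conditions: 50%
chalky grains with chalk fractions uniform in 0.2–0.5. What the generator
does *not* emulate: real starch texture, multiple chalk blobs or specific
chalk types (white-belly/core/base), touching or overlapping grains,
illumination gradients, abrasion stains and scratches. Passing tests
therefore demonstrate that the machinery is correct and recovers planted
signal; they do not certify accuracy on real scans, which additionally
needs representative images and, for the published accuracy regime,
ImageNet-pretrained backbones.

## Numerical choices and degenerate inputs

* Rasters are `[row = y, col = x]`; boxes are 0-based half-open
  `[x0, x1) × [y0, y1)` — stated once, used everywhere.
* Polygon rasterization sets a pixel iff its *center* lies inside under
  the even-odd rule, so rasterized area matches geometric area to about
  half the perimeter.
* Max-pool ties route gradients to the first (lowest-index) maximum;
  grid-search and prediction ties are likewise deterministic.
* All-zero heatmaps give empty masks and score 0; empty grain masks are an
  error (`Z = 0` would divide by zero); a uniformly bright crop is all
  grain, a uniformly dark crop has no foreground and errors.
* Every stochastic entry point takes a seed and restores the caller's RNG
  state.

## Problem sizes in the shipped tests

The test-suite and the acceptance script run the full pipeline at desk
scale, chosen so a complete run takes a few minutes on one CPU: 400
synthetic grains split 200/100/100, 30 training epochs, a 3-layer × 7
threshold grid, and 1000-case property sweeps for the quantifier. At these
sizes the synthetic task is deliberately easy (high contrast, one blob);
the classifier typically reaches ≥ 95% test accuracy and Grad-CAM
localizes the blob with GT-known accuracy well above the 60% bar the
package holds itself to.

## Known limitations

* Only the `"tiny"` backbone ships; the interface accommodates larger
  pretrained backbones but none are bundled.
* Touching grains are not separated (no watershed); truncated grains are
  dropped, not recovered.
* The chalkiness score is relative to the per-image heatmap maximum, so it
  is comparable across grains under one trained model and configuration,
  not across models.
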