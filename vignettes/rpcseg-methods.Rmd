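---
title: "Methods: residual pancreatic cancer segmentation, cross-validation and pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual pancreatic cancer segmentation, cross-validation and pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After neoadjuvant therapy (NAT), pathologists grade how much viable tumor —
residual pancreatic cancer (RPC) — remains in a resection specimen. Manual
grading is subjective; a pixel-level segmentation model applied to annotated
regions of interest (ROIs) from H&E whole-slide images yields an objective,
quantitative substrate: the number of pixels classified as cancer. `rpcseg`
implements that pipeline end to end, together with the statistical machinery
used to summarize how such a model transfers across slide scanners:
leave-one-scanner-out internal-external cross-validation and random-effects
meta-analytic pooling of the per-scanner mean F1 scores.

Because clinical H&E cohorts are not redistributable, the package carries a
seeded synthetic cohort generator so that every stage — annotation handling,
patch sampling, stain normalization, training, stitched inference, scoring,
cross-validation, pooling — is exercised by reproducible tests with known
ground truth.

## Class system

Annotations use a twelve-class taxonomy (normal ducts, cancer, in-situ
neoplasia, islets of Langerhans, acinar tissue, atrophic/metaplastic
parenchyma, adipose tissue, vessels, nerves, uncertain, lumina,
lymphoid/inflammatory infiltrates). For modeling these are merged to five
target classes:

| code | class | merged from |
|------|-------|-------------|
| 0 | background | stroma/unannotated, vessels, nerves, lymphoid/inflammatory |
| 1 | normal ducts | normal ducts |
| 2 | cancer | cancer + in-situ neoplasia |
| 3 | other epithelium | islets, acinar, atrophic/metaplastic |
| 4 | fat | adipose tissue |
| 255 | ignore | uncertain |

Design choices where the class system is genuinely open:

* **Lumina** have no fixed merged class: a lumen is the interior of whatever
  structure surrounds it, so at rasterization a lumen polygon takes the
  target class of its smallest enclosing annotated structure and falls back
  to background when nothing encloses it.
* **Uncertain** structures get the ignore code (255): they are rendered
  (white) but excluded from the loss and from every metric numerator and
  denominator. Scoring them as either correct or incorrect would reward or
  punish regions that even the annotating pathologists declined to call.
* **Cancer within vessels/nerves** is drawn on top during rasterization, so
  separately annotated cancerous foci inside such structures stay cancer
  regardless of polygon order in the file.
* **Pixel convention**: 0-based indices, even-odd polygon containment tested
  at pixel centers, half-open image bounds. This is unambiguous and lets a
  brute-force per-pixel oracle verify the scanline fill exactly.

## Synthetic cohort

`generate_roi()` builds a scene as hematoxylin/eosin concentration maps:
textured pink stroma with sparse near-pure eosin collagen specks; smooth
rings for non-neoplastic ducts; jagged, harmonically-modulated rings with
dense near-pure hematoxylin nuclear stippling for cancerous ducts (the
`atypia` parameter controls wall irregularity); clustered blobs for other
epithelium; pale circles for fat. Concentrations are rendered to RGB by
Beer-Lambert composition `I = 256 exp(-(c_h H + c_e E)) - 1` over a 2x3
optical-density stain basis, which makes deconvolution-based normalization
exactly verifiable: a scene rendered in the reference basis must be (and is,
to under 2 intensity units) a fixed point of `normalize_patch()`. The
near-pure nuclear and collagen pixels anchor the angular extremes of the OD
cloud, so the basis is identifiable from the image alone.

Scanner profiles (`default_scanner_profiles()`) perturb only the rendering:
a rotated stain basis plus per-channel gamma, brightness/contrast offsets
and Gaussian sensor noise. The philips profile is the neutral reference;
3dhistech is deliberately the most divergent, mirroring the qualitative
vendor differences reported for real scanners. Masks depend only on the
geometry seed, never on the profile, which is what enables controlled
normalization experiments: the same tissue, "scanned" twice.

Default study conditions: 8 cases per scanner, 192 px square ROIs at a
nominal 2 px/µm, class mixture 10% normal ducts / 18% cancer / 8% other
epithelium / 8% fat (remainder stroma), duct radii 14-26 px, wall thickness
0.55 of the radius, atypia 0.35. One global seed drives a per-case seed
sequence (`seed + case index`), so single cases can be regenerated in
isolation. What the generator does **not** emulate: nucleus-level texture,
out-of-focus regions, tissue folds, staining batch effects within a scanner,
and annotation noise. Passing tests on this cohort therefore demonstrate the
*mechanics* of the pipeline (information flow, losses, stitching, scoring,
pooling) and scanner-transfer behavior in a color-dominated regime; they do
not certify performance on real histology.

## Patch sampling

Training patches follow the protocol exactly: a sliding window of
512x512 px patches at 50% overlap (stride 256); a patch enters the data set
only if at least one foreground class (not background, not ignore) covers at
least 10% of its area — the threshold is inclusive, read literally; and at
most 50 patches per class per case, enforced by seeded uniform subsampling.
The per-(case, class) tally counts patches retained *for* that class, so a
patch qualifying for several classes is kept once but consumes one slot per
class it was drawn for. Boundary strips narrower than one stride are not
sampled during training (no padding); inference covers them separately. At
desk scale the same machinery runs with 128 px patches and stride 64.

## Model and training

The segmentation network is a compact U-Net-style convolutional
encoder-decoder implemented in RcppArmadillo with hand-derived
backpropagation: two 3x3-conv + ReLU + 2x2-maxpool encoder levels, a
bottleneck, nearest-neighbor upsampling with skip concatenation, and a 1x1
head with per-channel sigmoids. Width is a single knob (`base_channels`);
tests and the desk-scale cohort use 8 channels (~19k parameters), small
enough to train on one CPU in minutes. The loss is the protocol's
per-channel binary cross-entropy on one-hot targets over 5 channels
(background explicit), with ignore pixels given weight zero; inference
resolves channels by argmax of the sigmoid scores with ties to the lowest
class code. The optimizer is ADAM.

Choices worth recording:

* **Sigmoid + BCE rather than softmax cross-entropy** is the literal reading
  of a binary cross-entropy loss over a multi-channel mask; argmax at
  inference restores a single label per pixel.
* **Early stopping** watches validation loss on a held-out *case-level*
  split (default 25% of cases), never a patch-level split — patches of one
  case overlap heavily, and a patch split would leak. Training halts after
  `patience` consecutive epochs without improvement (protocol: 30 epochs,
  patience 7; desk scale: 10 epochs, patience 4) and returns the
  best-epoch weights.
* **Learning rate** defaults to 1e-4 for the protocol configuration; the
  desk-scale configuration uses 5e-3, appropriate for the much smaller
  network trained from scratch.
* **Determinism**: weight initialization, the case split, patch shuffling
  and augmentation draws all derive from the single config seed; two runs
  with equal seed, data and config produce identical weights. Gradients are
  verified against central finite differences in the test suite.

## Stain normalization and augmentation

`normalize_patch()` estimates the patch's two-stain basis Macenko-style:
project tissue OD pixels (white pixels removed) onto the top-two eigenplane
of their covariance, take robust angular extremes (1st/99th percentile) as
the stain vectors, solve per-pixel concentrations by least squares, and
re-render through the fixed built-in reference basis. Degenerate inputs
(blank patches, collinear bases) are returned unchanged with a warning. A
Reinhard-style channel-statistics alternative (`method = "reinhard"`)
matches OD channel means/SDs to reference statistics. Normalization is
applied per patch, identically at training and inference time, so train and
test distributions match.

Augmentation draws one geometric transform per patch (identity, 90/180/270
degree rotations, horizontal/vertical flips — applied to image and mask
alike, so per-class pixel counts are exactly preserved) plus color jitter on
the image only: brightness/contrast/saturation ±10% and hue ±0.02, mild
conventional ranges, all configurable.

## Stitched inference

Whole-ROI prediction slides the trained model at stride 256 (half overlap),
with the final row/column anchor clamped to the border so coverage is total;
ROIs smaller than a patch are reflect-padded for inference only. Overlapping
patch scores are combined by a weighted average with a separable
raised-cosine kernel floored at 0.01 — peaked at the patch center, strictly
positive at the edges. The kernel normalizes out exactly: where all covering
patches agree the stitched score equals that value to machine precision, and
with stride equal to patch size stitching degenerates to tiling. Rendered
overlays use a fixed bijective palette (cancer red, normal ducts green,
other tissue orange, fat pale yellow, ignore white, background black).

## Scoring and aggregation

Per case, one-vs-rest confusion counts are pooled at pixel level over all
ROIs; `F1 = 2TP/(2TP+FP+FN)` per class, with ignore pixels excluded from
every count. The headline score is the cancer-class F1 (the object of the
pipeline is RPC); a macro mean over defined classes is also reported. A
class absent from both truth and prediction is *undefined* and excluded
from averages rather than scored 0 or 1. Per scanner, the summary is the
mean headline F1 over cases with a t-based 95% CI,
`mean ± t(n-1, 0.975) · SD/√n` — the standard small-sample interval.

## Cross-validation and meta-analysis

Leave-one-scanner-out internal-external cross-validation trains on all
other scanners' cases and tests on the held-out scanner's, once per scanner;
a final model on all data can also be produced. Fold means are pooled with
a random-effects model:

* tau² by iterative REML (Fisher scoring, tolerance 1e-10, at most 100
  iterations, floored at 0, DerSimonian-Laird start). The test suite checks
  the root against the restricted profile likelihood and against an
  independent reference implementation.
* pooled mean `µ = Σ w_i y_i / Σ w_i` with `w_i = 1/(se_i² + tau²)`.
* 95% CI by the Hartung-Knapp-Sidik-Jonkman correction with a Jackson-type
  floor: the HKSJ scale `q = Σ w_i (y_i - µ)²/(k-1)` is floored at 1, so
  the corrected interval is never narrower than the unmodified Wald
  interval, and a `t(k-1)` quantile is used.
* heterogeneity: Cochran's Q; `I² = 100·tau²/(tau² + s²)` with the typical
  within-study variance `s² = (k-1)Σw̃ /((Σw̃)² − Σw̃²)`, `w̃_i = 1/se_i²`;
  a Q-profile interval for tau² (an approximation — the interval method
  behind published tau² CIs for this design is not standardized).

When pooling printed summaries, standard errors are reconstructed from 95%
CIs as `(upper − lower)/(2·1.96)`, assuming symmetric normal intervals —
the only information a printed table carries. Study inputs can come from
any CSV with `label`, `effect` and `se` or `lower`/`upper` columns
(`cmd_pool()`), which is the path that reproduces published per-scanner
tables. Internally generated fold summaries use `se = SD/√n`; pooling is
skipped (with the folds still reported) when a fold has a degenerate zero
SE, as happens when every case of a tiny fold scores identically.

## Problem sizes used by the tests

The suite runs at sizes chosen for a single CPU: unit tests use 96-128 px
ROIs, 48-64 px patches and 3-6 channel networks; the end-to-end check uses
the default study conditions (4 scanners x 8 cases, 192 px ROIs, 128 px
patches, 8-channel encoder, up to 10 epochs, fixed seed) and verifies that
every held-out-scanner fold reaches cancer F1 at least 0.80 and that
enabling normalization does not hurt the most divergent scanner. Parameter
recovery for REML runs 500 simulated meta-analyses at k = 50. The
Monte-Carlo check of the generator's mixture calibration uses 50 seeds at
512x512.

## Known limitations

* The deep encoder families used on GPU-scale cohorts (e.g. DenseNet-class
  encoders) are out of scope; the built-in encoder-decoder is intentionally
  compact. The module surface is identical, so a heavier backend could be
  substituted behind `train_config()`.
* Synthetic realism is bounded (see above); real-data performance claims
  require real cohorts.
* Normalization assumes a two-stain H&E model; immunohistochemistry or
  heavily faded slides violate it and trigger the degenerate-input path.
* The Q-profile tau² interval and the SE reconstruction from printed CIs
  are approximations, flagged as such.
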