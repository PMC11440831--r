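---
title: "Automated L3 selection and body-composition analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated L3 selection and body-composition analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodycomp)
```

## The problem

Body composition at the level of the third lumbar vertebra (L3) is the
standard CT surrogate for whole-body muscle and fat mass, and low muscle
mass (sarcopenia) is prognostic across oncology. Routine use requires two
automated steps that radiologists otherwise perform by hand:

1. **L3 slice selection** — find the axial slice through the L3 vertebral
   body in an abdominal CT volume;
2. **Tissue segmentation** — partition that slice into skeletal muscle
   (SM), visceral adipose tissue (VAT) and subcutaneous adipose tissue
   (SAT), from which the sarcopenia metrics follow.

`bodycomp` implements both steps, the derived metrics, and a synthetic
abdominal phantom generator so the entire pipeline can be trained,
validated and stress-tested without any clinical data.

## L3 selection as 2-D segmentation

A 3-D localization problem is reduced to 2-D. The volume is masked to the
body (threshold at -200 HU, largest 6-connected component, morphological
closing then dilation with a 5 mm box element), voxels outside the mask
are set to the background value, and a maximum-intensity projection along
the anteroposterior axis produces a coronal image in which the spine is
the dominant bright structure. Rows are rescaled to a fixed physical
height per pixel, and the image is padded to a fixed shape. A U-net is
trained to mark the L3 band: the single annotated row is extended to a
1 cm band to soften the extreme class imbalance.

Two numerical conventions matter and are stated once:

* slice `k` (0-based) sits at `z = k * spacing_z` mm, caudal to cranial;
* every projection carries a provenance record (crop offset, row scale,
  padding) that maps any projection row back to an original slice index;
  the inverse uses round-half-up, so the mapping is an exact identity
  whenever rows are at least as fine as slices.

Before projection, very long scans are pre-cropped: the lung centroid
(largest enclosed air component below -500 HU) and the pelvic centroid
(morphological skeleton of the bone mask in the caudal half, weighted
toward slices with large skeleton mass, which distinguishes the massive
pelvic ring from vertebral cross-sections) are located, and only when
they are more than 20 cm apart is the volume cut to
[pelvis - 20 mm, lungs + 20 mm]. The thresholds that the reference design
left unstated are explicit parameters here: body threshold -200 HU,
structuring element 5 mm, lung threshold -500 HU, bone threshold 150 HU,
crop margin 20 mm.

At inference time the network's L3-class probability map is averaged
across columns to a 1-D craniocaudal signal, smoothed with a Gaussian
(sigma 5 rows by default, configurable), and the global maximum among the
local maxima — ties broken toward the lowest row — is mapped back to a
slice index through the provenance.

## Tissue segmentation and HU windows

The selected axial slice is segmented by a second U-net into five
classes: background, other in-body tissue, SM, VAT and SAT. Class
probabilities are collapsed by per-pixel argmax (ties toward the lowest
class code, for determinism), and a Hounsfield-unit filter then forces
any pixel with HU above 150 or below -500 to background, whatever the
network said. The classical manual-analysis windows — muscle
[-29, 150] HU, adipose [-500, -30] HU — are available as an optional
strict per-class filter, off by default to keep the single global window
as the reference behaviour. The filter is idempotent by construction.

Network inputs are min-max normalized from the window [-1000, 1000] HU to
[0, 1]; the same normalization is applied at training and inference.

## Architecture, loss and training

Both tasks use a standard U-net: each encoder level applies two 3 x 3
convolutions with a 2 x 2 max pool; filters double per level; a
two-convolution bottleneck is followed by a symmetric decoder (2 x
nearest-neighbour upsampling, a channel-halving convolution, skip
concatenation, two convolutions), and a final 1 x 1 convolution with a
per-pixel softmax. Every hidden convolution is followed by per-channel
instance normalization (learnable scale and shift) and ReLU — the
de-facto standard in contemporary U-net practice. The normalization is
not a cosmetic choice here: with the small fixed learning rate, training
a from-scratch network on the L3 task is not feasible within the desk
epoch budget without it, while with it the loss descends smoothly. The
full-scale profiles mirror the reference design: depth 4 with 64 base
filters on 1088 x 512 projections for L3, and depth 4 with 32 base
filters on 512 x 512 slices for body composition.

Training minimizes the soft dice loss
`1 - (2 * sum(p*g) + s) / (sum(p) + sum(g) + s)` with smoothing constant
`s = 1`, averaged over foreground classes (all but background) in the
multi-class case; two empty maps therefore score a loss of 0. Adam is
used with learning rate 1e-4 and batch size 8 for up to 100 epochs, with
early stopping on the validation loss (patience 10 epochs, minimum
improvement 1e-4 — both unstated in the reference design and fixed here)
and checkpoint selection by the best validation DICE. Each batch
gradient is clipped to a global L2 norm of 1 before the Adam update: the
dice loss has a well-known failure mode in which the network collapses
to all-background predictions and the loss saturates with vanishing
gradients, and clipping the occasional exploding step prevents the jump
into that basin. Weights are He-initialized from a stored seed; the
whole loop is a deterministic function of its seeds. The convolution, pooling and upsampling primitives
and their adjoints are implemented in C++ (im2col plus BLAS matrix
multiplication); the backward pass is verified against finite differences
in the test suite.

Geometric augmentation (rotation, scaling, translation, optional elastic
deformation) applies one sampled transform identically to image and
target — bilinear for the image, nearest-neighbour for the target — and
can additionally paint artificial arm sections: soft-tissue-density
ellipses placed lateral to the body mask, emulating arms left in the
field of view.

## Desk-scale profiles

Everything in this package runs on a single CPU, so reduced "desk"
profiles are first-class configuration rather than an afterthought:

| | full | desk |
|---|---|---|
| L3 U-net | depth 4, base 64, 1088 x 512 | depth 3, base 16, 144 x 32 |
| body U-net | depth 4, base 32, 512 x 512 | depth 3, base 16, 64 x 64 |
| projection | 1 mm/row, pad to 1064 x 512 then 1088 | 3 mm/row, 12 mm/col, 144 x 32 |

At 3 mm per row the distance from the pelvic ring (the counting anchor)
to L3 fits comfortably inside the depth-3 receptive field, and a coarse
row grid costs little accuracy relative to the 1-5 mm slice spacings the
prediction is finally snapped to.

The desk experiments (`run_l3_experiment()`,
`run_bodycomp_experiment()`) use cohorts of 200 phantoms, train on 160
and evaluate on 40 held-out phantoms, with 15 training epochs. These
sizes were chosen once as the package's standard synthetic study
conditions; they keep a full experiment in the minutes range while
leaving the task non-trivial (slice thicknesses of 1-5 mm, jittered
anatomy, 20% arms, 10% implants).

## The phantom generator

The generator emulates the statistical structure the pipeline relies on,
not anatomy. A phantom is an elliptical trunk (with a mild craniocaudal
taper) built from a SAT rim, a muscle wall, paraspinal muscle blocks and
a VAT interior; a vertebral column of bone cylinders (35 mm bodies, 8 mm
disc gaps — a ~40 mm lumbar period) rising from a pelvic bone ring; lungs
as low-density ellipsoids in the cranial third; and optional hard cases:
arm cylinders lateral to the trunk and a cementoplasty-like implant
(1500 +/- 100 HU) filling one of the five most caudal vertebral bodies.
Default tissue HU distributions center the analysis windows with margin:
muscle 45 +/- 15, VAT -90 +/- 20, SAT -105 +/- 20, bone 400 +/- 100,
lung -800 +/- 50, air -1000. Per-voxel draws are truncated at +/- 3
standard deviations, so the window invariants hold for every voxel, not
just in expectation, and HU are stored as integers, as CT scanners do.
`noise_sd_hu` adds optional global noise on top and defaults to 0: the
per-tissue spread already provides texture, and a single noise knob keeps
the ground-truth HU/label consistency exact.

Ground truth for each phantom records the L3 z position and vertebral
extent, the tissue label map of the L3 slice, patient height, and the
construction's lung/pelvis centroids (used to validate the landmark
estimators). Cohort generation jitters slice thickness ({1, 2.5, 5} mm),
body size, column base (hence L3 position), vertebral height and patient
height, with configurable arm/implant fractions; the draw order is
documented so the sampling can be replayed independently.

What the phantoms deliberately do **not** model: organ texture and
contrast phases, realistic bone shape, scoliosis or transitional
vertebrae, ascites, and arms that touch the trunk. Passing the synthetic
experiments therefore demonstrates that the pipeline's operators,
training loop and coordinate bookkeeping are correct and that the method
works when its assumptions hold — it does not certify clinical accuracy,
which the reference cohorts (private) would be needed for.

## Sarcopenia metrics

With pixel areas in cm^2:

* SM/VAT/SAT areas: pixel count x pixel area;
* SMD: mean HU of SM pixels within [-29, 150] HU (windowed again inside
  the metric, so it is insensitive to whether the global filter ran);
* SMI = SM area / height^2 (cm^2/m^2);
* LBM = 0.3 x SM area + 6.06 (kg);
* SMG = SMI x SMD (HU cm^2/m^2). The reference text says "muscle area x
  SMD" while printing index units; the units win by default, and
  `smg_mode = "area"` provides the literal product.

Empty-vs-empty DICE is defined as 1, stabilizing per-class medians on
slices where a rare class is absent. The correct-slice tolerance defaults
to 20 mm — half a vertebral body — and is configurable, since "correctly
identified" has no published definition.

## Degenerate inputs and numerical details

* An all-air volume is a degenerate-input error in `body_mask()`.
* Missing lungs or pelvis downgrade `precrop()` to a no-op with a
  warning; the pipeline still emits a prediction.
* A constant probability signal is a no-peak error in `locate_l3()`.
* Projections larger than the target shape are center-cropped with a
  warning; padding uses -1000 HU everywhere.
* Fractional slice indices round half-up (toward cranial).
* An SMD over an empty windowed mask and an R^2 over fewer than two pairs
  or zero-variance truth are reported as undefined rather than guessed.

## Known limitations

* The early-stopping patience (10) and minimum delta (1e-4) are package
  choices; the reference design states early stopping without parameters.
* The desk profiles trade boundary resolution for speed; DICE values at
  64 x 64 are not comparable pixel-for-pixel with 512 x 512 results.
* DICOM support covers uncompressed little-endian 16-bit series only,
  which is sufficient for phantom round-trips and typical exports;
  compressed transfer syntaxes are rejected with a clear error.
* The 5-fold cross-validation harness is provided
  (`run_kfold_cv()`) but the shipped experiments use a single
  train/hold-out split to stay within CPU-scale budgets.
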