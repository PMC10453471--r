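---
title: "Methods: two-stage spine segmentation and vertebra recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage spine segmentation and vertebra recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Spine analysis in CT proceeds in two steps: first delineate the spine
against everything else (binary segmentation), then assign each spine voxel
a vertebra identity (recognition, background plus up to 24 vertebra classes
C1--L5 with an L6 allowance). `spineseg` implements both stages as
convolutional networks with hand-derived forward and backward passes over
compiled convolution kernels, so the complete pipeline — preprocessing,
augmentation, training, inference, evaluation — runs deterministically on a
CPU with no deep-learning framework dependency.

**Stage 1** is a 2D encoder--decoder applied slice-wise. Each encoder level
is a residual block followed by 2x2 max-pooling and a cascaded hierarchical
atrous spatial pyramid pooling (CHASPP) block: a root 3x3 dilated
convolution feeding three parallel dilated branches whose outputs are
concatenated and projected. Composing a root of dilation 2 (receptive field
5) with a branch of dilation 3 (receptive field 7) yields a receptive field
of 11 while sampling far more input positions than a single 3x3 kernel with
an equivalent reach — that densified sampling is the point of the hierarchy.
The decoder mirrors the encoder with nearest-neighbour upsampling; each
skip connection passes through an attention gate: per spatial position a
query is projected from the decoder state, a key and a value from the
encoder skip, the raw score is the query--key dot product and the logistic
of that score (strictly inside (0,1)) rescales the value. Dropout (0.3)
sits in the bottleneck and decoder. A final 1x1 convolution produces
background/spine logits; softmax and arg-max (ties to background) give the
mask.

**Stage 2** is a multi-view 3D network. Three independent lightweight 2D
encoders — inverted-residual bottleneck stacks (1x1 expansion, 3x3
depthwise convolution, linear 1x1 projection, shortcut when geometry
permits) with an interleaved residual block — process every axial, sagittal
and coronal slice of the two-channel input (normalized CT plus the stage-1
mask). Per-slice feature maps are restacked along their slicing axis,
trilinearly resampled to a common grid at 1/8 of the input extents, and
concatenated channel-wise in fixed order (axial, sagittal, coronal). The 3D
decoder upsamples by 2 three times; at the 1/4 and 1/2 scales it
concatenates fused skips recomputed from the encoders' intermediate
(stride-4 and stride-2) taps. A 1x1x1 convolution yields per-voxel class
logits, and predicted labels are zeroed outside the stage-1 mask — the
cascade contract.

## Preprocessing and augmentation

Volumes are reoriented to a single canonical convention (array axes run
superior-to-inferior, anterior-to-posterior, left-to-right; a pure
permutation/flip, never interpolation), Gaussian-smoothed with a physical
sigma (default 0.75 mm, converted per axis through the voxel spacing),
clamped to [-1000, 800] HU (air through dense bone), resampled to the
working grid (linear for images, nearest-neighbour for labels — label sets
can only shrink), and normalized. Four normalization modes are supported:
clamped HU passed through unchanged, per-volume zero-mean/unit-variance,
and affine maps of the fixed clamp window onto [0,1] or [-1,1]. The range
modes deliberately use the fixed clamp bounds rather than per-volume
extremes so the mapping is identical across volumes. All modes are
monotone.

Augmentation draws one parameter set per sample — in-plane rotation
(default +/-10 degrees), in-plane zoom (default 0.9--1.1), left--right
mirror flip, each applied with probability 0.5 — and applies the identical
geometric transform to image (linear interpolation) and labels
(nearest-neighbour). Rotation and zoom are composed into a single
resampling pass. Only left--right flips are enabled by default;
superior--inferior inversion is anatomically impossible.

## Training machinery and its numerical choices

Every layer implements an explicit backward pass; the test-suite verifies
each one (and both assembled networks) against central finite differences.
Key choices:

* **Channel normalisation** is deliberately asymmetric between the stages.
  Where used, it computes per-sample statistics identically in training and
  evaluation (instance-style): training is batch-free (mini-batches are
  formed by gradient accumulation), so per-sample statistics keep
  evaluation on exactly the distribution training saw; its scale and shift
  parameters are trainable and counted in parameter totals. The stage-2
  recognition network uses it after every convolution. The stage-1
  segmentation network is **normalisation-free by default**
  (`seg_model_config(norm = FALSE)`): CT intensities are calibrated, and
  per-slice normalisation makes the network blind to absolute intensity —
  on spine-free slices it rescales soft tissue into the intensity range
  that bone occupies on spine slices, and the model then hallucinates
  foreground on empty slices (observed as ~0.6 volume Dice from
  background-slice false positives alone, on training as well as test
  volumes, while every spine-bearing slice was segmented perfectly).
  Removing the data-dependent normalisation restored error-free background
  slices. Stage 2 is immune because its mask input channel anchors the
  prediction; there the normalisation helps train the deeper mobile
  encoder stack.
* **Loss** is `0.5 * (1 - soft Dice) + 0.5 * cross-entropy` on class
  probabilities. For recognition, the cross-entropy term supports
  inverse-frequency class weights (`class_weights = "balanced"`): each
  vertebra occupies well under 1% of the voxels, and without weighting the
  model collapses to all-background.
* **Optimizer** is Adam at an initial learning rate of 0.001 (the reference
  default) with reduce-on-plateau decay (factor 0.5 after 10 epochs without
  validation improvement). The best-validation parameters are restored
  after training.
* **Determinism**: all randomness flows through R's RNG from a single seed;
  convolutions are single-threaded compiled code; repeating a run
  bit-reproduces histories, weights and metric tables.
* **Degenerate inputs**: zero-variance volumes map to all zeros under
  zero-mean normalization; empty-vs-empty masks score Dice 1 (a vacuously
  perfect prediction); probability ties in arg-max resolve to the lower
  class index, so background wins exact ties.

## The synthetic phantom cohort

Real vertebra-challenge data (HU volumes with per-voxel masks and
per-vertebra centroids) cannot ship with the package, so a seeded generator
emulates that annotation structure: a soft-tissue elliptical torso (40 HU)
in air (-1000 HU) holding a cranio-caudal stack of ellipsoidal bodies
(700 HU, in-plane radius 8--12 mm, axial half-height 0.55 of the radius,
disc gaps 3--5 mm) on a centreline bowed by half a sine wave (amplitude
6 mm), plus Gaussian noise (sd 25 HU). Labels number the bodies superior to
inferior; centroids are exact label-mass centres in world millimetres. Bone
occupies a realistic 1--20% of the torso volume. Defaults: 64 x 96 x 96
voxels at 2 mm.

What the phantoms deliberately do *not* model: posterior elements (an
optional flag is out of scope by default), anatomically shaped bodies,
fractures, implants, field-of-view crops, scanner artefacts. Passing the
phantom study therefore demonstrates that the architecture, losses,
training loop and cascade wiring work end to end — it does not certify
performance on clinical CT, where contrast is lower and morphology far more
variable.

## The scaled-down study (`run_phantom_study()`)

The study generates 25 phantoms, splits them 80/20 at volume level (20
train / 5 test; per-volume splitting avoids slice leakage), then:

* **Stage 1** trains the reduced configuration (base width 8, depth 2,
  dropout 0.3, ~45k parameters) on sagittal slices at the native 96 x 96
  in-plane grid (the spine is contiguous in the sagittal plane, which is
  why that plane is the default): every slice containing spine plus half
  as many background slices, capped at 10 per volume, with augmentation
  on, 8 epochs, batch 2. Test metric: binary Dice over each full test
  volume.
* **Stage 2** trains the reduced multi-view network (~48k parameters) on a
  32^3 working grid with ground-truth mask unions as the second channel,
  balanced class weights, 8 epochs, batch 1. Test metric: the honest
  cascade — stage-1 predicted masks, resampled to the recognition grid,
  gate the recognition output — scored as macro Dice over the vertebra
  classes present in the truth.
* Both stages use an initial learning rate of 3e-3 in the study. The
  reference default (0.001) is tuned for long (150-epoch) full-scale runs;
  with roughly a hundredth as many optimizer steps, the larger step size is
  needed for the compressed schedule to converge at all — at 0.001 the
  reduced networks were still far from convergence when the epoch budget
  ran out.
* Metrics are computed on each stage's working grid, matching the practice
  of evaluating at the resized working resolution. Resampling predictions
  back to the native grid first was measured to cap macro Dice at 0.77-0.88
  purely from the label down/up-sampling round trip, which would conflate
  grid quantisation with model quality.

Problem sizes throughout (25 phantoms, 8/8 epochs, 32^3 recognition grid,
up to 10 slices per volume) were chosen so the whole study runs in minutes
on one CPU core while leaving clear headroom over the pass criteria.

## Macro averaging and reporting

Per-class metrics are one-vs-rest Dice/IoU/precision/recall; the macro row
averages over classes present in the ground truth, since per-scan vertebra
subsets vary in real cohorts. A class absent from both truth and prediction
scores 1 and is flagged absent (excluded from the macro mean). Reports are
written as CSV (per scan and class, percentages to two decimals) plus a
JSON summary of macro means.

## Known limitations

* Phantom realism, as above; no claim transfers to clinical CT without
  retraining at full scale.
* Stage-1 slicing is 2D; severe scoliosis that breaks sagittal contiguity
  would favour a different plane or a 3D first stage.
* The recognition working grid bounds achievable boundary precision; the
  reference pipeline exists precisely to be retrained at higher resolution
  and width (the reference configurations stay within the published
  two-stage parameter budget: 738,162 + 171,445 = 909,607 trainable
  parameters).
* Exact vertebra counting is implicit: the network has no explicit ordering
  head, so labellings that skip or merge a vertebra are penalised only
  through the voxel loss.
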