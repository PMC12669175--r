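---
title: "Multi-scale multi-scan state-space segmentation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale multi-scan state-space segmentation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmseg)
```

# The problem

Leptomeningeal lesions on contrast-enhanced T1 brain MRI are small, bright,
and sparse: the foreground typically occupies well under 5% of the brain,
the voxels are strongly anisotropic (sub-millimetre in plane, several
millimetres between slices), and cohorts of rare-disease patients are
necessarily pooled across scanners and years, so intensity distributions
differ systematically between subjects. `msmseg` implements a complete
pipeline for this regime: intensity harmonization, an encoder–decoder
segmentation network whose long-range modeling is done by selective
state-space scans over a multi-scale multi-scan serialization of the
volume, a combined Dice/cross-entropy training objective with deep
supervision, and spacing-aware evaluation metrics.

Axis convention throughout: axis order (x, y, z), shapes written
(nx, ny, nz), 0-based voxel indices in prose, spacing in mm per voxel.

# Harmonization

Each image $I$ is smoothed with Gaussian kernels of standard deviations
$\sigma_k \in \{0, 2, 4, 6\}$ voxels ($\sigma_0 = 0$ keeps the original
image). Every smoothed image is z-scored and mapped onto the moments of the
correspondingly smoothed reference scan,
$$\tilde I^{(k)} = \frac{I^{(k)} - \mu^{(k)}}{\sigma^{(k)}}\,
  \sigma^{(k)}_{\mathrm{ref}} + \mu^{(k)}_{\mathrm{ref}},$$
and the harmonized image is $\sum_k \tilde I^{(k)}$. By construction every
summand matches the reference mean and sd exactly at its scale, which is
the property the tests assert.

Choices a user should know about:

* **Sigmas are voxel units of the resampled grid.** Harmonization is meant
  to run after geometric standardization, so equal sigmas mean equal
  physical smoothing in plane. On the thick-slice axis the same sigma spans
  much more tissue; this mirrors applying the filter to the standardized
  grid rather than to physical space.
* **Statistics are whole-grid by default** (`stats_scope = "grid"`), with a
  `"nonzero"` option for skull-stripped scans where background zeros would
  dilute the moments. Whether brain-only statistics are preferable is a
  data-quality question the package leaves to the caller; the flag records
  the decision in the harmonization spec.
* **A constant image at a scale where the reference has variance is an
  error**, not a NaN: a clinical scan with zero variance is a data failure
  that should stop a pipeline, and silently propagating NaNs through a
  cohort average is worse than halting.
* **Smoothing reflects at the boundary.** Zero padding would darken the
  image rim at coarse scales and bleed that darkening into the matched
  moments; reflection keeps constants constant and preserves total
  intensity for interior-supported signals.
* The reference scan is an explicit argument. Picking it is a quality
  judgement (in practice, visual inspection); the package does not try to
  automate it.

Geometric standardization is conventional: trilinear resampling to a target
spacing (nearest-neighbour for label volumes, so the label alphabet
survives), in-plane cropping to the nonzero bounding box, and symmetric
zero-padding to a fixed shape with the odd voxel going to the high-index
side — a fixed, documented tie-break rather than an implicit one. An
all-zero volume keeps its full extent when cropping: total data loss is a
worse outcome than a no-op crop.

# The state-space core

The continuous system $h'(t) = A h(t) + B x(t)$, $y(t) = C h(t)$ is
discretized with the bilinear transform
$$\bar A = (I - \tfrac{\Delta}{2}A)^{-1}(I + \tfrac{\Delta}{2}A), \qquad
  \bar B = (I - \tfrac{\Delta}{2}A)^{-1}\Delta B, \qquad \bar C = C,$$
run either as the recurrence $h[n] = \bar A h[n-1] + \bar B x[n]$ (zero
initial state) or as the causal convolution with kernel
$\bar K[j] = \bar C \bar A^{j} \bar B$. The two routes are algebraically
identical; the package keeps both and the test suite checks their agreement
to $10^{-8}$ on randomized stable systems, which is a strong end-to-end
check on the discretization code.

The selective scan makes $B$, $C$ and $\Delta$ functions of each token:
$B_n = W_B x_n$, $C_n = W_C x_n$,
$\Delta_n = \mathrm{softplus}(w_\Delta^\top x_n + b_\Delta)$, with a shared
diagonal transition $a$. Decisions taken where the formulation leaves
freedom:

* **Softplus step-size activation.** $\Delta$ must be strictly positive for
  the bilinear step to be well posed; softplus is the standard smooth
  positive parameterization and its bias initializes $\Delta \approx 0.1$.
* **Real diagonal $A$ with negative initialization** $a = -(1, \dots, N)$.
  Diagonal state spaces are the established efficient form, make the
  bilinear inverse elementwise, and negative real parts keep the
  discretized system stable at initialization. Complex state spaces are out
  of scope.
* **Sequential-equivalent semantics.** The recurrence definition, not any
  particular execution strategy, is the contract: the compiled kernel must
  (and does) match a naive loop that re-discretizes at every token to
  $10^{-6}$.
* Zero initial hidden state, consistent with the convolutional expansion.

The scan and its full backward pass are the package's two compiled kernels
(plus the depthwise convolution); everything else is plain R, and the
backward pass is verified against central finite differences through the
entire assembled network.

# Multi-scale multi-scan serialization

A grid is partitioned into $N = 4$ segments per axis, giving $4^3 = 64$
basic elements. Choosing an odd or even block-index parity per axis yields
8 sub-volumes that partition the elements; each sub-volume holds
$(N/2)^3 = 8$ of them. Within a sub-volume the elements are numbered
x-fastest, then y, then z (1-based); each sub-volume is flattened by its
own canonical traversal order:

```{r}
build_scan_plan(4, c(64, 64, 12))
```

The orders are axis-priority scans (x-, y- and z-fastest), their full
reversals, and an in-plane snake with its reversal — eight unidirectional
scans whose starting elements cover all eight parity octants, so the
sequences are complementary rather than redundant. Multi-merge is the exact
inverse; the round trip is bit-identical and property-tested.

Interpretive decisions, recorded as such:

* **Element-level granularity.** The traversal orders permute whole basic
  elements; sequences concatenate element voxel blocks. Within an element,
  voxels follow an x-fastest raster whose direction follows the element
  order's sense (reversed sub-volumes reverse the whole sequence).
* **The numbering convention is chosen so the canonical orders *read* as
  axis-priority traversals**; with any other numbering the same tables
  would look arbitrary.
* **Divisibility by padding.** Deep layers have small extents, so grids are
  right-padded with zeros to the next multiple of $N$ before scanning and
  cropped after merging.
* **Dual branch and fusion.** The upper branch is scan → selective scan per
  sequence (shared parameters) → merge; the lower branch is a selective
  scan over the full-resolution x-fastest raster, preserving fine-grained
  order information. Fusion is an elementwise sum: parameter-free and
  shape-safe. Whether the lower branch should instead be a convolution is
  not determined by the formulation; a full-resolution scan keeps the whole
  module within one operator family.
* The full block is LayerNorm → module → residual → LayerNorm →
  convolutional feed-forward (pointwise expansion by ratio ER = 2, LeakyReLU,
  pointwise projection) → residual. The internal gating of published Mamba
  blocks is deliberately not reproduced: it is not constrained by the
  formulation implemented here, and the scan-SSM-merge path is the part
  with testable semantics.

# The network

Six encoder layers (channels 2 → 32 → 64 → 128 → 256 → 320 → 320 by
default) each run conv block → MSMS block → strided conv block; the strided
depthwise-separable convolution is the down-sampling operator. Kernels are
(3,3,1) and strides (·,·,1) in the three shallow layers — no z
down-sampling until features are nearly isotropic, mirroring the
thick-slice geometry — and (3,3,3)/(2,2,2) deeper. Decoder layers upsample
with transposed convolutions (kernel = stride = the matching encoder
stride, so each decoder layer restores its encoder layer's resolution),
concatenate the skip, and apply a conv block. The conv block is depthwise
conv → pointwise 1×1×1 → instance norm (ε = 1e-5) → LeakyReLU (slope 0.01).
The segmentation head is a pointwise convolution; deep-supervision heads
sit at every deeper decoder layer.

Two wiring choices deserve a note. First, the head is pointwise because
voxel-wise classification requires a resolution-preserving map. Second,
where the stated decoder strides for the shallow layers would not restore
resolution, the up-sampling factor is taken from the matching encoder
stride; this is an interpretation (the alternative reading leaves the
decoder unable to reach full resolution) and is flagged as such rather than
presented as fact.

The head biases initialize to favor the background class
(logits +3 / −3): with foreground below 1% of voxels, a symmetric start
wastes the first epochs re-learning the trivial all-background prediction,
and the class-prior start removes exactly that phase without touching the
objective.

# Objective and training

The loss is $\tfrac12 \mathcal L_{CE} + \tfrac12 \mathcal L_{Dice}$, with
$$\mathcal L_{Dice} = 1 - \frac{2\sum_i p_i y_i + \epsilon}
  {\sum_i p_i + \sum_i y_i + \epsilon}, \qquad \epsilon = 10^{-6},$$
computed over the foreground class only — with extreme imbalance a
background Dice is saturated and uninformative. Cross-entropy probabilities
are clamped to $[10^{-7}, 1 - 10^{-7}]$ because the raw expression is
unbounded at the ends. Deep supervision weights the level-$i$ loss by
$1/2^i$, normalized to sum to one so ablating levels does not rescale the
objective; auxiliary targets are nearest-neighbour down-sampled so labels
stay binary. Training uses AdamW (weight decay 0.05), cosine decay from
lr = 0.001 reaching zero at the final epoch, per-subject z-scoring, and
k-fold cross-validation with a pretrain → fine-tune path (a checkpoint can
seed a fresh schedule). All randomness flows from the recorded seed; a
non-finite loss aborts with diagnostics instead of training through NaNs.

# The phantom generator

The generator emulates the features of the target regime that the method's
correctness actually depends on:

* the study geometry — (64, 64, 12) voxels at 0.47 × 0.47 × 6.5 mm by
  default, the spacing of the clinical protocol it mirrors;
* an ellipsoidal "brain" support carrying smooth random tissue texture
  (amplitude 0.1 of the base intensity);
* a small number of bright ellipsoidal lesions (radius 2–4 mm, contrast
  ×1.8) placed **near the support boundary**, the leptomeningeal pattern;
  lesion centres snap to slice centres in z so a 2 mm lesion is never lost
  between 6.5 mm slices;
* heavy class imbalance — foreground fractions land around 0.5%, well
  inside the < 5% regime, and this is asserted across seeds;
* per-"scanner" affine intensity shifts (four default profiles with
  distinct gain/offset/noise) so harmonization has genuine between-scanner
  variation to remove, plus additive Gaussian noise (sd 0.05);
* an optional bright boundary stripe, a distractor reproducing the
  characteristic false-positive mode of bright non-lesion interfaces.

Everything is driven by one seeded generator per phantom, so identical
specs are bit-identical across runs. What the phantoms do **not** model:
MRI physics (bias fields, k-space artifacts, partial-volume blur), skull
and extracranial tissue, non-ellipsoidal lesion shapes, or realistic
texture spectra. Passing the end-to-end tests therefore demonstrates that
the pipeline is correctly assembled and trainable in the intended regime —
not that clinical-grade accuracy transfers to real scans, which would need
the full-scale transfer-learning protocol on real data that is outside
this package's desk-scale scope.

# Metrics

Confusion-count ratios (Dice, sensitivity, specificity, balanced accuracy,
accuracy, Jaccard, Cohen's kappa, volumetric similarity, Matthews
correlation) use double-precision counts (marginal products overflow
32-bit integers at whole-volume scale) and fixed degenerate-case
conventions so cohort averages are always defined: Dice/Jaccard/VS are 1
when both masks are empty and 0 when exactly one is; kappa and MCC return 0
when a marginal is degenerate. HD95 is the symmetric 95th percentile
(linear interpolation over the sorted directed distances) of
boundary-to-boundary nearest distances in mm, where a boundary voxel is
foreground with at least one face-adjacent background neighbour (grid edges
count as background); it is 0 when both masks are empty and NA when exactly
one is, since no finite distance is meaningful there. Per-subject metrics
are reported as mean ± sd across subjects.

# Problem sizes and numerical checks

The test suite and the acceptance script deliberately run at desk scale,
chosen so the full suite completes in minutes on one CPU while still
exercising every code path at realistic shapes: serialization is
property-tested on 200 random grids up to 16³ with up to 8 channels; the
dual-route state-space equivalence on 100 random stable systems with
sequences up to length 64; the selective scan against a naive per-token
re-discretization loop on 50 random cases; network backpropagation against
central finite differences on a two-layer network (the check covers the
compiled scan backward, all normalizations, both convolution types and the
loss); and the end-to-end run trains a two-layer, 8/16-channel network on
an 8-phantom cohort (6 train / 2 held out) for 18 epochs at lr 5e-3 over
five seeds, reaching held-out Dice ≈ 0.85–0.93. The reference six-layer
architecture is built and run at reduced input size to verify the channel
chain, resolution restoration and auxiliary-head stack.

# Known limitations

* The training loop is CPU-bound R + small compiled kernels; it is meant
  for method study and desk-scale experiments, not for full-resolution
  clinical training runs.
* Only binary segmentation is exercised; multi-class heads exist
  structurally but the Dice objective is foreground-only by design.
* Transposed convolutions are restricted to kernel = stride
  (non-overlapping phases); this matches the architecture here but is not
  a general deconvolution.
* Skull stripping, bias-field correction and registration are out of
  scope; inputs are assumed skull-free (the phantoms are generated that
  way).
* The checkpoint format is an RDS archive of the specification plus
  parameter values — simple and faithful, but not interoperable with other
  frameworks.
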