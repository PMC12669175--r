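# msmseg

Voxel-wise segmentation of small bright lesions in anisotropic 3-D brain
MRI, built around a selective state-space sequence model with a
**multi-scale multi-scan (MSMS)** serialization of the volume. The package
targets the regime of contrast-enhanced T1 imaging of rare
neurovascular disease: thin in-plane voxels and thick slices, lesions
occupying well under 5% of the brain, and scans pooled across scanners
with incompatible intensity distributions. Everything is exercisable on
reproducible synthetic lesion phantoms, so no clinical data are needed to
develop against or to test the method end to end.

It is aimed at methods researchers in medical image analysis who want a
fully inspectable, CPU-scale reference implementation of Mamba-style
sequence modeling for 3-D segmentation — every layer, gradient and metric
is ordinary R (with two small compiled kernels), not a framework call.

## The method

**State-space core.** A linear state-space model maps a sequence x through
a hidden state h by h'(t) = A h(t) + B x(t), y(t) = C h(t). It is
discretized with the bilinear transform,

    Ā = (I − Δ/2·A)⁻¹ (I + Δ/2·A),   B̄ = (I − Δ/2·A)⁻¹ Δ B,   C̄ = C,

giving the recurrence h[n] = Ā h[n−1] + B̄ x[n], y[n] = C̄ h[n], or
equivalently the causal convolution with kernel K̄ = (C̄B̄, C̄ĀB̄, C̄Ā²B̄, …).
The selective (Mamba-style) variant makes B, C and the step size Δ linear
projections of each token, with Δ kept positive through a softplus and a
shared diagonal A with negative real parts; the package implements both
routes and tests them against each other.

**MSMS serialization.** A feature volume is partitioned into N segments per
axis (N = 4, so 64 basic elements). Picking an odd/even block-index parity
per axis yields 8 sub-volumes that partition the volume; each sub-volume's
8 elements are flattened into a 1-D sequence by its own canonical traversal
order (axis-priority scans, their reversals, and in-plane snakes), the
selective scan runs on each sequence, and the exact inverse (multi-merge)
reassembles the volume. A parallel full-resolution raster-scan branch is
summed in, preserving fine-grained detail. The block wraps this module in
layer norms, residual paths and a convolutional feed-forward network.

**Network.** A U-Net-style encoder–decoder whose encoder layers are
conv → MSMS block → strided conv (depthwise-separable 3-D convolutions with
instance norm and LeakyReLU; no z-downsampling in the shallow layers, so the
thick-slice geometry is respected), with transposed-convolution upsampling,
skip connections, and deep supervision with 1/2^i level weights. The loss is
½·cross-entropy + ½·foreground Dice; training uses AdamW (weight decay
0.05) with cosine learning-rate decay from 0.001.

**Harmonization.** Images from different scanners are aligned to a reference
scan by multi-scale moment matching: for Gaussian scales σ ∈ {0, 2, 4, 6}
(voxels), each smoothed image is z-scored and mapped onto the smoothed
reference's mean and sd, and the per-scale images are summed.

**Evaluation.** Dice, sensitivity, specificity, balanced accuracy, accuracy,
Jaccard, Cohen's kappa, volumetric similarity, Matthews correlation, and the
spacing-aware 95th-percentile Hausdorff distance in mm.

## Worked example

```r
library(msmseg)

plan <- build_scan_plan(n_segments = 4, spatial_shape = c(64, 64, 12))
plan
#> <scan_plan> N = 4: 64 basic elements, 8 sub-volumes of 8
#>   SV1 (odd,odd,odd): [1, 2, 3, 4, 5, 6, 7, 8]
#>   SV2 (even,odd,odd): [8, 7, 6, 5, 4, 3, 2, 1]
#>   SV3 (odd,even,odd): [1, 3, 2, 4, 5, 7, 6, 8]
#>   SV4 (even,even,odd): [8, 6, 7, 5, 4, 2, 3, 1]
#>   SV5 (odd,odd,even): [1, 5, 2, 6, 3, 7, 4, 8]
#>   SV6 (even,odd,even): [8, 4, 7, 3, 6, 2, 5, 1]
#>   SV7 (odd,even,even): [1, 2, 4, 3, 5, 6, 8, 7]
#>   SV8 (even,even,even): [7, 8, 6, 5, 3, 4, 2, 1]

ph <- generate_phantom(phantom_spec(seed = 1))
ph$image
#> <msm_volume> 64 x 64 x 12 voxels, spacing 0.47 x 0.47 x 6.5 mm
#>   intensity range [-0.2271, 2.082]  (phantom seed 1)
mean(ph$mask$data != 0)          # foreground fraction: heavy imbalance
#> [1] 0.004760742

# score a deliberately degraded mask against the truth
pred <- ph$mask$data
pred[, , 1:6] <- 0               # drop everything in the lower slices
evaluate_masks(pred, ph$mask$data, spacing = ph$image$spacing)
#> <metrics_report>
#>   dice  0.5511
#>   sen   0.3803
#>   spe   1.0000
#>   bacc  0.6902
#>   acc   0.9970
#>   ji    0.3803
#>   kappa 0.5499
#>   vs    0.5511
#>   mcc   0.6158
#>   hd95  20.1356
```

Half the lesion voxels are gone, so Dice and sensitivity drop while
specificity and accuracy stay near 1 — the signature of a severely
imbalanced task, and the reason Dice (not accuracy) is the primary metric.
The Hausdorff distance is large because the surviving and removed lesions
sit several thick slices apart.

Training end to end (a two-layer, reduced-width network learns the phantom
task to a held-out Dice around 0.9 in a few minutes on one CPU):

```r
cohort <- generate_cohort(8, phantom_spec(seed = 100))
spec <- network_spec(channels = c(8, 16),
                     strides = list(c(2, 2, 1), c(2, 2, 1)),
                     kernels = list(c(3, 3, 1), c(3, 3, 1)),
                     in_channels = 1, d_state = 4)
net <- build_network(spec, seed = 1)
data <- lapply(cohort[1:6], function(s) list(image = s$image, mask = s$mask))
val  <- lapply(cohort[7:8], function(s) list(image = s$image, mask = s$mask))
res <- run_training(net, data,
                    train_config(epochs = 18, lr = 5e-3, batch_size = 1,
                                 seed = 1),
                    val_data = val)
tail(res$log, 1)
```

## Command line

A thin wrapper over the same functions lives in `inst/cli/msmseg`:

```sh
msmseg generate   --n 8 --out data/ --seed 7
msmseg preprocess --in scan.nii.gz --out pp.nii.gz --target-spacing 0.47,0.47,6.5 --pad 320,320,-1
msmseg harmonize  --reference ref.nii.gz --in pp.nii.gz --out harm.nii.gz --sigmas 0,2,4,6
msmseg train      --config cfg.yaml --data data/ --out run/
msmseg predict    --model run/checkpoint.rds --in harm.nii.gz --out labels.nii.gz
msmseg evaluate   --pred preds/ --truth truths/ --out metrics.csv
```

Every sub-command writes a JSON run manifest (config snapshot, package
version, seed, input digests, timestamps) next to its output.

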