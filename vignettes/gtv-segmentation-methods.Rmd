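---
title: "Methods: a 2.5D residual-SE U-Net with a transformer bottleneck for thick-slice CT target segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2.5D residual-SE U-Net with a transformer bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

Radiotherapy planning CT is usually acquired with a slice thickness several
times the in-plane pixel spacing (here about 5 mm slices against ~1 mm
pixels). A gross target volume (GTV) outlined on such a volume therefore has
sharp, information-rich edges *within* each slice but coarse, partial
structure *across* slices. `gtvseg` implements a volumetric encoder-decoder
segmentation network built around that asymmetry, together with its full
training protocol, evaluation metrics, and a synthetic phantom study that
exercises everything on one CPU.

## Network architecture

The network is a five-stage U-Net: an encoder extracting progressively
deeper features, a decoder restoring resolution with transpose convolutions,
skip connections concatenating encoder features into the decoder at every
stage, and a 1x1x1 convolution + softmax head producing per-voxel
probabilities for the background and target classes.

Three ideas distinguish the full model (`transresseunet25d`) from a plain 3D
U-Net:

1. **2.5D stages.** In stages 1 and 2 every convolution kernel (and stride)
   has extent 1 along the slice axis, so those stages learn purely in-plane
   edge features; stages 3-5 use full 3D kernels to integrate inter-slice
   context at reduced resolution. Rationale: at 5:1 anisotropy,
   through-plane kernels at full resolution mostly see partial-volume blur.
2. **Residual squeeze-and-excitation (Res-SE) blocks.** Each feature block
   is `conv -> BN -> LeakyReLU -> conv -> BN -> SE -> (+skip) -> LeakyReLU`.
   Block-A changes resolution/channels (its first convolution carries the
   stride and channel change; the skip is a strided 1x1x1 projection with
   BN); Block-B is shape-preserving with an identity skip. The SE gate
   global-average-pools each channel, passes the channel vector through a
   bottleneck MLP with reduction ratio r = 4, and sigmoid-scales each
   channel. All activations are LeakyReLU with slope 0.01; one BN sits
   between every convolution and its activation.
3. **Residual transformer bottleneck.** Stage 5 first applies a Block-A
   (stride 2, channels to C2 = 256), then serializes the C2 x D2 x H2 x W2
   map into P = D2*H2*W2 tokens: a 1x1x1 convolution lifts channels to
   C3 = 512 and the spatial axes are flattened in a fixed raster order
   (depth fastest, then height, then width). A learnable position embedding
   is added (`z0 = f + PE`), then M = 4 pre-norm transformer layers:

   `z*_m = MSA(LN(z_{m-1})) + z_{m-1}`, `z_m = MLP(LN(z*_m)) + z*_m`

   with H = 8 heads (head dimension C3/H), scaled dot-product attention
   (scale `1/sqrt(C3/H)`) and an MLP of hidden width h = 4096. The tokens
   are unflattened in the same raster order, mapped back to C2 channels by a
   1x1x1 convolution, and added to the bottleneck input as a residual.

At the reference patch of 32 x 256 x 256 with per-stage channels
(16, 32, 64, 128, 256) and strides ((1,1,1), (1,2,2), (2,2,2), (2,2,2),
(2,2,2)), the bottleneck is 4 x 16 x 16, i.e. P = 1024 tokens.

Five comparison variants are built by the same factory: `unet3d` (plain
double-conv blocks everywhere), `resseunet3d` (Res-SE blocks, all 3D),
`resseunet25d` (Res-SE with 2D stages 1-2), and the baselines `unet2d` /
`unet25d`. The last two appear in the comparison literature only by name;
this package reconstructs them explicitly: `unet2d` uses 2D-mode plain
blocks in all five stages (so depth resolution is never reduced), `unet25d`
uses plain blocks with 2D stages 1-2 and 3D stages 3-5. These
reconstructions are declared design choices, not inferences.

### Design choices where the design was genuinely open

* **Block internals.** The exact residual layout is fixed as
  `conv-BN-LReLU-conv-BN-SE-(+skip)-LReLU`, the standard residual-SE
  ordering consistent with "SE after the second BN". The Block-A skip is a
  projection because shapes differ; Block-B keeps an identity skip.
* **Block-A channel direction.** Written descriptions of Block-A disagree
  on whether it decreases or increases channels; the implementation treats
  it as "changes channels per configuration", which covers both readings.
* **Decoder stages.** Each decoder stage is: transpose convolution (kernel
  = stride, so upsampling is exact and cheap), concatenation with the
  encoder skip, a 1x1x1 fusion convolution restoring the stage channel
  count, then one Block-B (plain variants use two conv modules, mirroring
  their encoder). Whether the original decoder used one or two modules per
  stage is unstated; one Block-B was chosen to keep parameter counts close
  to the encoder.
* **Transformer MLP.** "Three-layer perceptron with an implicit layer h" is
  read as input -> hidden(h) -> output (two weight matrices). Its
  activation is LeakyReLU(0.01) for consistency with the rest of the
  network (the source is silent). LN normalizes each token over channels,
  eps 1e-5. PE is initialized from N(0, 0.02^2) ("learnable" is all that is
  specified) and its token count is fixed at configuration time.
* **Minimum width 16 and r = 4.** The channel plan starts at 16 = 64/4,
  which is also what makes the SE reduction r = 16/4 = 4 consistent.

## Preprocessing and augmentation

CT volumes in HU are windowed with the soft-tissue window (width 400, level
40): `out = clip((hu - (level - width/2))/width, 0, 1) * 255`, then divided
by 255. Whether windowed images are further rescaled before the network is
an open question in the source; mapping to [0, 1] is this package's
convention (and the padding value 0 then corresponds to air).

Training samples are random crops of the configured patch; validation crops
are deterministic, centered on the GTV centroid (voxel indices rounded
toward zero, offsets clamped into the padded volume). Augmentation magnitudes
are not stated in the source, so the defaults are declared here: mirror
probability 0.5 per axis, in-plane rotation up to ±15°, isotropic in-plane
scale in [0.9, 1.1], translation up to ±10% per axis, Gaussian intensity
noise with sd 0.02 (normalized units). Rotation is restricted to the slice
plane — at 5 mm slices a through-plane rotation resamples across
partial-volume gaps and destroys the label geometry — and depth translation
is rounded to whole slices for the same reason. Geometric transforms use
linear interpolation for the image and nearest-neighbor for the mask, so
masks stay exactly binary.

## Training protocol

The loss is the sum of a soft multi-class Dice loss
(`1 - mean_c (2*sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)`,
eps = 1e-5) and the mean voxelwise cross-entropy. The optimizer is Adam
(initial learning rate 1e-3, weight decay 1e-4, coupled L2 as classically
defined) with a polynomial schedule `lr0 * (1 - epoch/epochs)^0.9` applied
per epoch. Batch size is 4; one random crop per case per epoch
(configurable). After every epoch the mean validation DSC is computed on
the GTV-centered crops with hardened (argmax) predictions and frozen BN
statistics; the model is checkpointed whenever this DSC *strictly* exceeds
every previous epoch. Training aborts with a diagnostic naming the epoch
and batch if the loss becomes non-finite.

Full-volume inference tiles the volume with the training patch at 50%
overlap (final tile clamped to the edge), averages softmax probabilities
over the windows covering each voxel, and thresholds the target probability
at 0.5 (ties to background; with two classes this equals argmax).

## Evaluation metrics

* **DSC** `= 2|A ∩ B| / (|A| + |B|)` on whole volumes. Both masks empty is
  an explicit error (0/0); exactly one empty gives 0.
* **HD95** `= 0.5 * [P95_{z in S_B} d(z, S_A) + P95_{z in S_A} d(z, S_B)]`
  in mm. Surfaces are foreground voxels with a background 6-neighbor
  (out-of-bounds counts as background); distances are voxel center to voxel
  center using the anisotropic spacing; the percentile interpolates
  linearly between order statistics (R type 7). Conventions differ between
  toolkits on all three points, which is why they are pinned here, and why
  the tests verify the implementation against an O(n^2) brute-force oracle
  to 1e-9 mm. Units are mm (spacing-aware) since results in this field are
  reported in mm.

## The phantom generator

The generator emulates the data regime the method targets: anisotropic
volumes with spacing (5, 1, 1) mm (slice thickness ≈ 5x pixel spacing), a
single soft-tissue lesion (40 HU) on an air-like background (-800 HU),
additive Gaussian noise (20 HU), and a binary label that is exactly the
analytic lesion support at voxel centers — no partial-volume antialiasing,
so every mask voxel is checkable against the ellipsoid inequality.
Lobulated lesions are unions of jittered ellipsoids (each lobe covers the
nominal center, so the union is connected). One master seed spawns named
child streams (geometry, noise, per-case), so changing the noise level
never moves a lesion and any case can be regenerated in isolation.

What the phantoms deliberately do **not** model: lung anatomy (airways,
vessels, pleura), intensity texture, respiratory motion, inter-observer
contour variability, and multi-focal disease. Passing the phantom study
shows the architecture, losses, protocol and metrics are implemented
correctly and can fit a volumetric target at high contrast; it says nothing
about clinical-grade accuracy, which requires the clinical cohorts and
GPU-scale training outside this package's scope.

## Problem sizes used in tests and the acceptance run

The reference configuration (patch 32 x 256 x 256, channels 16-256, M = 4,
H = 8, h = 4096, 500 epochs) is far beyond a CPU test run, so the shipped
experiments use a scaled-down profile chosen once: patch 16 x 64 x 64,
channels (8, 16, 32, 64, 128), transformer M = 2, H = 4, h = 256, C3 = 128;
phantoms of 24 x 80 x 80 voxels at (5, 1, 1) mm with lesion semiaxes
(12, 16, 16) mm jittered per case; 20 training / 4 validation / 4 test
cases; batch 4; 12-15 epochs. Under these conditions the full model reaches
validation DSC ≥ 0.85 well within 30 epochs, and each variant can overfit a
single phantom crop to DSC ≥ 0.95 in under 200 Adam steps. Unit tests use
an even smaller five-stage configuration (channels 4-16, patch 8 x 32 x 32)
whose whole-network backward pass is verified against central finite
differences.

## Numerical notes

* Convolutions are computed by im2col + GEMM in single precision (the
  unfolded patch matrix dominates memory traffic; activations and gradients
  stay well inside float range), with double precision elsewhere
  (batch-norm statistics, losses, Adam state). The whole-network
  finite-difference check passes at 5% relative tolerance, consistent with
  the mixed precision.
* Strided convolutions require even extents along strided axes and error
  with the offending axis name; this keeps every stage's shape arithmetic
  exact (no ceil/floor ambiguity).
* Batch normalization uses biased batch variance for normalization,
  unbiased updates for the running estimates (momentum 0.1), and frozen
  running statistics in evaluation mode — validation is therefore exactly
  repeatable.
* Softmax subtracts the per-voxel maximum; cross-entropy clamps
  probabilities at 1e-12.
* The Adam weight decay is coupled (added to the raw gradient), the
  classical definition; a decoupled variant was considered and not adopted
  since the reference protocol predates that distinction.

## Known limitations

* No GPU path: the training engine is a CPU reference implementation meant
  for the phantom study and for verifying the method's structure, not for
  clinical-scale training.
* DICOM / RT-STRUCT parsing is out of scope; NIfTI is the interchange
  format.
* The bottleneck position embedding is tied to the configured patch size;
  sliding-window inference therefore uses the training patch.
* `unet2d` / `unet25d` are declared reconstructions (see above), suitable
  as baselines of the ablation, not as reimplementations of any specific
  external network.
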