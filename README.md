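# gtvseg

Automatic segmentation of a gross target volume (GTV) in thick-slice
radiotherapy CT, for medical-imaging researchers and methodologists who
need a fully inspectable, CPU-runnable reference implementation of a
2.5D residual squeeze-and-excitation U-Net with a transformer bottleneck —
including its training protocol, its evaluation metrics, and a synthetic
phantom study that exercises the entire pipeline without any clinical data.

## The method

Planning CT is strongly anisotropic (slice thickness ≈ 5× the in-plane
pixel spacing), so the network treats the two regimes differently:

* **Stages 1–2 (2.5D):** every convolution kernel and stride has extent 1
  along the slice axis — pure in-plane edge extraction.
* **Stages 3–5 (3D):** full 3D kernels integrate inter-slice context at
  reduced resolution.
* **Res-SE blocks:** `conv → BN → LeakyReLU(0.01) → conv → BN → SE →
  (+skip) → LeakyReLU`, with squeeze-and-excitation channel gating
  (reduction r = 4). Block-A changes resolution/channels via a strided
  first convolution and a projection skip; Block-B is shape-preserving.
* **Res-Dual-Attention bottleneck (stage 5):** after a Block-A downsample
  to C₂ = 256 channels, the D₂×H₂×W₂ feature map is serialized into
  P = D₂·H₂·W₂ tokens of width C₃ = 512, a learnable position embedding is
  added (z₀ = f + PE), and M = 4 pre-norm transformer layers are applied:

      z*ₘ = MSA(LN(zₘ₋₁)) + zₘ₋₁
      zₘ  = MLP(LN(z*ₘ)) + z*ₘ        (H = 8 heads, MLP hidden width h = 4096)

  then tokens are deserialized, mapped back to C₂ channels, and added to
  the bottleneck input as a residual.
* **Decoder:** transpose-convolution upsampling, skip concatenation, and a
  1×1×1 softmax head over {background, target}.

Training follows the reference protocol: summed soft Dice + cross-entropy
loss, Adam (lr 1e-3, weight decay 1e-4), polynomial decay
`lr₀·(1 − epoch/epochs)^0.9`, batch 4, random 32×256×256 crops for
training, GTV-centered crops for validation, and best-model checkpointing
on strict validation-DSC improvement. Evaluation uses the whole-volume
Dice similarity coefficient `DSC = 2|A∩B|/(|A|+|B|)` and the 95%
Hausdorff distance `HD95 = ½[P95 d(S_B→S_A) + P95 d(S_A→S_B)]` in mm with
anisotropic spacing.

Six architecture variants are available for ablation:
`unet2d`, `unet25d`, `unet3d`, `resseunet3d`, `resseunet25d`,
`transresseunet25d`.

All network layers (convolutions, batch norm, SE gates, multi-head
attention) are implemented in this package with explicit forward and
backward passes on an RcppArmadillo/BLAS core, so every computational step
of the method is visible and testable.

## Worked example

Train the full model on a seeded phantom study at the CPU-sized profile
and evaluate on held-out phantoms:

```r
library(gtvseg)

sp <- phantom_spec(shape_voxels = c(24, 80, 80), spacing_mm = c(5, 1, 1),
                   lesion_semiaxes_mm = c(12, 16, 16), noise_sd_hu = 20)
train <- generate_dataset(20, sp, seed = 11)
val   <- generate_dataset(4, sp, seed = 99)

cfg <- network_config("transresseunet25d",
                      stage_channels = c(8, 16, 32, 64, 128),
                      patch = c(16, 64, 64),
                      transformer = list(M = 2, H = 4, h = 256, c3 = 128))
net <- build_network(cfg, seed = 1)
tc  <- train_config(batch_size = 4, epochs = 12, patch = c(16, 64, 64), seed = 7)
th  <- train_network(net, train, val, tc)
th
#> <train_history> 12 epochs, best val DSC 0.9160 at epoch 11

tail(th$history[, c("epoch", "lr", "train_loss", "val_dsc")], 3)
#>    epoch           lr train_loss   val_dsc
#> 10    10 0.0002871746  0.8452006 0.9151502
#> 11    11 0.0001993719  0.8340288 0.9160372
#> 12    12 0.0001068407  0.8271043 0.9159496
```

The validation DSC is the mean hardened Dice over the four GTV-centered
validation crops; the loss column is the summed Dice + cross-entropy on
the augmented random training crops (some of which clip or miss the
lesion, so it sits well above the validation loss). A trained network
segments whole volumes by overlapping sliding windows:

```r
net_load_state(net, th$best_state)                  # best checkpoint
case <- generate_phantom(sp, 123)
vol  <- normalize_volume(window_ct(case$volume))    # HU -> 0-255 -> [0,1]
pred <- predict_volume(net, vol)
dsc(pred, case$mask)                                # whole-volume Dice
#> [1] 0.9129721
hd95(pred, case$mask)                               # mm, spacing-aware
#> [1] 2
```

On this phantom the whole-volume Dice is 0.913 and the HD95 is 2 mm —
the predicted surface sits within two in-plane voxels of the analytic
lesion surface nearly everywhere.

A thin command-line interface wraps the same functions
(`exec/gtvseg generate-phantoms | train | predict | evaluate |
compare-variants`), configured by a strict-schema YAML file
(see `load_config()`; ready-made profiles ship in `inst/configs/`:
`toy.yaml` for the CPU-sized study, `reference.yaml` for the full-scale
protocol).

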