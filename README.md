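# halfunet

Encoder–decoder networks for binary medical-image segmentation, built around
**Half-UNet**: a simplified U-Net that keeps the contracting
(divide-and-conquer) half of the architecture and collapses the expanding
half into a single full-scale additive fusion. The package is aimed at
people studying segmentation-network *efficiency* — it lets you build the
whole comparison family (U-Net, a UNet3+-style full-scale-aggregation
network, channel-doubling ablations, and Half-UNet with or without Ghost
modules), account for every parameter and FLOP analytically, and train any
of them on synthetic data on a plain CPU, with no deep-learning framework
and no external datasets.

## The architecture family

All networks share a five-scale encoder over square grayscale inputs. They
differ in channel policy and in how multi-scale features are fused:

* **U-Net** doubles channels after every 2×2 max-pool (64 → 1024) and
  decodes with 2×2 transposed convolutions, skip concatenation, and a
  double 3×3 convolution per scale.
* **UNet3+ (full-scale aggregation)** keeps the U-Net encoder but fuses all
  five encoder scales at each decoder layer: every tap is resampled to the
  layer's scale, unified to 64 channels by a 3×3 convolution, concatenated
  (5 × 64 = 320 channels) and fused by a 3×3 convolution.
* **Half-UNet** unifies all feature maps at 64 channels, bilinearly
  upsamples the five encoder outputs to full resolution and fuses them by
  **addition** — a fusion stage with *zero* learnable parameters and zero
  FLOPs under the accounting below — followed by two further blocks and a
  1×1 sigmoid head. Its convolutions are **Ghost modules**: half of the
  output maps come from a standard K×K convolution (the *intrinsic* maps)
  and the other half from a cheap 3×3 depthwise convolution applied to
  them.

Complexity is counted in closed form. For a K×K convolution with `Cin`
input channels, `Cout` output channels and an `H×W` output,

    params = (K² · Cin + 1) · Cout
    FLOPs  = 2 · K² · Cin · Cout · H · W

a Ghost module with ratio s = 2 costs

    params = [K² · (Cin + 1) + 2] · Cout / 2
    FLOPs  = 2 · K² · (Cin + 1) · (Cout / 2) · H · W

and a transposed convolution's FLOPs scale with its *input* size,
`2 · K² · Cin · Cout · Hin · Win`. Batchnorm contributes 2 parameters per
channel; bias, activation, pooling, interpolation and addition are costed
at zero FLOPs. Evaluation uses the Dice coefficient
`2|P∩M| / (|P|+|M|)`, sensitivity `TP/P` and specificity `TN/N`; training
minimizes a smoothed soft-Dice loss with Adam.

## Worked example

```r
library(halfunet)

net <- build_half_unet(arch_config(input_shape = c(1, 128, 128)))
count_network(net)
#> totals: 208,865 params (0.21 M), 2,268,569,600 FLOPs (2.27 G)
```

Half-UNet needs 0.21 M parameters; the baseline U-Net built by
`build_unet()` needs 31.04 M (148× more) and about 10.6× the FLOPs at
128×128. Splitting each network's final fusion stage shows where that goes:

```r
fusion_table(c(1, 128, 128))
#>     network  part  params       flops params_label flops_label
#> 1    UNet3+  left 1143744 37446746112       1.14 M     37.45 G
#> 2    UNet3+ right  922560 30198988800       0.92 M     30.20 G
#> 3     U-Net  left   32832   268435456       0.03 M      0.27 G
#> 4     U-Net right   73920  2415919104       0.07 M      2.42 G
#> 5 Half-UNet  left       0           0       0.00 M      0.00 G
#> 6 Half-UNet right   18912   613416960       0.02 M      0.61 G
```

The "left" part is the fusion itself (upsampling/deconvolution/unifying
convolutions plus the add or concat), the "right" part the first
convolution after it. Half-UNet's bilinear-add fusion is free, and its
post-fusion Ghost module costs 0.61 G FLOPs where the UNet3+-style
aggregation convolution costs 30.20 G.

Training end to end on synthetic data (a bright soft-edged mass on a noisy
background; masks are the exact generating geometry):

```r
cfg <- synthetic_config("mass", image_size = 64, n_images = 150, seed = 7)
man <- generate_dataset(cfg, "massds")
arr <- load_manifest_arrays(man, "train")
fit <- train_network(build_half_unet(arch_config(input_shape = c(1, 64, 64))),
                     arr$x, arr$y,
                     train_config(epochs = 8, batch_size = 14, seed = 11),
                     verbose = TRUE)
#> epoch   1  lr 0.00100  train loss 0.7642  val dice 0.5437
#> ...
#> epoch   8  lr 0.00100  train loss 0.3763  val dice 0.9839
evaluate_network(fit, manifest = man, split = "test")$aggregate
#>        dice sensitivity specificity
#>   0.9813147   0.9931804   0.9979535
```

A shell entry point wrapping the same functions lives at
`inst/cli/halfunet.R` (`generate`, `networks`, `summarize`,
`networks-table`, `fusion-table`, `train`, `eval`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/halfunet.R", package="halfunet"))')" \
    summarize half-unet --input 1x128x128
#> {"network":"half-unet","params":208865,"flops":2268569600,
#>  "params_label":"0.21 M","flops_label":"2.27 G"}
```

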