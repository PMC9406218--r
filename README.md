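# icoseg

Lightweight conv-transformer segmentation of ICOS-positive cells in
immunohistochemistry (IHC) patch images — implemented natively in R.

## The problem

Inducible T-cell COStimulator (ICOS) is an immune-checkpoint biomarker. In
DAB-stained IHC slides of colon cancer, ICOS-positive cells show brown
cytoplasmic staining with blue hematoxylin nuclei; negative cells show blue
nuclei only. Scoring positive cells over tissue-microarray patches by hand
is slow, so this package segments them automatically: 256 × 256 RGB patches
are resized to 224 × 224, pushed through an encoder–decoder network, and
thresholded at 0.5 into binary masks, which are then scored at pixel level
(Dice, sensitivity, specificity) and instance level (aggregated Jaccard
index, cell counts).

The package is aimed at computational-pathology researchers who want a
fully inspectable, dependency-light reference implementation of this model
family: every forward and backward pass is implemented in the package
itself (R plus compiled im2col convolution kernels), so the whole pipeline
— synthetic data, training, inference, evaluation — runs on one CPU with no
external deep-learning runtime.

## The model

A five-stage MobileViT-style encoder and a transposed-convolution decoder:

- **Encoder** — conv stem (stride 2) + MobileNetV2 inverted-residual (MV2)
  blocks for stages 1–2; stages 3–5 pair a strided MV2 block with a
  MobileViT block: local 3 × 3 conv → point-wise projection to dimension
  *d* → unfold into 2 × 2 patches → *L* pre-norm transformer layers applied
  across patches per intra-patch position → fold → project back → fuse with
  the input. Widths 16/32/64/96/128/160, *d* = 144/192/240, *L* = 2/4/3.
- **Bottleneck** — point-wise expansion to 640 channels and
  squeeze-and-excitation channel attention (reduction 16).
- **Decoder** — five 4 × 4, stride-2 transposed convolutions (216, 112, 64,
  32, 16 channels) with batch norm + ReLU, concatenative skip connections
  from the encoder stages at strides 16/8/4/2 plus the stem, and a 1 × 1
  sigmoid head.

Total: **8,117,705 trainable parameters (8.1 M)** — about 8× fewer than the
66 M of the Efficient-UNet predecessor on the same task.

Training minimizes the weighted loss *L* = γ·BCE + (1 − γ)·Dice with
γ = 0.4 (Dice with squared-magnitude denominator), using Adam (lr 1e-4),
batch size 8, flip/rotation/scale augmentation, and halving the learning
rate when the validation Dice stalls for two consecutive epochs.

Because the original clinical cohort is private, the package ships a seeded
synthetic generator that emulates the stained patches (brown DAB cytoplasm,
blue nuclei, pink tissue, touching-cell pairs, blur artifacts) with exact
instance ground truth, so everything is trainable and testable end to end.

## Worked example

```r
library(icoseg)

params   <- synth_params(patch_size = 128, radius_range = c(7, 14))
manifest <- generate_dataset(200, params, "synthetic-ihc", seed = 1)

fit <- icoseg(manifest,
              model_config = icoseg_config("small"),
              config = train_config(input_size = 64, epochs = 20, seed = 42),
              verbose = FALSE)
print(fit)
#> Fitted ICOS-positive cell segmentation network
#> Segmentation network configuration (preset: small )
#>   input 64 x 64  threshold 0.5
#>   encoder: stem 8 | stages 16/24/32/48/64 | transformer dims 32/48/64 depths 1/1/1
#>   bottleneck 128 (channel attention, reduction 8) | decoder 64/48/32/24/16
#>   trainable parameters: 0.61 M
#>   trained 20 epochs on 120 patches; best val Dice 0.8511 (epoch 20)

report <- evaluate_model(fit)
print(report)
#> Segmentation metrics over 60 patches
#>   dice         0.8553 +/- 0.0542
#>   aji          0.3926 +/- 0.1810
#>   sensitivity  0.9885 +/- 0.0075
#>   specificity  0.9584 +/- 0.0160
#>   cells: 217 ground truth, 229 predicted
```

This is the package's reduced-scale smoke experiment: a ~0.6 M-parameter
variant of the same topology trained for a few minutes of CPU time on
64-px synthetic patches. The mean test Dice of ~0.86 says the
implementation learns the task (the acceptance bar is 0.6); the aggregated
Jaccard index is lower because it additionally demands that fused touching
cells be split into the right instances. The full-size `"reference"`
configuration is instantiated with `icoseg_init(icoseg_config())` and
described stage by stage with `describe_model()`.

A command-line wrapper with `synth`, `train`, `predict`, `eval` and
`describe` subcommands is installed under `inst/scripts/icoseg` and is a
thin shell over the functions above (`icoseg_cli()`).

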