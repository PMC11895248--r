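---
title: "Segmenting retinal microaneurysms with a triple-attention U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting retinal microaneurysms with a triple-attention U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masegnet)
```

## The problem

Microaneurysms (MAs) are the earliest visible lesions of diabetic
retinopathy: round, reddish capillary swellings of 15-60 um that occupy a
handful of pixels in a colour fundus photograph. Segmenting them at pixel
level is hard for three compounding reasons: extreme class imbalance (MA
pixels are a small fraction of a percent of the image), low contrast against
a textured reddish background, and confusability with thin blood vessels,
which share both shape and colour locally. `masegnet` implements a complete
patch-based segmentation pipeline for this problem: fundus-specific
preprocessing, a U-shaped convolutional network with three cooperating
attention mechanisms, training with a plateau-halving learning-rate
schedule, and pixel-level evaluation.

## Preprocessing

Raw fundus photographs carry a large black backdrop around the circular
field of view. The chain applied by `preprocess_fundus()` is, in order:

1. **Border crop** (`crop_border()`): tight bounding box of pixels whose
   maximum channel exceeds a threshold. The default threshold of 10/255 is
   deliberately above zero so that compression noise in the nominally black
   border does not defeat the crop.
2. **Resize** to a 512 x 512 working resolution, bilinear with the
   half-pixel-centre convention (an exact identity at equal sizes, and exact
   2 x 2 block averaging at a factor-two reduction). Masks are resized with
   nearest-neighbour interpolation and re-thresholded at 0.5 so they remain
   binary.
3. **Green channel** (`extract_green()`): of the three colour channels the
   green one carries the highest lesion/background contrast, so later
   stages are single-channel.
4. **CLAHE** (`apply_clahe()`): contrast-limited adaptive histogram
   equalisation on a non-overlapping 8 x 8 tile grid. The clip limit
   defaults to 2.0, the common default for this operator.
5. **Gamma correction** (`apply_gamma()`): pointwise
   `((R / R_max)^gamma) * R_max` with `gamma = 0.9`, a mild brightening
   that counteracts over-darkening after equalisation. With `gamma < 1`
   the map is pointwise non-decreasing in brightness.
6. **Non-local-means denoising** (`denoise_nlm()`): each pixel is replaced
   by a similarity-weighted average over a 21 x 21 search window, with
   patch similarity measured over 7 x 7 templates and weights
   `exp(-D / h^2)`, `h = 10`. The implementation box-filters the per-offset
   squared-difference images with integral images, so the cost is
   `O(N * search^2)` independent of the template size; weights are read
   from a quantised exponential table (4096 steps per unit of
   `D / h^2`), which changes individual weights by well under 0.4% and the
   filtered image imperceptibly. Boundaries are handled by symmetric
   reflection. A constant image is exactly preserved.

Patches are then cut on a non-overlapping 64 x 64 grid
(`extract_patches()`), giving 64 patches per 512 x 512 image; residual
margins at foreign sizes are dropped rather than padded, a choice that is
irrelevant at the native resolution where 64 divides 512. Patch-grid
coordinates allow lossless stitch-back (`stitch_patches()`), which is also
how whole-image probability maps are assembled at prediction time.

Training patches are expanded exactly fourfold by deterministic
augmentation (`augment_pairs()`): each patch/mask pair contributes its
original plus a 90-degree rotation, a horizontal flip, and a vertical
flip. The expansion is deterministic rather than sampled per epoch because
the pipeline's patch arithmetic (4096 training patches becoming 16384) is
an exact multiplication, not an expectation.

## The network

`build_model()` constructs a U-shaped encoder-decoder. Each encoder stage
is two 3 x 3 convolutions with ReLU (no batch normalisation, matching the
plain conv + ReLU block design; a flag could add it but the default stays
faithful to the plain block), refined by a convolutional block attention
module (CBAM), then 2 x 2 max-pooled. Filter counts double at each of the
4 downsampling stages from a base of 32, giving a 512-filter bottleneck;
the narrow ablation ladder (base 16, bottleneck 256) is the same
construction. The head is a 1 x 1 convolution and a sigmoid, so the output
is a per-pixel lesion probability at the input resolution.

**CBAM** applies channel attention then spatial attention, sequentially and
channel-first. Channel attention pools the feature map globally by both
average and max, passes the two descriptors through a shared one-hidden-
layer perceptron (hidden width `C / r`, ReLU, reduction ratio `r = 16` --
the operator's customary default, as the ratio only needs to bottleneck
the descriptor), sums the outputs and applies a sigmoid. Spatial attention
pools across channels (mean and max), convolves the two-map stack with a
single 7 x 7 kernel and applies a sigmoid. Both maps lie strictly in
(0, 1) and act multiplicatively, so attention can only attenuate, never
amplify: `|F''| <= |F|` elementwise, a property the test suite checks.

**Attention gates** sit on the skip connections. The skip features and the
coarser decoder-side gating signal are each projected to an intermediate
width (half the skip channels) by 1 x 1 convolutions; the gating signal is
resampled to the skip grid by bilinear interpolation (the 2D counterpart
of the trilinear interpolation used in volumetric attention U-Nets); the
sum is rectified and collapsed to a single-channel sigmoid coefficient map
`alpha` that rescales the skip features. Gating the raw skip with the
coarser decoder signal *before* concatenation follows the attention U-Net
design this block derives from, and keeps the subsequent double 3 x 3
convolution as the normalisation of the concatenated map.

**The three-fold decoder block** combines all three mechanisms: attention
gate on the skip, 2 x 2 transposed-convolution upsampling of the decoder
signal, channel concatenation, double 3 x 3 convolution + ReLU, then CBAM
(channel then spatial) on the result.

Design choices where the architecture description leaves freedom:

- *Depth 4* (16x total downsampling): with 64 x 64 patches this leaves a
  4 x 4 bottleneck grid; a fifth pooling would leave 2 x 2 and starve the
  spatial-attention convolution. Depth is configurable.
- *Bottleneck CBAM*: included by default (the attention framing covers
  encoder and decoder ends of the U), toggleable.
- *Same-size padding* everywhere (zero padding 1 for 3 x 3, 3 for 7 x 7),
  required for the shape contracts and exact stitch-back.
- *Initialisation*: He-uniform with zero biases under a caller-supplied
  seed, the standard choice for ReLU networks.

With CBAM and the attention gates disabled the model collapses exactly to
a plain U-Net of the same widths; the test suite verifies this by
comparing the parameter count against an independently computed closed
form.

### Implementation note

No deep-learning framework is used: forward and backward passes are
written directly. Feature maps are `(H, W, B, C)` arrays; a same-padding
convolution is evaluated as k^2 BLAS `dgemm` calls on pointer-shifted
views of a zero-padded copy of the tensor, and its data/weight gradients
are the adjoint gemms, so all heavy arithmetic lands in the linear-algebra
library. The full backward pass is validated against central finite
differences in the test suite.

## Training

`train_model()` runs mini-batch Adam (`lr` from the schedule, otherwise
standard moments 0.9/0.999). The reference recipe -- batch 16, 40 epochs,
binary cross-entropy with predictions clamped at `1e-7`, initial rate
`1e-3` -- is the `train_config()` default. Dice loss (soft counts,
additive smoothing 1) and focal loss (`gamma = 2`, `alpha = 0.25`, the
customary defaults) are selectable for the loss ablation.

The learning rate follows a reduce-on-plateau rule: after 5 consecutive
epochs without a strict validation-loss improvement the rate is halved,
never falling below `1e-5`. Two details are pinned down here because any
implementation must choose them: *strict improvement* means a decrease of
more than `1e-4` below the best loss seen, and the first observed epoch
initialises the best loss while counting as stagnant (there is nothing to
improve upon), so a constant validation loss yields the sequence `1e-3`
for epochs 1-5, `5e-4` for 6-10, and so on down to the floor. The
monitored validation set is a seeded 10% holdout of the training patches
-- never the test patches -- unless the caller supplies one explicitly.
The best-validation parameters are kept and returned alongside the final
ones.

## Evaluation

`evaluate_predictions()` reports pixel-level accuracy, Dice, IoU (at a 0.5
binarisation threshold) and ROC/AUC. Counts are micro-aggregated over all
pixels of all images, with a per-image breakdown alongside; micro is
primary because per-image Dice is undefined or degenerate on lesion-free
patches. Empty-vs-empty Dice and IoU are defined as 1. Dice is computed in
the overlap form `2TP / (2TP + FP + FN)`, which equals the
precision-sensitivity form `2 P SE / (P + SE)` identically (a unit test
asserts the identity). The ROC sweeps 256 evenly spaced thresholds joined
with the empirical score set when that set is small, anchors the curve at
(0,0) and (1,1), and integrates trapezoidally; on small instances the
result matches exhaustive Mann-Whitney pair counting to 1e-12.

Accuracy is reported but deliberately de-emphasised: with 0.5% lesion
pixels, the all-background predictor scores 99.5% accuracy with a Dice of
zero -- the test suite asserts this as a regression documenting why Dice
and IoU are the primary surface.

## The synthetic generator

`generate_fundus()` emulates exactly the features of fundus images that
the method's design responds to: a circular field of view on black, a
reddish-orange background with low-frequency texture (a 16 x 16 Gaussian
field bilinearly upsampled, plus radial brightness falloff -- enough
structure for CLAHE to act on), dark curvilinear vessels drawn as random
quadratic Bezier strokes (the vessel-like distractors MAs are confused
with), and 3-20 non-overlapping dark disks of radius 1-4 px whose
contrast drop (10-40%) is twice as deep in the green channel as in red
and blue, making green-channel selection consequential. The mask marks
exactly the lesion disks; vessels are never foreground. Lesion centres
are rejection-sampled to keep whole disks inside the field of view and
separated, so connected-component counts equal the configured lesion
count. One integer seed drives a single pseudo-random stream, and output
is quantised to 8-bit, so images are bit-reproducible.

What the generator does *not* emulate: optic disc and macula, exudates
and haemorrhages, vessel branching trees, camera vignetting asymmetries,
and JPEG artefacts. Tests passing on synthetic data therefore demonstrate
that the pipeline's machinery is correct and that the network can learn
the lesion-versus-vessel discrimination it was designed for -- not that
clinical-grade accuracy transfers to real fundus datasets.

## Problem sizes used in tests

The test suite and the acceptance script size their computations to run
comfortably on a single CPU: the patch-arithmetic check runs the full
81-image reference shape at 512 x 512, unit tests use 128-256 pixel
images and 2-8 filter models, and the capacity check trains the full
default network (base 32, depth 4, bottleneck 512) on eight 64 x 64
patches with early stopping once the training Dice exceeds 0.9. Training
runs at the reference scale (16384 patches, 40 epochs) are possible with
the same code but are not exercised by the tests.

The capacity check uses a recipe worth spelling out because each element
addresses a specific small-sample pathology. Inputs are standardised to
zero mean and unit variance (without batch normalisation, raw 0-0.55
intensities make first-layer activations small and slow). The head bias
starts at the log-odds of the foreground pixel fraction
(`build_model(..., head_bias = qlogis(prior))`), so the network begins at
the class prior instead of spending tens of epochs collapsing to
background — the standard prior-initialisation trick for heavily
imbalanced dense prediction. The batch size is 2, giving four Adam
updates per epoch; with all eight patches in one batch, "200 epochs"
would mean only 200 optimiser steps, which is the binding constraint at
this scale. Finally the plateau schedule floors at 1e-4 rather than 1e-5,
keeping the late memorisation phase moving. With this recipe the default
network passes Dice 0.9 in about 45 epochs; none of it changes the
training path used at realistic data scales, where the defaults apply.

## Known limitations

- The network trains on CPU in double precision; at the reference data
  scale a full 40-epoch run is a long computation, so the package is
  positioned for method study and desk-scale experimentation rather than
  production training.
- The NLM weight table quantises the exponential; bit-level agreement
  with a naive `exp()` implementation is not guaranteed (agreement is to
  ~4 significant digits).
- `EBImage::clahe` performs the CLAHE step; its interpolation arithmetic
  may shift constant images by a fraction of a grey level (constancy
  itself is preserved).
- Determinism is per-platform: the same seed reproduces results exactly
  on the same BLAS/CPU, not necessarily across maths libraries.
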