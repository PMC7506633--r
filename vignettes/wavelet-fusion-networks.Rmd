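---
title: "Spectral-spatial wavelet-fusion networks: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-spatial wavelet-fusion networks: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haarnet)
```

## The model

Convolutional classifiers extract spatial features; for histopathology,
where diagnosis rests on cell-scale texture at several magnifications,
frequency-domain (spectral) structure carries complementary information.
haarnet implements a convolutional network whose downsampling path is fused,
by channel concatenation, with a multilevel 2D Haar wavelet decomposition of
the input image: at each resolution where the convolutional trunk halves its
spatial size, the matching level of the wavelet pyramid is concatenated into
the feature stack, so deep layers see both learned spatial features and
fixed multi-resolution spectral features.

### The Haar front end

The 2D Haar analysis bank consists of four separable $2\times2$ kernels
built from the scaling function $\phi$ and wavelet $\psi$: the approximation
kernel $W_{LL}$ (all entries equal) and three zero-sum detail kernels
$W_{LH}, W_{HL}, W_{HH}$. One decomposition level correlates each input
channel with all four kernels over non-overlapping $2\times2$ blocks
(stride-2 valid correlation, top-left anchored), mapping an
$H \times W \times C$ image to an $H/2 \times W/2 \times 4C$ subband stack;
level $l$ decomposes the approximation (LL) channels of level $l-1$. A
four-level pyramid of a $512 \times 512 \times 3$ image therefore yields
stacks of $256^2$, $128^2$, $64^2$ and $32^2$ by 12 channels.

Three kernel normalizations are exposed because two natural conventions
coexist and differ only by per-subband scale:

* `raw` — entries $\pm 1$, the form in which the filters are usually
  printed. The LL response to a constant image $c$ is $4c$.
* `orthonormal` — raw scaled by $1/2$; the four flattened kernels are
  orthonormal, so each level conserves the sum of squares (Parseval). This
  is the network default: it keeps activation scale stable across pyramid
  levels, which matters when four levels are concatenated into one network.
* `average` — LL rescaled to entries $1/4$ (details stay orthonormal), so
  the LL subband *is* $2\times2$/stride-2 average pooling exactly. This
  makes the "wavelet as pooling" reading literal: a strided filter bank
  downsamples like average pooling while also emitting detail channels.

Subband and channel order is fixed as (LL, LH, HL, HH) blocked per input
channel. Any fixed order is equivalent up to a channel permutation, which
the first convolution absorbs. Odd-sized inputs are rejected rather than
padded — the network input is constrained to multiples of 16, so all four
levels divide evenly and no boundary rule is needed.

### The layer graph

`build_architecture()` declares the network as a named, topologically
ordered graph (kinds: input, wavelet, conv, batchnorm, relu, avgpool,
concat, flatten, dense, dropout). All convolutions are $3\times3$, "same"
padding, each followed by batch normalization and ReLU. The spatial trunk
halves resolution only at four stride-2 convolutions (`conv_1_2`,
`conv_2_2`, `conv_3_2`, `conv_4_2`); pyramid levels 1–4 enter through
parameter-free taps consumed by `conv_1`, `conv_a`, `conv_b`, `conv_c`, and
three concatenation points fuse the two branches at matched resolutions
(192, 256 and 512 channels). The head is a window-2/stride-1 average pool
(shape preserving), flatten to 32768, two dense-2048 + BN + ReLU + dropout
blocks, and a dense classifier.

```{r audit}
g <- build_architecture(num_classes = 4, input_size = c(512, 512, 3))
audit_parameters(g)$totals
```

`audit_parameters()` counts parameters in closed form — conv
$(9C_{in}+1)C_{out}$, dense $(N_{in}+1)N_{out}$, batch norm $2C$ trainable
(scale, shift) plus $2C$ non-trainable (running mean, variance) — and
`forward_shapes()` propagates shapes symbolically. Both reproduce the
reference layer table cell for cell; `instantiate_model()` is required (and
tested) to allocate exactly the audited counts.

Reconstructions and interpretations the reference table forced:

* **`norm_4`.** The printed table has no `norm_4` row, yet `relu_4` lists
  `norm_4` as its input, and only with a 256-channel batch norm there do
  the non-trainable halves sum to the printed 13,440. It is therefore
  reconstructed as BatchNorm(256) between `conv_4` and `relu_4`, giving 17
  batch-norm layers in total.
* **Batch-norm cells.** Printed batch-norm parameter cells equal $4C$ —
  consistent with both printed totals only if read as trainable $2C$ plus
  non-trainable $2C$; the audit adopts that reading.
* **Downsampling.** No pooling rows exist where the trunk halves, so
  halving is realized as stride-2 convolution.
* **Pooling type.** The surrounding text mentions both max and average
  pooling; average pooling is the one formalized (and is what the
  `average` filter-bank mode reproduces), so `pool_5_1` is average pooling
  with window 2, stride 1, same padding — the only configuration matching
  its printed shape-preserving behaviour. With "same" padding, overhanging
  windows average in-bounds pixels only, so a constant map stays constant.
* **`wavelet[k]` indexing.** Tap $k$ is pyramid level $k+1$: the consumers'
  printed parameter counts (13,952; 6,976; 27,904) all imply 12 input
  channels, and their spatial sizes match levels 2–4.
* **Totals.** An abstract-level summary elsewhere cites "7.6 million"
  parameters; the layer table itself sums to 76,289,732 trainable +
  13,440 non-trainable, and the table is taken as authoritative.
* **Head.** Output activation and loss are not stated; softmax with
  cross-entropy is used, the conventional reading of a dense-$K$
  classifier. The dropout rate is likewise unstated; the default is 0.5,
  configurable.

`width_multiplier` scales every conv filter count and the dense-2048 widths
(never the classifier) so the same topology can be audited and trained at
reduced width; fractional channel counts are rounded with a warning.

## Patching and augmentation

Large slides are cut into $512\times512$ windows with 50% overlap
(stride $= side \cdot (1-\text{overlap})$, anchored grid, top-left origin;
partial border windows are discarded). If an image is smaller than the
window along an axis — e.g. $700\times460$ sources against a 512 window —
the whole extent of that axis is taken and the crop is rescaled to
$512\times512$ bilinearly. Each window is expanded into 8 variants: the four
90° rotations, each with and without a vertical mirror (flip across the
horizontal axis — "vertical mirroring" is ambiguous, but either reading
generates the same 8-element orbit once composed with the rotations, so
downstream results are unaffected). Labels are inherited from the source
image. Normalization — subtracting each color channel's own mean
(per-patch, the closest reading of normalizing "each patch") — is applied
*after* the geometric transforms, so the zero-mean postcondition holds on
every emitted patch.

## Training harness

`split_dataset()` partitions at **source-image level**, stratified per
class, before any patching: overlapping patches of one image are highly
correlated, so a patch-level split would leak test content into training.
The no-leakage condition is re-asserted at run time. Defaults follow the
reference setup: 70/30 split, 200 epochs, batch size 3 (the stated "3 batch
sizes" is read as batch size 3; the phrasing could also mean three sizes
were tried, so it is a config field, not a constant). The optimizer is not
specified in the reference setup; Adam at learning rate $10^{-4}$ with
softmax cross-entropy is the default, all overridable and logged in the
fit. Per-epoch history records training and test accuracy measured on the
same footing — evaluation mode, un-augmented patches of each split — so the
two curves are directly comparable; the running training-mode mini-batch
accuracy (a noisier, dropout-depressed estimator) is kept as a separate
column, and the best-test-accuracy weights are checkpointed. Evaluation reports both patch-level metrics and image-level
metrics, the latter by averaging an image's patch softmax vectors and
taking the argmax; macro one-vs-rest reductions are used for multi-class
sensitivity/specificity/AUC (the reduction used by the reference results is
unstated, so both granularities and the reduction are labelled explicitly
in the report).

### The CPU reference backend

No deep-learning framework is attached: `instantiate_model()` binds the
graph to a compact backend written for this package — im2col + GEMM 3×3
convolutions (compiled via RcppArmadillo), batch normalization with batch
statistics in training and running statistics (momentum 0.9,
$\varepsilon = 10^{-5}$) in evaluation, inverted dropout, and Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$). "Same"
padding follows the ceiling convention (stride 2 on even sizes pads only
bottom/right). All backward passes are hand-derived and verified against
central finite differences in the test suite; the convolution is verified
against an independent naive correlation oracle, and the wavelet front end
against both a brute-force block-dot-product oracle and an external wavelet
library. Weight initialization is He-normal, fully seeded: one seed
determines split, initialization, shuffling and dropout, so runs are
reproducible bit for bit on a single-threaded BLAS.

## Synthetic fixtures

Real histology datasets are large external downloads; the package instead
generates seeded "histology-like" RGB images that emulate only the
statistical hooks the method exploits: a stain-like base color, an oriented
sinusoidal texture of class-specific frequency (cycles per 100 px),
Poisson-placed Gaussian "nucleus" spots of class-specific density and
radius that darken the image with a blue-shifted absorption profile, and
Gaussian pixel noise, clipped to $[0,1]$. Because per-channel mean
subtraction erases mean color, the built-in classes are separated by
texture frequency and spot density — multi-scale statistics that the
wavelet detail bands resolve directly; a threshold on level-1 detail energy
alone separates the built-in class pair with >90% accuracy, and the
separability is monotone in the frequency gap (both properties are tested).
These fixtures validate the machinery, not the biology: passing tests show
the pipeline learns genuinely class-dependent multi-scale texture, but say
nothing about performance on real stained tissue, with its stain
variability, cell overlap and inter-patient heterogeneity.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at sizes chosen to
exercise every code path at full fidelity while remaining friendly to a
laptop CPU: parameter/shape audits run on the full 512-input,
width-1 graph (closed form, instant); gradient checks and
backend/audit agreement on a 16-input, width-1/16 graph; unit training
runs on 64×64 fixtures at width 1/8; and the end-to-end smoke training on
the documented fixture conditions — 2 classes × 20 images of
$256\times256$, width multiplier 0.25, 5 epochs, batch 3 — which reaches
>0.9 training and >0.8 test accuracy from the default seed. Training at
full 512/width-1 scale works through the same code path but is a
GPU-scale undertaking; reproducing published histology accuracies would
additionally require the external datasets and is explicitly out of scope.

## Known limitations

* The backend is a single-threaded CPU implementation intended for
  correctness, moderate-scale experiments and testing, not for GPU-scale
  training.
* Only the Haar family is implemented; other wavelet families
  (Daubechies, Coiflet, biorthogonal) are natural extensions of the filter
  bank but are not provided.
* No inverse transform/reconstruction, no undecimated transform, no stain
  or color normalization, and no whole-slide (pyramidal TIFF) readers.
* PNG and TIFF are the supported raster formats.
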