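---
title: "Few-view CT restoration with DEAR networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-view CT restoration with DEAR networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dearct)
```

## The problem

X-ray CT dose scales with the number of projections. Acquiring far fewer
views than the Nyquist-sufficient count (a *few-view* or *sparse-view* scan)
is one route to low-dose imaging, but analytic filtered back-projection
(FBP) then produces severe streak artifacts that bury lesions and subtle
soft-tissue detail. The DEAR family of networks (deep encoder-decoder
adversarial reconstruction) treats restoration as a learned mapping
$I_{\mathrm{FullV}} = T(I_{\mathrm{FewV}})$ from a few-view FBP volume to
its fully sampled counterpart, with the key ingredient that $T$ operates on
a 3-D block of adjacent slices at once: streaks live in 3-D, and a 3-D
network can exploit inter-slice context that per-slice networks discard.

`dearct` implements this pipeline end to end on synthetic data: a seeded
phantom generator, a fan-beam projector/FBP simulator, the normalization and
patch-stack pipeline, the DEAR-3D generator with its 2-D ablation variants
and 3-D Wasserstein critic, the composite MSE + SSIM + adversarial
objective under WGAN-GP training, and PSNR/SSIM/RMSE evaluation with
sliding-window whole-volume inference.

## The generator

The generator is a stride-1 U-net crossed with DenseNet:

* **Encoder**: four *unpadded* $1\times3\times3$ convolutions
  (slice $\times$ row $\times$ column; stride 1, ReLU). Because no spatial
  down-sampling is used, each "down" stage shrinks the padded sides by
  exactly 2 pixels ($64 \to 62 \to 60 \to 58 \to 56$) while the slice
  dimension is untouched. After each sampler sits a **dense block**: five
  zero-padded $3\times3\times3$ convolutions (growth-rate filters, ReLU)
  where layer $l$ consumes the concatenation of the block input and all
  previous layer outputs, $x_l = T_l([x_0, \dots, x_{l-1}])$. The stage
  emits the full concatenation $[x_0, x_1, \dots, x_5]$.
* **Decoder**: four transpose convolutions (realized as full-padding
  $1\times3\times3$ convolutions, growing the sides back
  $56 \to 58 \to \dots \to 64$), each followed by a dense block whose input
  is the concatenation of the up-sampled features with the size-matched
  encoder stage's concatenation (the *conveying path*). A shortcut conveys
  the deepest down-sampler output around the fourth dense block into the
  first up-sampler.
* **Output stage**: the final dense block uses four growth layers; a linear
  1-filter $3\times3\times3$ convolution consumes the concatenation of the
  last up-sampler output and the last feature map, and the network input is
  added to it. The network therefore learns the *negative artifact field*
  — it must emit negative values to cancel bright streaks — which is why
  the reconstruction layer has no ReLU, and why `build_generator()`
  zero-initializes it: a freshly built generator is exactly the identity,
  the natural residual starting point.

The canonical 3-D configuration uses stage widths 48, 66, 80, 112 (mirrored
in the decoder) with dense growth 20, totalling 5,123,617 trainable
parameters. The 2-D variants replace the dense-block kernels by
$3\times3$ and use a uniform width everywhere: 38 filters (DEAR-2D,
3,459,749 parameters) or 48 filters (DEAR-2D-i, 5,519,329 parameters — a
widened 2-D network whose budget matches the 3-D net for fair comparison).
These three totals are wiring oracles: the count of a uniform-width
2-D generator is exactly quadratic in the width,
$2394F^2 + 74F + 1$, and the test suite verifies that a quadratic fitted at
widths 2, 3, 4 predicts the width-38 count to the last digit — any
mis-wired concatenation breaks this.

Because the generator is fully convolutional (and the samplers change sizes
only by fixed margins), trained weights apply to any input with sides of at
least 9 pixels; whole volumes are restored by `reconstruct_volume()` with a
sliding 9-slice window and uniform averaging of overlapping predictions
(center-slice fusion is available via `fusion = "center"`).

## The critic and the adversarial framework

The critic is a Wasserstein discriminator: six zero-padded stride-2
$3\times3\times3$ convolutions with 64, 64, 128, 128, 256, 256 filters and
leaky-ReLU (slope 0.2) activations, then fully connected layers of 1024 and
1 units, with no final nonlinearity. Stride-2 SAME convolutions reduce a
$9\times64\times64$ input along the slice axis as
$9\to5\to3\to2\to1\to1\to1$.

Training minimizes, over critic parameters,
$$\mathbb{E}[D(G(I_{\mathrm{FewV}}))] - \mathbb{E}[D(I_{\mathrm{FullV}})]
  + \lambda\,\mathbb{E}_{\bar I}\big[(\lVert \nabla_{\bar I} D(\bar I)\rVert_2 - 1)^2\big],$$
with $\bar I = \alpha I_{\mathrm{FullV}} + (1-\alpha) G(I_{\mathrm{FewV}})$,
$\alpha \sim U[0,1]$ per sample and $\lambda = 10$. The penalty gradient is
taken with respect to the interpolated *input*, the WGAN-GP convention.
Since no automatic-differentiation framework is involved, the parameter
gradient of the penalty is computed by explicit double backpropagation: for
piecewise-linear activations the input gradient at fixed activation masks
is a linear function of the weights, and for any cotangent $r$ the
derivative $\partial (r^\top g)/\partial W_k$ has the ordinary
weight-gradient form with the mask-linearized forward propagation of $r$ as
"input" and the cached backward quantities as "output gradient". The test
suite verifies this against finite differences on every layer of a small
critic.

## The generator objective

$$L_G = \lambda_{al} L_{al} + \lambda_{sl} L_{sl} + L_2$$

* $L_2 = \frac{1}{N_s N^2} \sum_{i=1}^{N_b} \lVert Y_i - X_i \rVert_2^2$ —
  note the printed normalization: summed over the mini-batch, divided by
  the voxels of a *single* sample (no $1/N_b$); the learning rate absorbs
  the constant.
* $L_{sl} = \frac{1}{N_b} \sum_i (1 - \mathrm{SSIM}(Y_i, X_i))$, with SSIM
  evaluated per 2-D slice with an $11\times11$ window ($K_1 = 0.01$,
  $K_2 = 0.03$, dynamic range 1 on normalized data) and averaged over the
  $N_s$ slices of each sample. The window is uniform by default (the
  Gaussian-weighted window of the classic SSIM is available via
  `ssim_window_type = "gaussian"`); whether the structural term should use
  a 3-D window is genuinely open, and the slice-wise 2-D convention was
  chosen because display and reading happen per slice.
* $L_{al} = -\mathbb{E}[D(G(I_{\mathrm{FewV}}))]$.

Weights: $\lambda_{sl} = 0.5$, $\lambda_{al} = 0.0025$. Optimization: Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rate $10^{-4}$ halved after
every epoch (both networks share the schedule), mini-batch 10 — giving the
canonical $10\times9\times64\times64\times1$ training tensor — and 5 critic
updates per generator update (the WGAN-GP convention; the framework's
papers specify only "iterative" alternation). The SSIM gradient needed for
backpropagation is computed in closed form from the per-window partials
with respect to the window mean, variance and covariance, back-projected
through the (adjoint) window correlation; it is finite-difference-checked
in the tests.

## Fan-beam simulation

Few-view inputs are produced physically: each slice is forward-projected
with an equiangular fan-beam geometry (source-detector 1085.6 mm,
source-isocenter 595 mm, pixel 0.664 mm, full scan of $2\pi$) and
reconstructed by weighted FBP (cosine ray weighting, discrete equiangular
ramp kernel applied by FFT, distance-weighted backprojection). Choices the
geometry description leaves open are configurable with these defaults:
equiangular detector sampling with the arc sized to cover the
image-diagonal field of view plus 2% margin and spacing matched to the
pixel size at the isocenter; Ram-Lak filtering (Hann behind
`filter = "hann"`). Negative FBP values are retained until normalization —
clipping would hide exactly the streak structure the network must learn.
Few-view simulation runs on HU images *before* normalization, mirroring
reconstruction from raw data; the patching module then applies one shared
window to both members of a pair.

The projector is validated analytically: line integrals are linear in the
image to $10^{-6}$, the central ray through a centered disc of radius
$r$ and attenuation $\mu$ integrates to $2r\mu$ within 1%, a full-view
round trip reconstructs a disc to under 5% relative RMSE inside its
support, and reducing the view count strictly lowers PSNR while raising
streak variance outside the support.

## The phantom generator

Clinical abdominal training data cannot be redistributed, so the package
ships a seeded synthetic stand-in, `phantom_spec()` /
`generate_phantom_volume()`: piecewise-constant ellipse composites — air at
−1000 HU, a soft-tissue body ellipse at 40 HU, nested organ ellipses at
40 HU plus a drawn contrast, and spherical low-contrast lesions (default
−40 to −10 HU against their host tissue). Ellipse centers and axes drift
across slices as a reflected random walk (default 0.5 mm per slice),
emulating the slice-to-slice continuity of contiguous 1 mm abdominal
series; lesions are genuine 3-D spheres, so their cross-sections wax and
wane across slices. Mild Gaussian noise (default 5 HU) and an optional
smooth texture field complete the model. Piecewise-constant regions are a
deliberate choice: every region is analytic, so lesion masks, lesion
contrast and partial-volume counts have exact oracles
(`generate_lesion_mask()` is rebuilt from the same seeded draw and can
never drift from the volume).

What the phantoms do *not* emulate: anatomical shape variability, organ
texture, contrast dynamics, metal or motion artifacts, and detector
physics (noise enters in image space, not in the projections). Passing
tests on phantoms therefore demonstrate that the pipeline's machinery —
simulation, objectives, optimization, inference — behaves as specified,
not that clinically trained performance transfers.

## Patch pipeline

Normalization maps a per-corpus HU window (default −1000 to 2000) linearly
to $[0,1]$ with clipping; a per-image window would put the two members of
a pair on different scales. $64\times64$ patches are cropped with stride
32; patch origins sit at multiples of the stride with an *exclusive* upper
bound, $K = \lfloor (N_{img}-\mathrm{size})/\mathrm{stride} \rfloor$
positions per axis — 14 per axis, 196 per $512\times512$ image, and
exactly 502,936 patches over a 2566-image corpus, which is the arbiter
between the two plausible conventions (the inclusive boundary variant is
available via `origin_convention = "inclusive"`). 3-D stacks take 9
consecutive slices per 2-D origin with stride one along the slice axis;
mini-batches of 10 are drawn with seeded shuffling and short final batches
are dropped so the batch shape is constant.

## Ablation variants

`ablation_suite()` trains five networks with shared seed and data:
DEAR-2D1 (2-D, MSE only), DEAR-2D2 (2-D, MSE+SSIM), DEAR-2D-i (widened
2-D, MSE+SSIM), DEAR-3D1 (3-D, MSE+SSIM, no adversarial framework — no
critic is built at all), and full DEAR-3D (MSE+SSIM+adversarial under
WGAN-GP). The critic's dimensionality follows the generator's.

## Numerical and design notes

* **Engine.** All convolutions run through one C++ routine family
  (im2col + GEMM via RcppArmadillo) covering valid/same/full padding,
  stride-2 SAME, and transpose convolutions (full-padding convolutions).
  Forward/backward passes are exercised against brute-force loops and
  central finite differences layer by layer.
* **Determinism.** Builders, the batch iterator, interpolation draws and
  phantom generation restore the caller's RNG state and derive everything
  from explicit seeds; two runs with the same configuration are
  bit-identical.
* **Degenerate inputs.** Generators reject inputs whose sides would
  collapse in the encoder (sides below 9); the critic rejects inputs too
  small for its six halvings; empty datasets, inverted windows, inverted
  ranges and mismatched geometries raise immediately. A non-finite
  generator loss aborts training with the last checkpoint retained.
* **Known limitations.** Double precision throughout (no GPU, no mixed
  precision); the critic's fully connected layer fixes its input patch
  shape (the generator alone is fully convolutional); training at the
  published clinical scale (502,936 patches of $64\times64$) is out of
  scope for a CPU engine.

## Test-scale choices

The acceptance-style training checks run the full pipeline at a reduced
scale chosen up front on arithmetic-budget grounds: phantoms on a 128-pixel
grid (pixel 2 $\times$ 0.664 mm), 4-filter networks, $9\times16\times16$
patch stacks (200 stacks, 3 epochs for the restoration check; 60 stacks,
2 epochs, 3 seeds for the objective comparison). One scaling choice
deserves emphasis: on a coarser grid a literal 75-view simulation is only
mildly undersampled, so the tests preserve the *view-density ratio* of the
reference setting (75 of 2304 views at 512 pixels $\approx$ 19 views at
128 pixels). Under that scaling the simulated FBP inputs land at
$\approx$ 25 dB PSNR — the same degradation severity as the reference
few-view baseline — and a reduced DEAR-3D trained for three epochs
recovers more than 1 dB of it, while the composite objective matches or
beats the MSE-only variant in validation SSIM (median over three seeds).
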