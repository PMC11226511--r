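---
title: "Large-kernel attention for 3D segmentation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-kernel attention for 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lka3d)
```

## The problem and the model

Multi-organ and tumor segmentation of 3D CT/MRI volumes needs both local
contextual detail and long-range dependencies. Query–key self-attention
captures the latter but is quadratic in the voxel count and ignores channel
structure; plain convolution is local. `lka3d` implements the middle road: a
**large-kernel (LK) attention** operator whose attention map is produced by a
convolution with a very large effective receptive field, made affordable by
**kernel decomposition**.

### Decomposing a large kernel

A dense cubic convolution with kernel side $K$ over $C$ channels costs

$$N_{\mathrm{PRM,O}} = C\,(C K^3 + 1)$$

parameters. The decomposition replaces it with a $(2d-1)^3$ depthwise (DW)
convolution, a $(K/d)^3$ depthwise *dilated* (DWD) convolution with dilation
$d$, and a $1^3$ pointwise convolution:

$$N_{\mathrm{PRM,D}} = C\left((2d-1)^3 + (K/d)^3 + C + 3\right),$$

where the $+3$ counts one bias per convolution in the chain. For
$K = 21, d = 3, C = 32$ this is 16,096 instead of 9,483,296 parameters.
FLOPs are the parameter count times the voxel count $H W D$ for both
variants, so the same ratio applies. Treating $d$ as continuous and setting
$\partial N_{\mathrm{PRM,D}}/\partial d = 0$ gives the stationarity equation

$$24 d^2 - 24 d - \frac{3K^3}{d^4} + 6 = 0,$$

solved by bisection in `optimal_dilation()`; for $K = 21$ the root is
$d^* \approx 3.4159$, and evaluating the exact objective at the neighbouring
integers selects $d = 3$. `decompose_kernel()` derives the chain geometry,
including the "same"-size paddings $d-1$ (DW) and $d(K/d-1)/2$ (DWD), and the
effective receptive field $2d - 1 + d(K/d - 1)$ of the spatial chain.

### The attention operator

For an input feature map $X$, the module computes

$$Z = \sigma_{\mathrm{lReLU}}(\mathrm{GN}(X)), \qquad
A = \sigma_{\mathrm{sigmoid}}\!\big(\mathrm{Conv}_{1^3}(\mathrm{Conv}_{\mathrm{DWD}}(\mathrm{Conv}_{\mathrm{DW}}(Z)))\big), \qquad
\mathrm{Output} = A \otimes Z + Z.$$

$A \in (0,1)$ acts as a multiplicative spatial *and* channel gate (the
pointwise convolution mixes channels), and the residual addition keeps the
map a modulation rather than a bottleneck: wherever $Z \neq 0$ the output is
between $1\times$ and $2\times$ $Z$.

Two details are genuinely open in the operator's definition and are design
choices here:

* **Convolution order.** The composed formula can be read DWD-before-DW or
  DW-before-DWD; parameter count and receptive field are identical either
  way. We default to DW → DWD → pointwise, the order the decomposition is
  usually drawn in; `conv_order = "dwd_first"` switches for exactness
  studies.
* **Residual source.** The printed operator adds the normalized-activated
  input $Z$; a raw-input residual is available via `residual = "raw"` but is
  off by default.

Group normalization uses the largest divisor of $C$ not exceeding 8 as the
group count (unspecified in the operator's definition; 8 is the common
choice, and the divisor rule keeps degenerate channel counts valid), with
per-channel affine parameters. The leaky-ReLU slope is 0.01 throughout. All
convolutions are zero-padded "same" at stride 1. Weights are initialized
He-fan-in normal, biases zero, deterministically under a seed.

## The U-Net

`network_config()` describes a six-scale encoder–decoder: per scale two
$3^3$ convolutions each followed by GN and leaky ReLU; stride-2 $3^3$
transition convolutions (with GN + lReLU) double the channels up to a cap of
512 (32, 64, 128, 256, 512, 512 — the deepest map is 1/32 of the input);
$4^3$ stride-2 transposed convolutions upsample; skip connections
concatenate channels and the first decoder convolution maps $2C \to C$;
$1^3$ segmentation heads sit at every scale except the two lowest, giving
deep supervision with geometric weights $1, 1/2, 1/4, 1/8$ normalized to sum
one (the weighting itself is a package choice). Softmax heads serve
exclusive multi-organ labels; sigmoid heads serve overlapping tumor-region
channels.

Attention modules are inserted **directly after a transposed convolution,
before concatenation with the skip** — the only placement consistent with
the channel counts 512/256/128/64/32 implied by the published per-variant
parameter increments. `mid_placements()` is the single equal-21 module at
the middle decoder scale; `full_placements()` covers all five decoder
scales.

### Parameter accounting

`network_param_breakdown()` lists every component's exact count;
placement-additivity,

$$\mathrm{params}(\text{variant}) - \mathrm{params}(\text{Base})
 = \sum_{(s,K,d)} C_s\left((2d-1)^3 + (K/d)^3 + C_s + 3\right),$$

holds exactly for the convolution parameters of the added modules and
reproduces every published "+x.xx k" increment (Mid +76.67 k, Full
+444.06 k, deepest-scale +291.33 k, ...). The module's internal GN affine
pairs ($2C$ each) are carried by the network but excluded from that identity
(`conv_only_attention = TRUE`), matching how the increments are quoted. Our
Base network counts 100,988,988 trainable parameters; the commonly quoted
base total of 101,017.22 k differs by 0.028%, attributable to undocumented
implementation details of the original network (head/transition minutiae),
which is why the breakdown — not the grand total — is the architecture
check. The relative cost of the Mid module, $76{,}672 / \mathrm{params}
(\text{Base})$, rounds to 0.0759% either way.

## Losses, metrics and statistics

* **Weighted soft Dice** (multi-organ): per foreground class
  $\mathrm{sd}_c = (2\sum p t + \varepsilon)/(\sum p + \sum t +
  \varepsilon)$ with $\varepsilon = 10^{-5}$; the loss is
  $1 - \sum_c w_c\,\mathrm{sd}_c / \sum_c w_c$. Weights are one minus the
  class's foreground-to-background voxel ratio, pooled over the whole
  training set (dataset-level is stable; per-batch is not) and clamped to
  $[0,1]$. Background is excluded from the loss classes; normalizing by the
  weight sum is our reading of "weighted" (the alternative raw weighted sum
  only rescales gradients).
* **BCE + soft Dice** (tumor regions): mean binary cross-entropy plus
  unweighted soft Dice over the region channels, 1:1.
* **Dice / HD95**: Dice is $2|X \cap Y|/(|X|+|Y|)$. HD95 as commonly printed
  applies a percentile to a maximum of two scalars, which is degenerate; we
  implement what the words describe — the 95th percentile of the pooled
  directed boundary-to-boundary distances (boundaries via 6-connectivity
  erosion, distances in mm via the voxel spacing, R's type-7 quantile). A
  `directed_max` switch takes the maximum of the two directed percentiles
  instead. Conventions: both masks empty → Dice 1, HD95 0; empty reference
  with non-empty prediction under the enhancing-tumor challenge convention →
  Dice 0, HD95 373.13 (applied per class via `fp_penalty`).
* **Region maps**: enhancing tumor, tumor core (ET + necrotic/non-enhancing)
  and whole tumor (core + edema) nest as $ET \subseteq TC \subseteq WT$.
* **Paired t-tests** compare per-case scores between two models
  (`compare_reports()`).

## Data pipeline

Resampling Gaussian-presmooths each axis that is downsampled
($\sigma = \text{factor}/3$ voxels — the factor-proportional rule; the
exact constant is unspecified upstream) before trilinear interpolation;
labels go nearest-neighbour without smoothing. Center crop/pad records its
inverse so predictions return to the original grid. Intensity normalization
is per-channel z-scoring over nonzero voxels for MRI, and 0.5/99.5-percentile
clipping then z-scoring for CT.

The augmentation policy (probability, range): brightness 0.30,
$U(0.7,1.3)$ multiplicative; contrast 0.15, $U(0.6,1.4)$ about the channel
mean; Gaussian noise 0.15, $\sigma \sim U(0,1)$ (the upstream table
conflates "variance" and $\sigma$; we draw $\sigma$); blur 0.20, kernel
$\sigma \sim U(0.5,1.5)$; gamma 0.15, $\gamma \sim U(0.7,1.5)$ applied on
min–max normalized intensities; scaling 0.30, $U(0.65,1.6)$; rotation 0.30,
independent per-axis angles $U(-30,30)^\circ$; elastic 0.30,
$\alpha \sim U(5,10)$ voxels with field smoothing $\sigma = 3\alpha$;
flipping 0.50, each axis independently with probability 1/2. Intensity
transforms never touch labels; spatial transforms use trilinear/nearest
sampling for image/label. Every draw is seeded.

## The phantom generator

`generate_phantom()` emulates a multi-class scan: per class, disjoint
ellipsoidal "organs" (rejection-sampled bounding spheres) of distinct mean
intensity (1, 2, … by default, within-blob sd 0.1) on a zero-mean noisy
background (sd 0.1), default grid $64^3$ at 1 mm spacing, three classes, two
blobs each — high-contrast, well-separated structures that a working
pipeline must segment essentially perfectly. What it does **not** emulate:
anatomical shape variability, partial-volume boundaries, intensity
inhomogeneity, inter-organ contact and class imbalance of clinical data.
Passing the phantom suites therefore validates the machinery (shapes,
gradients, conventions, determinism), not clinical accuracy; the published
clinical Dice/HD95 comparisons require the original datasets and GPU-scale
training and are explicitly out of scope here.

## Numerical and engineering choices

* Exact integer arithmetic for all parameter counting; k/M unit rendering
  rounds half-up at presentation only.
* Bisection for the dilation root (tolerance $10^{-8}$, bracket $[1, K]$
  where the stationarity function provably changes sign for $K \ge 2$).
* The convolution engine (dense, depthwise dilated, transposed, group norm,
  Adam, backprop) is written in C(++) with hand-derived gradients; all
  layer gradients are finite-difference-checked in the test suite.
  Transposed convolutions use kernel $4^3$, stride 2, padding 1 (exact
  doubling).
* Training defaults: Adam ($\beta = (0.9, 0.999)$, no weight decay), 200
  epochs, batch size 1, initial learning rate $3\times 10^{-4}$ with
  polynomial decay of power 0.9 (a constant-rate switch exists; only the
  initial rate is specified upstream). Gradient clipping off by default.
  NaN losses abort with the offending sample and step.
* Problem sizes in the test suite are chosen for a single CPU: oracle
  equivalence on $\le 8^3$ grids with $\le 4$ channels, metric oracles on
  $6^3$ masks, and a memorization smoke test — a four-scale, base-width-8
  Mid-type network overfitting one default $64^3$ phantom (constant
  learning rate $3\times10^{-2}$ — a group-normalized network of this size
  tolerates it, and it cleans up the early foreground over-prediction that
  the Dice loss corrects only slowly at small rates; early stop once the
  monitored foreground Dice reaches 0.85, hard cap 200 steps) and then
  reaching mean foreground Dice ≥ 0.8 on that phantom.

## Known limitations

No sliding-window inference (whole volumes must fit in memory after
cropping); no 2D or anisotropic-kernel variant; no multi-head or
channel-attention branch; no DICOM ingestion or registration; single-device
training only. The complexity calculus covers stride-1 cubic kernels, as
decomposed in the attention module — not strided or grouped variants.
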