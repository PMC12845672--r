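---
title: "Hybrid CNN-Transformer super-resolution for brain MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid CNN-Transformer super-resolution for brain MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charms)
```

## The problem

Single-image super-resolution (SR) reconstructs a high-resolution MR slice
$I^{SR} = f_\theta(I^{LR})$ from a low-resolution acquisition. In brain MRI
this shortens scan time and, in the cross-field setting, upgrades clinical
3T images toward the appearance of 7T references. The constraint that
shapes everything in this package is *lightweightness*: the network must
stay under ~2 M parameters and a few tens of GFLOPs per slice so it can run
in clinical reconstruction pipelines, which rules out both heavy CNNs and
quadratic-cost spatial transformers.

## The network

The model is a three-stage hybrid:

1. **Local feature extraction.** A shallow 3×3 convolution lifts the
   single-channel slice to `C = 64` features, followed by four **RRAF**
   (Reverse Residual Attention Fusion) blocks. Each RRAF block cascades
   `K = 4` **RLFE** units, $F_k = F_{k-1} + \varepsilon_k(F_{k-1})$, and
   finishes with a channel shuffle:
   $F_{out} = \mathrm{Shuffle}(F_{in} + \sum_k \varepsilon_k(F_{k-1}))$.
   An RLFE unit is two 3×3 convolutions with a ReLU, gated elementwise by
   an **ESA** (Enhanced Spatial Attention) map
   $A_s = \sigma(C_\uparrow(C_{d2}(C_{d1}(P(C_\downarrow(F))))))$:
   a 1×1 channel reduction (factor 4), 3×3 stride-2 max pooling, dilated
   3×3 convolutions at rates 1 and 2, bilinear interpolation back, and a
   1×1 recovery to a single-channel sigmoid map. After each RRAF block a
   **PCA** (pixel–channel attention) module recalibrates features with
   $A_{PCA} = (A_p + A_c)/2$, where $A_p$ is a per-pixel sigmoid map from
   a 1×1 convolution and $A_c$ a per-channel sigmoid weight from a
   two-layer bottleneck-free MLP on globally pooled features; the half-sum
   keeps the combined map inside $[0,1]$ deterministically (a per-map
   min–max normalization was rejected as unstable for near-constant maps).
   The PCA module is residual — a 3×3 transform and a 1×1 fusion wrap the
   gating additively — so a zero-weight module reduces exactly to
   $0.5\,F$, which the tests exploit.

2. **Global context.** One transformer block: **MDDTA** attention plus a
   **GDDFN** feed-forward stage, each with a residual skip. MDDTA computes
   *channel-wise* (transposed) attention: queries, keys and values are
   reshaped to $[HW, C]$ and contracted over positions, giving a
   row-stochastic $[C, C]$ matrix per head,
   $\mathrm{softmax}(Q^\top K / d)$, applied to the values and combined
   over heads with learned scalar weights. One head per dilation rate
   (1, 2, 3) of the depthwise 3×3 convolutions that refine the shared
   1×1 Q/K/V projection. Spatial self-attention would be quadratic in
   pixels; the channel-wise form is the only reading consistent with the
   linear-complexity requirement, and `mddta_flops()` verifies linearity.
   The temperature $d$ is stored on the log scale (initialized to
   $\log\sqrt C$) so it stays positive under gradient updates. GDDFN
   expands with a 1×1 convolution to $2 e C$ channels, splits into two
   branches refined by dilated depthwise 3×3 convolutions, gates one with
   GELU of the other, and projects back.

3. **Reconstruction.** Shallow features are added back (global residual),
   then one (×2) or two (×4) conv + pixel-shuffle stages upsample, a 3×3
   refinement convolution cleans the high-resolution grid, **HFIR**
   applies a sigmoid-gated residual correction
   $U + \sigma(C^{(4)}(U)) \odot U$ with four stacked depthwise-separable
   3×3 convolutions, and a 3×3 convolution maps to the single output
   channel. We read the gated form as "gate computed from U, multiplying
   U", which matches its role of selectively boosting edges; at zero
   weights the block returns exactly $1.5\,U$. An optional image-space
   bicubic skip exists but is off by default.

### Width calibration

The published budgets are the only constraint on the hidden widths, so the
defaults were calibrated once against them: trunk width `C = 64`, head
width 64, ESA reduction 4 with bias-free attention-branch convolutions,
per-RRAF PCA placement, shared-projection MDDTA, GDDFN expansion 0.5, and
a 3×3 group-fusion convolution that accompanies channel shuffling. With
these choices the assembled models count exactly 1.46 / 1.49 / 1.69 /
1.72 / 1.74 M parameters across the ×2 ablation sequence and 1.61 / 1.64 /
1.84 / 1.87 / 1.89 M at ×4, and the full ×4 model costs 25.4 GFLOPs for a
256×256 reconstruction (multiply-add = 2 FLOPs; convolutions and attention
contractions counted, elementwise ops not). Two notes on interpretation:
the ablation tables label the budget column "(MB)" but the values align
column-for-column with the "(Million)" parameter columns elsewhere, so we
treat all of them as millions of parameters; and a 256×256 *input* at
these budgets would cost >150 GFLOPs for any matching architecture, so the
complexity figure is understood — and `count_flops()` is defined — with
256×256 as the super-resolved output grid (the standard evaluation
geometry), i.e. a 64×64 input for the ×4 model.

Channel shuffling itself is parameter-free (a fixed interleaving
permutation of channel groups; `channel_shuffle_perm()` exposes the
bijection). The group-fusion convolution attached to the shuffle flag is
what gives the "+CS" configuration its distinct budget and lets shuffled
group information mix across the full channel width.

## Training

Pre-training minimizes L1 over 200 epochs with AdamW
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), batch 16,
learning rate $10^{-4}$ — these are the `train_config()` defaults.
Cross-field fine-tuning (`charms_finetune()`) minimizes the composite
objective

$$L = \lambda_1 \lVert f_\theta(x) - y \rVert_1
    + \lambda_2 (1 - \mathrm{SSIM}(f_\theta(x), y))
    + \lambda_3 L_{AR}, \qquad
  (\lambda_1, \lambda_2, \lambda_3) = (1, 0.1, 0.005),$$

at learning rate $10^{-5}$ with the early CNN backbone frozen: only the
last $\min(2, n_{transformer})$ transformer blocks and the decoder
(upsampling stages, refinement convolution, HFIR, output convolution)
adapt. Frozen weights are bit-identical before and after, which the test
suite asserts.

The functional form of the attention-regularization penalty $L_{AR}$ is
a design choice of this package: its two stated goals are suppressing
diffuse activations and decorrelating heads, so the default variant is
mean row entropy of the $[C,C]$ attention matrices (zero for one-hot
rows, $\log C$ for uniform rows) plus mean pairwise cosine similarity
between flattened head matrices (1 for identical heads), equally
weighted. The regularizer is pluggable through `ar_register()` so
alternative forms can be swapped without touching the trainer. Setting
$\lambda_3 = 0$ detaches it exactly — the AR graph is never built — so
composite training degenerates to L1 + SSIM bit-for-bit. Whether AR is
active during pre-training is configurable and off by default (the stated
pre-training loss is plain L1).

### Numerical choices

* **Engine.** Training runs on a compact reverse-mode autodiff tape with
  compiled (RcppArmadillo) kernels for convolution, pooling and bilinear
  resampling; analytic gradients are verified against central finite
  differences through the full model to ~1e-6 relative error.
* **Initialization.** Convolutions use the standard Kaiming-uniform
  convolution default (bound $1/\sqrt{\text{fan-in}}$, i.e. gain for
  $a=\sqrt5$), biases zero. A gain-1 Kaiming bound was tried first and
  rejected: through 16 cascaded residual units it inflated activations to
  magnitude ~40 and training diverged. Weight draws are seeded from the
  model config, so assembly is bit-reproducible.
* **Stability.** The global gradient norm is clipped at 1 before each
  update (configurable). Small-batch runs at aggressive learning rates
  otherwise show rare catastrophic loss spikes.
* **Model selection.** When validation pairs are supplied the weights with
  the best validation PSNR are restored at the end of training.
* **Determinism.** All randomness (batch order, patch positions, phantom
  noise) flows from explicit seeds through an RNG-state-preserving
  `with_seed()`; identical configs reproduce identical loss trajectories
  bitwise.

## Synthetic phantoms

`generate_phantom()` renders nested ellipsoids — background, a CSF layer,
a cortical gray-matter ribbon, a white-matter core — with a sinusoidal
angular perturbation of the GM/WM boundary emulating sulci
(`sulci_frequency` controls the folding scale), an optional smooth
multiplicative bias field, and additive Gaussian noise (Rician available
behind a flag; at the simulated SNRs the Gaussian approximation is
appropriate). Masks are the noiseless generative labels, so SNR/CNR and
foreground-masking code can be tested against exact ground truth. T1w
phantoms order intensities WM > GM > CSF, T2w the reverse; the orderings
are enforced. A `background_level` pedestal (default 0) emulates a
scanner noise floor: with it, background noise is uncensored by the
non-negativity clip and the empirical background SD recovers the
generating $\sigma$; without it, background statistics are censored but
the default foreground threshold $\tau = 0.01$ behaves as intended.
Foreground masking applies a one-pixel opening before the specified
closing because threshold speckle from background noise would otherwise
merge into a single giant component.

`paired_field_phantoms()` renders the same anatomy twice for cross-field
experiments: the "7T-like" member at nominal noise and contrast, the
"3T-like" member with a 1.5-pixel Gaussian blur, doubled noise, and the
GM–WM contrast gap shrunk to 70%. These degradations are chosen to
reproduce the qualitative orderings of real 3T/7T comparisons (7T > SR >
3T in SNR and CNR), not their magnitudes.

What phantoms do *not* emulate: real cortical topology, partial-volume
effects, k-space acquisition artifacts, motion, or scanner-specific
contrast nonlinearity. Tests that pass on phantoms therefore demonstrate
that the implementation learns and measures what it claims, not that it
reaches any particular fidelity on real MRI.

## Data pipeline

Volumes are read from NIfTI-1/2 with RNifti, reoriented to RAS, min–max
normalized per volume onto $[0,1]$ (constant volumes map to zeros with a
warning; the inverse map is retained), and the central 100 slices (start
index $\lfloor (D-n)/2 \rfloor$) are degraded slice-wise with an
antialiased Catmull-Rom bicubic kernel ($a = -0.5$, kernel stretched by
the scale factor on downsampling, replicate edges, row-normalized
weights). The bicubic dialect is pinned here deliberately: PSNR
comparisons are sensitive to it. Splits are by subject, 70:20:10 with
largest-remainder rounding and a guaranteed non-empty test partition.
Bias-field correction and skull stripping are upstream preprocessing and
out of scope; the loader warns on negative intensities.

## Metrics

PSNR is $10\log_{10}(R^2/\mathrm{MSE})$ with an infinity flag at zero
MSE; SSIM uses the standard 11×11 Gaussian window ($\sigma = 1.5$,
$k_1 = 0.01$, $k_2 = 0.03$) over valid window positions; the data range
is 1 after normalization. SNR is mean brain-tissue intensity (WM ∪ GM)
over background SD; CNR is $|\mu_{GM} - \mu_{WM}|$ over background SD —
the source tables never define these, so the standard mask-based MR
conventions are used and documented. Per-slice rows aggregate to
per-subject means and an overall mean ± population SD. Paired
significance uses a two-sided exact Wilcoxon signed-rank test (robust at
10 subjects; a paired t-test is available), with $p = 1$ by convention
when all differences vanish. Foreground-masked PSNR/SSIM exists behind a
flag and is off by default.

## Desk-scale study protocols

Two scaled-down protocols make the training machinery testable on one
CPU in minutes; their sizes are fixed in the package so tests, vignette
and scripts share one definition:

* `phantom_sr_study()`: 8 training + 2 validation + 4 held-out phantom
  subjects of 4 slices at 64×64, 32 training pairs at ×2; a width-16
  full model trained 500 AdamW steps (batch 1, 16×16 LR patches biased
  toward foreground, lr $3\times10^{-3}$ with cosine decay, clipping at
  1, validation every 100 steps). Reported: mean held-out PSNR of the
  model versus bicubic upsampling. Across 20 seeds the trained model won
  in 20/20 with margins of +0.04 to +0.20 dB.
* `crossfield_study()`: 20 fine-tuning + 5 held-out paired-field
  subjects (one 64×64 slice each); brief self-supervised-style
  pre-training on 7T-like pairs, then frozen-backbone composite-loss
  fine-tuning (lr $5\times10^{-4}$ at this scale — the production
  $10^{-5}$ default moves a 200-step-pretrained toy model imperceptibly)
  mapping degraded 3T-like inputs to 7T-like targets. Reported: held-out
  PSNR of the super-resolved 3T versus the native 3T, against the
  7T-like reference. The adapted model recovers the suppressed contrast
  and exceeds native 3T by ~2 dB on every held-out subject.

These runs demonstrate a learning signal and the directional cross-field
gain; they make no claim about the magnitudes achievable with full-scale
training on real data.

## Known limitations

Strictly 2D slice-wise processing (no through-plane continuity); CPU
training is practical only at reduced widths; the autodiff engine covers
exactly the operations this architecture needs; checkpoints are R
serializations, not a cross-language exchange format; and the attention
regularizer's published form is unrecoverable, so any quantitative effect
attributed to it here reflects this package's variant.
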