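---
title: "Fusing structural and functional brain images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing structural and functional brain images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical brain imaging produces complementary modalities.  Structural images
(MRI, CT) resolve anatomy — edges, tissue boundaries, texture — in a single
gray channel.  Functional images (PET, SPECT, perfusion maps) encode
metabolism or blood flow as pseudo-colour, at the price of blurry structure.
Image fusion composes one image that keeps the anatomy of the structural
scan and the colour-coded physiology of the functional scan.  `medfuse`
implements a complete fusion pipeline for *registered* pairs (pixel-aligned
slices; registration itself is out of scope) together with the ten objective
quality metrics commonly used to judge fusion results.

## Pipeline overview

For a structural image $S$ and a functional RGB image $F$:

1. **Colour decomposition.** $F$ is mapped to the NTSC YIQ space.  Y is
   luminance; I and Q are the chroma axes ordered by human colour
   sensitivity.  Only Y takes part in fusion; I and Q pass through
   untouched, which is what preserves the functional colour exactly.
2. **Intuitionistic fuzzy preprocessing (IFP).**  $S$ and the Y channel are
   independently contrast-enhanced (below).
3. **Encoding.**  Both enhanced images run through a small convolutional
   encoder, giving one feature stack per source.
4. **Trace fusion.**  Each stack is reduced to a scalar salience (sum of
   absolute feature-map traces); normalised saliences weight a convex
   combination of the stacks.
5. **Decoding.**  The fused stack is decoded to a fused luma $O$, which
   replaces Y before the inverse YIQ transform (clamped to the RGB gamut
   only at this final step).

`fuse_pair()` runs steps 1–5; `fuse_gray_pair()` skips the colour steps.

### The colour matrix

The forward map is the standard signed NTSC matrix

$$\begin{pmatrix}Y\\I\\Q\end{pmatrix} =
\begin{pmatrix} 0.299 & 0.587 & 0.114\\
                0.596 & -0.274 & -0.322\\
                0.211 & -0.523 & 0.312 \end{pmatrix}
\begin{pmatrix}R\\G\\B\end{pmatrix},$$

whose I and Q rows sum to zero, so achromatic pixels carry zero chroma.  An
all-positive variant with blue-luma weight 0.144 circulates in parts of the
fusion literature; it does not separate chroma (a gray image would acquire
colour), so it is clearly a typographical loss of the minus signs.  We
default to the signed matrix and expose the all-positive one as
`matrix = "paper-literal"` for comparison.  The inverse is computed
numerically from the forward matrix rather than hard-coded, so the two are
consistent to machine precision whichever variant is selected.

## Intuitionistic fuzzy preprocessing

Radiometric uncertainty makes fixed membership functions (Gaussian,
triangular) fragile across modalities.  IFP instead derives everything from
the image's own extrema $g_{\min}, g_{\max}$:

$$\nu(g) = \frac{g_{\max}-g}{g_{\max}-g_{\min}}, \qquad
\nu_\lambda = \nu^\lambda, \qquad \xi_\lambda = 1-\nu_\lambda,$$

where $\xi_\lambda$ is the enhanced image and $\lambda > 0$ controls how
aggressively dark content is suppressed.  $\lambda$ is chosen from the grid
$\{200, 300, \ldots, 800\}$ by maximising the fuzzy entropy

$$E(\lambda) = \frac{1}{MN}\sum_{x,y}
\frac{2\,\mu_\lambda\,\xi_\lambda}{\mu_\lambda^2+\xi_\lambda^2},$$

with ties broken toward the smallest $\lambda$ for determinism.  The
membership image $\mu_\lambda$ is not pinned down by the source material
beyond its name; we take the mirror of the non-membership construction,
$\mu_\lambda = [(g-g_{\min})/(g_{\max}-g_{\min})]^\lambda$, which makes the
per-pixel term a symmetry measure between membership and enhanced intensity
(1 when they agree, 0 when either vanishes).  Pixels where both are zero
contribute 0.  Two degenerate rules keep the pipeline total: $\lambda \le 0$
is an error, while a *constant* image (extrema coincide, the ramp is
undefined) passes through unchanged with a warning rather than failing
mid-pipeline.  Enhancement is monotone in intensity for fixed extrema, so
ordering of tissues is never inverted.

## The encoder/decoder

The encoder is a stem convolution (C1) followed by a three-layer
detail-capture block (CIDN) with exactly one dense feature-reuse layer: the
second CIDN layer consumes the concatenation of all previous outputs (C1 and
CIDN1), and its output is routed both onward and to the fusion layer.  This
is a deliberately reduced DenseNet: one reuse layer preserves mid-network
detail without the feature redundancy (and cost) of a full dense block.
All convolutions are 3×3, zero-padded, stride 1, so any input of at least
8×8 keeps its spatial shape end to end.  Activations are SeLU,

$$\mathrm{selu}(x) = \lambda_s x \; (x>0), \qquad
\lambda_s \alpha_s (e^x-1) \; (x \le 0),$$

with the self-normalizing constants $\lambda_s = 1.0507\ldots$,
$\alpha_s = 1.6733\ldots$ (both configurable); the published form of this
activation sometimes omits $\lambda_s$ from the negative branch, but the
self-normalizing property requires it on both.

Channel widths are not dictated by the design, so they are architecture
parameters with defaults C1: 1→16, CIDN1: 16→16, CIDN2: 32→16 (dense
input), CIDN3: 16→16; the stack handed to fusion is the concatenation of
CIDN2 and CIDN3 (32 maps).  The text supports routing CIDN2 to both the
next layer and the fusion layer; concatenating CIDN2 with CIDN3 keeps both
readings without doubling the decoder.  The decoder narrows 32→16→8→1; its
last layer is squashed by a logistic so outputs are valid Bernoulli means
for the cross-entropy loss (the design leaves the output activation open;
the logistic is the choice consistent with that loss).  Initialisation is
LeCun-normal (variance scaling $1/\mathrm{fan_{in}}$), the appropriate
scheme for self-normalizing activations, drawn from a seeded RNG.

The network engine itself — forward convolution, backpropagation and Adam —
is implemented in-package as vectorised im2col/BLAS matrix operations; the
backward pass uses the adjoint identity that the gradient of a zero-padded
correlation is a correlation with the spatially flipped, channel-transposed
kernel.  All gradients are verified against central finite differences in
the test suite.

## Training

Encoder and decoder are trained jointly as an autoencoder (the fusion layer
is bypassed) under the mixed loss

$$L = \alpha\,L_{\mathrm{CE}} + \beta\,(1 - \mathrm{SSIM}(I, O)),$$

with $\alpha = 500$, $\beta = 1$, learning rate $5\cdot10^{-4}$, batch size
32, 10 epochs, and the per-epoch exponential decay
$lr = 0.95^{\,\mathrm{epoch}}\, lr_0$.  $\beta$ is not stated by the source
design (only $\alpha$); $\beta = 1$ makes the SSIM term the unit reference.
$L_{\mathrm{CE}}$ is reduced as a *mean* over pixels, which keeps
$\alpha, \beta$ independent of image size; the literal summed form is one
flag away (`reduction = "sum"`).  Reconstruction targets are continuous
intensities, so the cross entropy has an irreducible floor (the binary
entropy of the target); what matters during training is the decrease, not
the absolute value.  The optimiser is Adam with default moments — the design
only asks for first-order gradient descent and a determinism contract:
given a seed, initialisation, shuffling and hence the loss log are
bit-reproducible.  A non-finite loss aborts with diagnostics rather than
continuing silently.

The training corpus in the original setting is 80,000 natural images at
256×256, converted to grayscale.  That scale is neither redistributable nor
necessary for validating the machinery; the package's synthetic corpus
(below) uses 200 images at 64×64 — enough for the autoencoder to reach
held-out reconstruction SSIM above 0.9 in minutes on one CPU, which is the
regime the tests and the acceptance script exercise.  The 11×11 Gaussian
SSIM window is unchanged at this scale.

## Trace fusion

A feature map's trace (sum of diagonal entries; for a symmetric map, the
sum of its eigenvalues) summarises its energy along the diagonal.  Source
$i$'s salience is $s_i = \sum_j |\mathrm{Tr}\,\varphi_i^j|$ and its weight
$w_i = s_i / \sum_k s_k$.  Two gaps in the published rule needed decisions:
(i) the weight is written as if it varied per pixel, but a trace is one
scalar per map, so weights are global scalars per source; (ii) SeLU features
can have negative traces, which could produce negative or undefined
weights — absolute values keep the weights a probability vector, and
`signed = TRUE` preserves the literal signed sum for comparison.  If every
salience is zero the weights fall back to uniform.  Fusion is the convex
combination per map index, so fused responses are bounded by the sourcewise
envelope; a `mean` strategy (the addition baseline) is available for
ablation.

## The metric suite

Ten metrics are computed per (a, b, fused) triple, with these conventions
where the literature leaves latitude:

* **EN** — Shannon entropy (bits) of the 256-bin histogram.  The printed
  formula in some sources normalises pixel *values* rather than histogram
  counts, which is not a probability distribution; the histogram form
  matches the verbal definition ("average information").
* **CE** — symmetric KL divergence between 256-bin histograms (natural
  log), sources weighted 0.7/0.3; the weights come from a 35-of-50
  physician preference survey.  Histograms are smoothed by $10^{-12}$ per
  bin for log safety.
* **RMSE** — equal-weight average of the two source-vs-fused RMSEs.
* **AG** — mean forward-difference gradient magnitude
  $\sqrt{(\Delta_x^2+\Delta_y^2)/2}$ over the $(M-1)\times(N-1)$ interior.
* **SSIM** — 11×11 Gaussian window ($\sigma = 1.5$), $c_1 = 0.01^2$,
  $c_2 = 0.03^2$, $c_3 = c_2/2$, dynamic range 1, reported for the triple
  as the mean of SSIM(a, f) and SSIM(b, f).
* **Q0 / Qabf / Qw / Qe** — the universal image quality index over 8×8
  sliding windows (step 1, unbiased variances), extended per Piella:
  saliency = local variance (the framework leaves $s(\cdot)$ open),
  $\lambda(w) = s_a/(s_a+s_b)$, window weight $C_w = \max(s_a, s_b)$
  normalised over windows, and the edge-dependent variant with exponent
  $\alpha = 0.5$ on gradient-magnitude edge images.  Windows with zero
  variance or zero mean energy are undefined and skipped; negative $Q_w$ is
  floored at zero only where a fractional power would be undefined, so the
  identities $Q_e|_{\alpha=0} = Q_w$ and $Q_e|_{\alpha=1} = Q_w'$ hold
  exactly.
* **FMI** — mutual information (bits, 64-bin joint histograms) between
  gradient-magnitude feature images of the fused image and each source,
  summed, without normalisation.  Gradients are the default feature choice
  among the alternatives (DCT, wavelets), which are out of scope.
* **VIF** — standard four-scale pixel-domain formulation (Gaussian filter +
  2× downsampling per scale, blockwise variance decomposition, noise
  variance 2 on the 0–255 scale).  The source material describes VIF only
  verbally; the implementation is pinned by the identity property
  $\mathrm{vif}(x,x) = 1$ and monotone degradation under blur and noise.
  Scales with no valid window (inputs near the 32×32 minimum) are skipped.

Every windowed metric is cross-checked in the tests against an independent
naive nested-loop oracle at $10^{-9}$ on small images.

## Synthetic phantoms

`make_structural()` draws a nested-ellipse head (bright skull ring,
mid-gray brain, 3–5 random tissue ellipses, low-amplitude band-limited
texture) — piecewise-constant with sharp edges so AG/EN and the IFP
enhancement are discriminative.  `make_functional()` places 2–4 Gaussian
activity blobs strictly inside the same anatomy mask and renders them
through a black→blue→green→yellow→red perfusion colormap, so the pair is
registered by construction.  `make_training_corpus()` mixes phantoms,
oriented ramps, filtered noise and blends, giving mean histogram entropy
above 4 bits.  All generators are seeded and bit-reproducible, and all
shape/noise magnitudes are fixed defaults chosen once to resemble
tomographic slices at 64×64.

What the phantoms do *not* emulate: acquisition physics (no k-space, no
attenuation, no partial-volume effects), inter-subject variability, and
pathology beyond generic blobs.  Passing tests therefore demonstrate that
the pipeline's machinery is correct and well-behaved, not that fusion
quality on clinical data matches any published figure — the published
comparisons rest on a clinical database that is not redistributable.

## Numerical choices and limitations

* Intensities are \[0,1\] doubles throughout; integer images are normalised
  at read time and clamped only at RGB write-out.
* Cross-entropy clamps reconstructions to $[10^{-7}, 1-10^{-7}]$.
* IFP entropy defines $0/0$ pixels as 0; argmax ties break to the smallest
  grid value.
* Degenerate inputs: constant images bypass IFP with a warning; all-zero
  feature stacks fuse with uniform weights; histogram metrics smooth empty
  bins.
* The problem sizes used by the tests and the acceptance script — 200
  training images at 64×64, 10 epochs, 20 held-out images, 4 evaluation
  pairs — are the package's desk-scale study conditions; they keep a full
  run in the minutes range on a single CPU while leaving every code path
  exercised.
* Known limitations: weights are global per source (no spatially varying
  trace variant); only the gradient FMI feature is implemented; training
  at the 80,000-image natural-image scale is out of scope, as are the
  comparison fusion algorithms and any subjective-scoring tooling.
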