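---
title: "Diffusion-based dehairing of dermoscopic images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based dehairing of dermoscopic images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermadiff)
```

## The problem and the model

Dermoscopic photographs of skin lesions are frequently occluded by hair
strands, which degrade both human reading and automated lesion
classification. `dermadiff` treats dehairing as conditional image
generation: given a hairy image $x$, generate the hair-free image
$y_0$ by reversing a Gaussian diffusion, with $x$ supplied to the
denoiser at every step.

**Forward process.** The clean image is corrupted by a Markov chain
$q(y_t \mid y_{t-1}) = \mathcal{N}(\sqrt{\alpha_t}\, y_{t-1},
(1-\alpha_t) I)$. Writing $\gamma_t$ for the cumulative noise variance,
the corruption has the closed form

$$ y_t = \sqrt{1-\gamma_t}\, y_0 + \sqrt{\gamma_t}\, \varepsilon,
   \qquad \varepsilon \sim \mathcal{N}(0, I), $$

with the consistency relation $1-\gamma_t = (1-\gamma_0)
\prod_{s\le t}\alpha_s$. This parameterization is variance-preserving:
$(1-\gamma) + \gamma = 1$, so unit-variance signal stays unit-variance
at every noise level — the property the Monte-Carlo test in the suite
checks at $n = 10^5$ with a 1% tolerance. The schedule places
$\gamma_0 < \cdots < \gamma_T$ linearly on
$[\gamma_{\min}, \gamma_{\max}]$, and $\alpha_t$ is derived as
$(1-\gamma_t)/(1-\gamma_{t-1})$, which makes the consistency relation
an identity of the construction (it is still asserted to $10^{-12}$
relative error as a guard). Whether $\gamma_0$ is exactly zero is a
free choice; the default is $\gamma_0 = 10^{-4}$, and the identity
above carries the explicit $(1-\gamma_0)$ factor so it is exact either
way.

**Training.** The denoiser $f(x, y_t, \gamma)$ is trained to predict
$\varepsilon$ by plain mean-squared error, averaged over all elements
so the loss is comparable across image sizes. Noise levels are drawn
from the piecewise-uniform mixture over schedule knots: pick a step
$t$ uniformly, then $\gamma \sim U(\gamma_{t-1}, \gamma_t]$. Sampling a
continuous $\gamma$ rather than a discrete step index lets the noise
conditioning interpolate between knots; the sampler's empirical CDF is
tested against the closed-form piecewise-linear CDF (KS distance
$< 0.01$ at $n = 10^5$).

**Inference.** Two reverse updates are provided, because the two
natural readings of the reverse process differ and both are useful:

* *ancestral* (default): $y_{t-1} \sim \mathcal{N}(\mu, \sigma_t^2 I)$
  with $\mu = (y_t - \frac{1-\alpha_t}{\sqrt{\gamma_t}}
  \hat\varepsilon)/\sqrt{\alpha_t}$ and the fixed variance
  $\sigma_t^2 = 1-\alpha_t$; the last step returns $\mu$ without noise.
  This matches the $\varepsilon$-prediction objective and is what the
  package uses by default.
* *residual*: the plain additive update
  $y_{t-1} = f(y_t, x, t) + y_t$, with the network output applied
  verbatim and no rescaling. It is kept first-class because iterative
  additive refinement is a documented mode of this model family; note
  it is not algebraically consistent with training $f$ to predict
  $\varepsilon$, so with a trained model the ancestral sampler is the
  one that restores well.

The variance choice $\sigma_t^2 = 1-\alpha_t$ is the simplest member of
the fixed-variance family; learned variances are out of scope.

## The denoiser

The noise predictor is a small conditional U-Net written directly in R
(forward and backward passes, plus Adam), since no deep-learning
runtime is among the package's dependencies. Its structure:

* input: channel-wise concatenation of the conditioning image $x$
  (resized to the noisy image's grid if needed) and $y_t$;
* encoder stages of ResNet blocks (3×3 conv → noise-level bias → ReLU
  → 3×3 conv, identity or 1×1-projected skip), 2×2 mean-pool between
  stages; mirrored decoder with nearest-neighbor upsampling and
  concatenated encoder features; 3×3 output head;
* noise-level conditioning: $\gamma$ is mapped to a sinusoidal
  embedding (geometric frequencies, default length 16) and injected
  into every block through a per-block linear layer as a per-channel
  bias. The mechanism the conditioning uses is a package choice — only
  that the noise level reaches every denoising step is prescribed by
  the model family.

Numerical choices that matter:

* **internal range**: images enter as $[0,1]$ arrays and are mapped
  affinely to $[-1,1]$ inside the diffusion core, so standard-normal
  noise and signal have comparable scale;
* **zero-initialized output head**: the untrained network predicts
  exactly zero noise. This stabilizes early optimization markedly at
  desk scale (it also gives the test suite a convenient exact
  "zero denoiser" oracle for the sampler contracts);
* **divisibility**: U-Net pooling needs spatial sizes divisible by
  $2^{\text{stages}-1}$; `predict_noise()` pads reflectively and crops
  the output, while the training loop simply requires conforming sizes;
* **gradients**: backpropagation is hand-written (im2col convolutions,
  pooling/upsampling adjoints, concat splits) and verified against
  central finite differences at $10^{-4}$ relative tolerance in the
  suite. ReLU is non-differentiable at 0; the checks probe generic
  points where this does not matter.

Training defaults follow the benchmark-scale settings of the method:
Adam at $\eta = 10^{-4}$, $T = 2000$ steps — those are `train_config()`
and `diffusion_config()` defaults. Desk-scale runs override them
explicitly (see below).

## Synthetic degradations

**Mask overlay.** A binary mask (1 = hair) is inverted
($m \mapsto 1-m$), added to the image, and 1 is subtracted. The
composition is exactly $\text{img} - \text{mask}$: background pixels
are bit-identical to the input and hair pixels are shifted to
$\text{img}-1$, i.e. negative. The unclipped result is exposed
(`$final_unclipped`) because the intermediate arithmetic is the
definition of the degradation; the rendered image is the $[0,1]$-clipped
variant, in which hair pixels are black. The arithmetic makes hair
*dark*, which is what its output images show; the package implements
the arithmetic as defined and does not attempt any skin-tone
inpainting in the generator.

**Line synthesis.** The self-supervised generator draws, per segment
and in this fixed order: integer $x_\text{start} \in [0, W]$, integer
$y_\text{start} \in [0, H]$ (both inclusive, read literally from the
procedure's uniform-integer convention), integer length
$L \in [10, 30]$, direction $d \in \{-1, +1\}$; endpoints are
$x_\text{end} = x_\text{start} + dL$, $y_\text{end} = y_\text{start} + L$
— every strand is a 45° downward diagonal. Default count is 1000
segments. Rasterization is Bresenham with width 1 and color 0 (dark
strands); geometry is the only prescribed part, so stroke color and
width are exposed parameters. Endpoints may leave the canvas;
rasterization clips to it.

## Procedural fixtures and what they do (not) show

No real dermoscopic data ships with the package. Fixtures are:

* `make_lesion_texture()`: a smooth skin-toned background (coarse
  random field, bilinear upsampling) plus one darker, softly bounded
  ellipse. It emulates the two features the dehairing task needs —
  smooth skin and a coherent dark lesion — and nothing else: no pigment
  network, no color statistics of real skin, no acquisition noise.
* `make_procedural_hair_mask()`: thin curved strands, one per vertical
  band, walking strictly downward with a clamped random-walk heading.
  Band confinement plus unit steps guarantee exactly `n_strands`
  8-connected components (for band width ≥ 4 px), a testable contract;
  the price is that procedural strands never cross, unlike real hair.

Passing tests on these fixtures demonstrates that the pipeline — data
synthesis, training, sampling, scoring — is internally correct and that
the model can learn to remove the synthetic degradation it was trained
on. They say nothing about performance on real dermoscopy (domain gap
in texture, color, hair geometry and illumination), which requires the
real paired benchmark data and full-scale training.

## Desk-scale experiment sizes

The recovery experiment used by the acceptance checks trains on 24
pairs of 16×16 grayscale textures degraded with 6 line segments of
length 3–7 (the default 10–30 px lengths are sized for 256 px images;
lengths are scaled with the canvas), $T = 50$, 500 Adam iterations at
$\eta = 10^{-2}$ with batch size 8, and evaluates on 8 held-out pairs.
These sizes are chosen so the whole experiment runs in about a minute
on one core while leaving a wide margin on its success criterion
(restored PSNR exceeding hairy PSNR; typical runs gain 8–17 dB). The
larger learning rate relative to the benchmark default reflects the
tiny model and short budget.

The dataset convention mirrors the paired-benchmark layout: two roots
(`Data_Skin_with_Hair`, `Data_Skin_without_Hair`) with seven diagnostic
class subdirectories (`akiec`, `bcc`, `bkl`, `df`, `mel`, `nv`,
`vasc`), matching basenames across roots, and a per-class reserved test
split (100 per class at benchmark scale → 700 test images).

## Metrics

* **PSNR** $= 10\log_{10}(\text{MAX}^2/\text{MSE})$; `Inf` sentinel at
  zero MSE; `MAX` defaults to 1 for $[0,1]$ images.
* **SSIM**: the standard per-window statistic with uniform 8×8 sliding
  windows (configurable; capped at the image size) and conventional
  stabilizers $C_1 = (0.01\,\text{MAX})^2$, $C_2 = (0.03\,\text{MAX})^2$.
  The window convention is a package choice; the per-patch formula is
  the defining part.
* **LPIPS**: the weighted multi-layer feature-difference sum with an
  *injectable* extractor. The default backend is a fixed-seed random
  convolution stack, so desk-scale runs need no pretrained weights;
  with the identity extractor the metric reduces exactly to mean
  squared pixel difference, which the suite uses as a calibration
  point. Values from the random backend are comparable only within a
  fixed seed/backend, not with published LPIPS numbers.
* **Classification metrics** are computed from one-vs-rest confusion
  counts and macro-averaged over classes; the reduction is declared
  because a single scalar over seven classes is otherwise ambiguous.
  Zero denominators yield `NaN` sentinels rather than silent zeros;
  cross-entropy floors probabilities at $10^{-12}$.

## Known limitations

* The residual sampling mode applies the network output verbatim; with
  an $\varepsilon$-trained model it will not restore well and is
  provided for completeness and contract testing.
* Pure-R training is practical to roughly 64 px and a few tens of
  thousands of parameters; benchmark-scale (256 px, $T = 2000$,
  pretrained-backbone LPIPS) is out of reach by design.
* PNG is the supported raster format (8/16-bit read, 8-bit round-half-up
  write); other formats must be converted first.
* The procedural fixtures are deliberately minimal; conclusions about
  real dermoscopic data require real data.
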