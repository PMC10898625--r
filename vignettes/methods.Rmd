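---
title: "Multi-site MR harmonization by content-style disentanglement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site MR harmonization by content-style disentanglement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Images collected at different MRI sites carry systematic, non-biological
appearance differences — global intensity scale, tissue contrast, bias
fields, noise and effective resolution — that confound any downstream
analysis pooling data across sites. Harmonization transforms images so that
these site effects are removed while the subject's anatomy is untouched.
Supervised harmonization needs *traveling phantoms*: the same subjects
scanned at every site. This package implements an unsupervised alternative
that needs only site labels.

## The model

Every image `x` is assumed to factorize into a *site-invariant content*
representation `c` (a spatial feature map encoding anatomy) and a
*site-specific style* vector `s` (a low-dimensional code for appearance).
Five network roles realize this factorization:

* a **content encoder** `E^C`, shared across sites, mapping an image to `c`;
* **style encoders** `E_i^S` (shared convolutional trunk, one output head
  per site) mapping an image to `s`;
* a **generator** `G(c, s)` that renders content under a style, with the
  style injected through adaptive instance normalization (per-channel gain
  and bias predicted from `s`);
* **style generators** `G_j^S` (MLP trunk, one head per site) mapping a
  standard-normal latent code `z` to a site-plausible style; and
* per-site **discriminators** `D_j` scoring whether an image looks like a
  real image from site `j`.

Training uses *content-style disentangled cycle translation*: a batch from
site `i` is translated forward to site `j` (`x̃_j = G(c_i, s_j)`, with
`s_j` either generated from a latent draw or encoded from reference images
of site `j`), re-encoded, and translated backward
(`x̂_i = G(c̃_j, s_i)`), which must reconstruct the input. Seven loss terms
shape the solution (all norms are **means over elements**, so the weights
are canvas-size independent):

| term | form | weight |
|------|------|--------|
| adversarial | `E[log D_i(x_i)] + E[log(1 − D_j(x̃_j))]` | 1 |
| content consistency | `‖c_i − c̃_j‖₁` | 10 |
| content alignment | `KL(N(c_i, I) ‖ N(0, I)) = ½·mean(c²)` | 0.01 |
| style diversity | `‖G(c_i, s_j) − G(c_i, s_j′)‖₁`, maximized | 1 |
| style consistency | `‖s_j − s̃_j‖₁` | 10 |
| cycle | `‖x_i − x̂_i‖₁ + 0.1·‖g(x_i) − g(x̂_i)‖₁` | 10 |
| identity | `‖x_i − G(c_i, s_i)‖₁` | 10 |

During training the content code of real images is perturbed,
`c_i = E^C(x_i) + η` with `η ∼ N(0, I)`, which regularizes the generator to
treat content features as a distribution rather than memorized points;
codes re-extracted from generated images are not perturbed, and no
perturbation is applied at inference.

### Design choices where the design was genuinely open

* **Diversity sign.** The diversity term appears with a positive weight in
  a minimized objective in some presentations, yet its purpose is to
  *increase* intra-site variability; minimizing it would collapse all
  latent draws to one output. The generator therefore **maximizes** it here
  (it enters the total negatively), clipped at a ceiling (`sd_clip = 1`) so
  it cannot dominate late training. `model_config(sd_literal = TRUE)`
  restores the literal sign for comparison.
* **Style consistency endpoints.** Comparing the *source* style `s_i` with
  the style re-extracted from the target-site image `s̃_j` would contradict
  disentanglement (they live in different site branches); the implementation
  compares the **generation style** `s_j` with `s̃_j`.
  `model_config(sty_literal = TRUE)` selects the literal variant.
* **GAN optimization.** The discriminator ascends the printed adversarial
  value; the generator minimizes the non-saturating surrogate
  `−E[log D_j(x̃_j)]`, the standard stable realization (the plain minimax
  form saturates when the discriminator wins early).
* **Image gradient `g(·)`.** Forward finite differences along both spatial
  axes with edge replication, concatenated; the simplest operator that
  penalizes edge displacement.
* **Style path schedule.** Latent-path and reference-path target styles
  alternate randomly with probability `style_source_mix = 0.5` per step, so
  both inference modes are trained; the diversity term is computed only on
  latent-path steps (it needs two latent draws) and reported as 0 on
  reference-path steps.
* **Stopping.** The theoretical stopping point (discriminator at chance on
  harmonized images) is not an operational rule; training runs a fixed
  `total_steps` and logs the discriminator calibration, which the test
  suite checks post hoc (mean real-probability on held-out fakes within
  (0.25, 0.75)).
* **Architecture scale.** The network stack follows the multi-domain
  image-to-image translation lineage (strided-conv encoder with a residual
  head; AdaIN generator; trunk-plus-heads style encoder, style generator
  and discriminator). Defaults are a base width of 8 (content trunk 8→16),
  `d_s = 8`, `d_z = 16`, canvas 64 and **downsampling 2** — a deliberate
  desk-scale capacity at which the full study (simulate, train ~1500 steps,
  evaluate) runs in minutes on one CPU core. Downsampling 2 matters
  qualitatively: a content map at half resolution can carry per-pixel
  texture (noise, thin boundaries), so identity translation can approach
  the input exactly instead of its denoised caricature; at downsampling 4
  the 16×16 map cannot represent that detail and reconstruction saturates
  at the denoising floor. The content encoder's residual head is left
  unnormalized and its output is multiplied by a fixed `content_scale`
  (default 8), so the training-time perturbation `η ~ N(0, I)` stays a
  perturbation instead of pinning the content signal-to-noise ratio at
  one (instance-normalized codes have unit scale by construction). All
  dimensions are configurable in `model_config()`.
* **Desk-scale learning rate.** The method's reference learning rate
  (`train_config()` default) is `1e-4`, appropriate for long training runs
  on full-size images. ADAM moves each weight by at most ≈ lr per step, so
  a 1500-step desk-scale budget caps total per-weight movement at ~0.15 at
  that rate — measured reconstruction loss then plateaus near 0.1 no matter
  the architecture. The shipped desk-scale studies therefore train with
  `learning_rate = 1e-3`, a standard small-model rate; this is a property
  of the study size, not of the method.
* **2.5D bookkeeping.** Three adjacent axial slices form the three channels
  of each training image. The window stride is 1 with edge replication,
  and at inference each window contributes only its center channel, so a
  volume is reassembled with exactly one output per axial position — the
  simplest scheme with no overlap averaging. Channel normalization to
  [-1, 1] is per-channel per-slice; harmonized outputs are mapped back to
  intensity units with the *source* slice's normalization record, since a
  generated image has no native intensity scale.

## The synthetic multi-site simulator

Real multi-site data with traveling phantoms is access-restricted, so the
package ships a simulator that reproduces the *structure* the method
assumes, with ground truth for everything the evaluation needs:

* **Shared anatomy**: a nested-ellipse head phantom (CSF-like ring,
  GM-like shell, WM-like core on background) warped by a smooth random
  deformation field; each subject is an integer anatomy seed.
* **Site styles**: per-site tissue-class mean intensities, a contrast
  exponent (gamma), a low-frequency multiplicative bias field (smoothed
  seeded noise — the standard MR coil-inhomogeneity model), additive
  Gaussian noise, and in-plane Gaussian blur (an effective-resolution
  analog; site 0 is blur-free by construction so cross-resolution recovery
  has a sharp target). Sites sit on a deterministic parameter grid with a
  small seeded perturbation, so any two sites differ in several parameters
  at once.
* **Intra-site variability**: the class means and gamma are jittered per
  sample (relative sd 0.03). The magnitude of intra-site style variance in
  real repositories is not characterized; this default is a plausible
  scientific choice, not a claim about any dataset.
* **Paired test sets**: held-out anatomies rendered under *every* site's
  style — synthetic traveling phantoms — with masks retained; train and
  test anatomy seeds are disjoint by construction.

What the simulator does *not* model: anatomically realistic brains, lesions,
registration error, through-plane anatomy change (the synthetic samples are
single slices, handled as degenerate 2.5D windows with all three channels
equal). Passing tests therefore demonstrate that the machinery implements
the method correctly and that the method removes *this family* of site
effects; they do not quantify performance on real brains.

## Evaluation

Paired fidelity uses MAE, MS-SSIM (scale count adapted to image size — 3
scales at 64×64 — with renormalized standard weights) and PSNR (peak 2 for
[-1, 1] data, capped at 100 dB), computed on min-max normalized images
because a harmonized image has no native intensity units. In the paired
(traveling-phantom) protocol the target rendering exists, so the fidelity
metrics use reference-path harmonization (style extracted from that paired
target image): a latent-draw style cannot know the target realization's
jitter, bias field or noise, which would put an irreducible floor on
paired error. The distributional metrics keep the latent-draw site-mode
protocol (harmonized sets scored against the target site's training
images). Distributional
quality uses the Fréchet distance and the unbiased polynomial-kernel (degree
3) MMD² on features from a **fixed seeded untrained convolutional
embedding** — deterministic and download-free; any pretrained embedding can
be substituted wherever a feature matrix is accepted, and only *relative*
comparisons (harmonized vs unharmonized against the same target set) are
asserted. The Fréchet matrix square root uses an eigen-decomposition with
negative eigenvalues clipped at zero. Segmentation consistency uses an
internal phantom segmenter (intensity-floor background at 12% of the range,
largest 4-connected component, 3-means clustering of foreground intensities
with deterministic quantile initialization, classes relabelled by ascending
mean intensity — hence invariant to positive intensity scaling) and the Dice
coefficient (defined as 1 when both sets are empty). Edge sharpness is
measured as a robust 10–90% transition-width proxy: per row, the ratio of
the robust intensity range to the maximum absolute finite difference,
medianized over rows and columns crossing strong edges.

## Numerical choices

* Log arguments in the probability-form adversarial loss are clamped at
  `1e-7`; the training path works on logits through stable softplus forms.
* Instance normalization uses `eps = 1e-5`; ADAM uses the conventional
  moments (0.9, 0.999, `eps = 1e-8`) with the stated learning rate `1e-4`.
* A non-finite total loss aborts training with the last checkpoint
  retained; `total_loss()` names the offending term.
* All randomness flows through R's RNG; derived streams (dataset anatomy
  seeds, per-sample renders, training, style draws) use hashed sub-seeds
  below 2^31, so every artifact is a pure function of (config, data, seed),
  bitwise, at a fixed BLAS thread count.

## Problem sizes used by the shipped studies

The test-suite and acceptance studies use 3 sites, a 64×64 canvas, 50
training anatomies per site, 10 paired test anatomies, batch 4 and 1500
training steps — sizes chosen so the full cycle runs comfortably on a
single CPU core. Determinism checks use a 32×32 canvas and a width-4 model,
where a training step costs milliseconds.

## Known limitations

* The simulator's site effects are global and smooth; spatially localized
  scanner artifacts (ghosting, motion) are out of scope.
* The embedding for FID/KID is untrained; absolute values are not
  comparable to published numbers computed with Inception features — only
  within-study contrasts are meaningful.
* Adapting a trained model to an unseen site (e.g. by distillation) is not
  implemented.
* Reconstruction at the desk-scale training budget is imperfect: identity
  translation cannot reproduce a test image's exact noise realization
  unless the model learns noise passthrough, so its error sits above the
  denoising floor; residuals appear as mild smoothing at tissue boundaries.
* Faithful style transfer into a site whose style includes heavy blur and
  noise necessarily produces images that segment *worse* than a pristine
  source — segmentation-consistency comparisons across sites of unequal
  segmentability conflate this with model error. The converse direction
  (harmonizing a noisy site's images into the clean site) improves
  segmentation.
* Effective resolution partially travels with the content code at
  downsampling 2: the model preserves detail it is given but only weakly
  restores detail removed by prior resolution degradation. Stronger
  restoration requires coarser content (at a reconstruction cost) or far
  longer adversarial training.
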