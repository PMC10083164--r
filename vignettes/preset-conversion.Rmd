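---
title: "Unpaired conversion of OCT B-scans between scanning presets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired conversion of OCT B-scans between scanning presets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octpreset)
```

## The problem

Optical coherence tomography scanners trade scanned area against image
quality. Every tomogram is built by averaging several B-scans taken at the
same retinal location; averaging suppresses speckle — the multiplicative
interference noise that dominates OCT image quality — but costs acquisition
time that involuntary eye movement limits. The two volume presets most used
clinically sit at the two ends of this trade-off:

* **Macular Cube**: 9 B-scans averaged per tomogram, 25 slices over a
  20°×20° fundus patch — many, noisy images;
* **Seven Lines**: 25 averages, 7 slices over a 30°×5° strip — few, clean
  images.

The visual gap between the presets fragments datasets and starves
computer-aided diagnosis models of high-quality training data. This package
implements an unpaired translation approach: two generative models learn,
without any paired examples, to restyle images of one preset as the other
while preserving the underlying tissue structure, together with the
quality-driven model selection and validation machinery around them.

## The translation model

Conversion is a contrastive unpaired translation GAN. The generator
$G = G_{dec} \circ G_{enc}$ is a residual encoder–decoder; a patch
discriminator $D$ is trained in parallel to tell target-preset images from
generated ones, giving the adversarial objective

$$\mathcal{L}_{GAN}(X, Y) = \mathbb{E}_{y\sim Y} \log D(y) +
  \mathbb{E}_{x\sim X} \log(1 - D(G(x))).$$

`adversarial_loss()` implements this literal form (`mode = "vanilla"`,
with the non-saturating generator variant $-\log D(G(x))$) as well as a
least-squares form that replaces the logarithms with squared-error targets
1/0. Training defaults to `least_squares`: the architecture family this
generator belongs to is conventionally trained with the least-squares
objective, which is markedly more stable at the small scale this package
targets, while the vanilla form remains available and is what the loss
unit tests pin down.

Structure preservation comes from a patchwise noise-contrastive loss.
Feature columns are read off selected encoder layers
$l \in \{0, 4, 8, 12, 16\}$ (atomic layers counted from the input, so tap
0 is the raw patch) for both the input image and its translation, embedded
by a per-layer two-layer MLP $H_l$ and unit-normalised. For a location $s$,
the embedding of the translated patch is the query $\hat z_l^s$, the
same-location embedding of the original is the positive $z_l^s$, and the
other sampled locations of the *same original image* are the negatives
$z_l^{S\setminus s}$:

$$\ell(q, q^+, q^-) = -\log\frac{\exp(q\cdot q^+/\tau)}
 {\exp(q\cdot q^+/\tau) + \sum_{n=1}^N \exp(q\cdot q_n^-/\tau)},
 \qquad \tau = 0.07.$$

`nce_term()` computes this with a log-sum-exp stabilisation;
`patchwise_nce_loss()` averages it over layers and sampled locations
(an average rather than a raw double sum — the constant factor is absorbed
by the loss weights $\lambda_X, \lambda_Y$, both 1 by default). The
generator objective adds the same loss computed on target-class images fed
through $G$ (the `NCE_Y` identity regulariser). Unit normalisation of the
embeddings is required for a temperature as sharp as 0.07 to be meaningful.

### Training schedule

`training_config()` carries the full-scale recipe: Adam with
$\beta_1 = 0.5$, $\beta_2 = 0.999$, learning rate $2\times 10^{-4}$ held
for 200 epochs and decayed linearly to zero over the last 200 of 400;
inputs resized to 286 and randomly cropped to 256; a generator checkpoint
every 20 epochs (20 checkpoints in total). `lr_at_epoch()` and
`checkpoint_epochs()` expose the schedule as pure functions.

### Implementation

No deep-learning framework is used: the networks are built on a small
tape-based layer library inside the package (convolutions through
Rcpp/Armadillo im2col kernels, instance normalisation, residual blocks,
nearest-neighbour upsampling, manual backward passes). Every backward pass
is validated against finite differences in the test suite. Batches are of
size one, as is conventional for this architecture family. The generator
output is squashed onto $[0,1]$ by a scaled tanh; arbitrary input sizes are
reflection-padded to the stride multiple and cropped back after conversion.

## The synthetic phantom

The clinical dataset behind this methodology is private, so the package
ships a generator of layered speckled phantoms
(`sample_phantom_spec()`, `make_reflectivity_map()`, `simulate_bscan()`)
that reproduces the *statistical* contrast between the presets:

* a piecewise-constant reflectivity map with four smooth, near-parallel
  sinusoid-plus-tilt interfaces (bright superficial band, darker plexiform
  band, brighter outer band, attenuated bottom — ILM/choroid analogues
  giving the contrastive loss structure to anchor on);
* fully developed speckle: each of $L$ looks multiplies the map by i.i.d.
  unit-mean exponential intensity noise, and the frames are averaged. This
  is the standard coherent-imaging model; on the linear (pre-compression)
  intensities the equivalent number of looks
  $\mathrm{ENL} = \bar x^2/s^2$ of a homogeneous region recovers $L$, and
  the two presets differ *only* in $L$ (9 vs 25) given the same anatomy;
* optional (default-on) logarithmic display compression,
  $\log(1 + 100 I)/\log(1+101\cdot\mathbb{1})$-style, since OCT images are
  viewed log-compressed. Quantitative ENL statements hold pre-compression;
  `speckle_intensity()` exposes that stage directly.

Images are intensity-normalised to $[0,1]$ (the acquisition pipeline's
normalisation is not documented for the original study; this choice is
recorded here). What the phantom does **not** model: pathology, motion
artefacts, vendor post-processing, axial point-spread blur, depth-dependent
attenuation within a layer. Passing tests on phantoms therefore demonstrate
the machinery's correctness and the direction of its effects, not clinical
image fidelity.

Each phantom also yields ground-truth quality-metric annotations
(`auto_annotation()`): a background rectangle in the tissue-free band above
the first interface and a homogeneous ROI inside the first tissue layer.

## Quality assessment and checkpoint selection

`enl()` and `cnr()` implement the referenceless speckle estimators
$\mathrm{ENL} = \bar x_{BG}^2 / s_{BG}^2$ and
$\mathrm{CNR} = (\bar x_{ROI} - \bar x_{BG})/s_{BG}$ with the sample
(n−1) variance — the convention is recorded so results are reproducible
bit-for-bit. Both are invariant to positive rescaling, CNR also to offsets;
constant regions raise errors rather than returning infinities.

`brisque_features()` natively implements the 36-dimensional
natural-scene-statistics feature vector of the BRISQUE evaluator:
mean-subtracted contrast-normalised coefficients (7×7 Gaussian weighting,
σ = 7/6), a generalised-Gaussian fit of the coefficients plus asymmetric
generalised-Gaussian fits of the four orientation products, at two scales.
The canonical regression stage is a support-vector model trained on an
externally rated corpus of pristine and distorted images — data this
package cannot ship — so the scorer is pluggable. The shipped default,
`fit_brisque_scorer()`, is trained in the same spirit on two anchor sets
supplied by the caller: a Fisher discriminant axis through the 36 features
pointing from a high-quality reference set (in the pipeline, the original
Seven Lines images) towards a low-quality distorted set (the original
Macular Cube images), standardised so the reference sits near zero.
Higher score = lower perceptual quality, preserving the BRISQUE
convention and — importantly — giving the score an explicit quality
*axis*, so that "highest mean score" identifies the noisiest checkpoint
rather than merely the most unusual one (a pure distance-to-reference
scorer was tried first and failed exactly there: early, artifact-heavy
checkpoints are far from the reference without being noisy). Any
`function(features) -> score` can be substituted.

GAN losses converge to an uninformative equilibrium, so the stopping point
cannot be read off the loss curves. Instead every checkpoint's generated
set is scored (`evaluate_checkpoints()`) and `select_checkpoint()` picks
the epoch with the lowest mean score for the model generating the clean
preset and the highest for the model generating the noisy preset, ties
resolved to the earliest epoch.

## The separability experiment

`split_dataset()` partitions the originals 60/20/20 with the
floor-remainder rule (1034 images → 622/206/206), class-balanced to within
one image; sizes depend only on `n`, memberships only on the seed.
`train_classifier()` fits a small strided CNN whose head reads global
channel statistics — the mean and log standard deviation of every
stage's feature maps, not only the deepest — because the preset difference
is a noise-texture difference: fine-scale statistics that repeated
stride-2 subsampling averages away (with last-stage average pooling alone
the net plateaued at chance). Inputs are per-image min-max normalised,
augmentation is horizontal flips, gradients are averaged over mini-batches
of 8, and three seeded restarts are trained with the best-validation-loss
restart kept (tiny nets on tiny data occasionally land in a poor basin).
The experiment tests the conversion, not classifier capacity; a
DenseNet-scale backbone would add nothing at 64×64 and is not provided.
Training is early-stopped at the epoch of minimal validation loss with
the full curves retained. `synthetic_separability_test()` then classifies converted images:
positives are images of the target class, so the design has no true
negatives or false positives and specificity is uncomputable — the
headline number is the fraction of conversions assigned their target
preset.

## Desk-scale experiment sizes

The shipped `"desk"` pipeline preset and the test suite run: 64×64
phantoms, 100 images per preset, generator width 16 with 3 residual blocks
(encoder taps {0, 4, 8, 12}), 64 contrastive locations per layer,
64-dimensional embeddings, 10 epochs per direction with a checkpoint every
3 epochs, and a 16-epoch classifier. These sizes keep a two-direction
training run in the ten-minute range on a single CPU core while remaining
large enough for the directional effects — ENL moving towards the target
preset and conversions being classified as it — to be stable across seeds.
The full-scale configuration (width 64, nine residual blocks, 286/256,
400 epochs) is exposed via `training_config()` and
`pipeline_config("full")` but is only practical with serious compute.

## Numerical choices and degenerate inputs

* Weights are initialised $\mathcal{N}(0, 0.02)$; instance normalisation
  is non-affine with $\varepsilon = 10^{-5}$; embeddings are normalised
  with a $10^{-10}$ guard.
* Non-finite losses abort training with a stage-tagged diagnostic rather
  than silently continuing.
* One master seed fans out to phantom sampling, shuffling, crops, patch
  sampling and classifier training; every stage records its derived seed,
  and re-running a pipeline with the same configuration reproduces the
  same artifacts.
* Degenerate inputs (crossing layer boundaries, constant quality regions,
  constant images for BRISQUE, empty splits or image sets, undersized
  images for the generator) raise informative errors; the tie rule for
  checkpoint selection is the earliest epoch.

## Known limitations

* The phantom's realism is statistical, not anatomical; results transfer
  to clinical OCT only in direction, not magnitude.
* The default BRISQUE scorer measures distance to a reference
  distribution, not externally calibrated perceptual quality; its scale is
  not comparable to published BRISQUE scores.
* Batch-size-one training on a CPU bounds practical image counts and
  epochs; the full-scale recipe is configuration-complete but untested at
  scale in this package.
* Only single B-scans are converted; volume geometry (slices, field) is
  carried as metadata.
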