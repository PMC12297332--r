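---
title: "Token reconstruction: self-supervised pretraining for fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Token reconstruction: self-supervised pretraining for fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundistill)
```

## The problem

Foundation models for retinal imaging are pretrained without task labels and
then adapted to downstream tasks from their vector embeddings alone. The
dominant pretraining recipe in general computer vision — masked autoencoding,
which reconstructs the *pixels* of masked patches — is designed for training
from scratch on natural images with huge high-level diversity. Colour fundus
photographs are the opposite regime: all images look broadly alike, and the
clinically decisive information is often a handful of lesions a few pixels
wide. Pixel-space reconstruction under mean squared error rewards predicting
the *average* plausible patch, which is a blur; the presence of small lesions
barely moves that average. `fundistill` implements an alternative that
reconstructs in feature space instead.

## The objective

Two copies of the same vision transformer are made at the start of training:

* a **teacher**, frozen at the initial parameters, which sees **clean**
  images and emits its output tokens;
* a **student**, trainable, which sees **corrupted** versions of the same
  images and is penalised with the mean squared error between its output
  tokens and the teacher's, over all tokens and dimensions.

Corruption has two parts, applied jointly to each image:

1. **Token corruption** — a per-image ratio $r \sim U(0, \tfrac13)$ is drawn,
   and $\mathrm{round}(r \cdot n_\text{patches})$ patch embeddings, chosen
   uniformly without replacement, are replaced by a single trainable
   *corruption token*. Content is erased; position is kept (the positional
   embedding is added afterwards). Class and register tokens are never
   corrupted.
2. **Pixel noise** — i.i.d. Gaussian noise with standard deviation 0.2 added
   to the normalised image tensor.

The last image of every batch is fed to the student uncorrupted, so the model
stays calibrated for inference, where no corruption token appears.

To reconstruct the teacher's tokens for an erased patch, the student must
infer its content from the surrounding context — which structures co-occur,
and what tends to appear where. That is the knowledge the embeddings should
carry. A residual projector head (LayerNorm → linear → GELU → linear, output
multiplied element-wise by a learnable scale and **added** to the final
tokens) absorbs part of the reconstruction task; embeddings always come from
the backbone tokens without the projector. The scale is initialised at zero,
chosen so the head is an *exact* identity at initialisation: together with
the frozen teacher this gives the anchor property that the loss on an
uncorrupted batch at step 0 is exactly zero, which the test suite asserts
bitwise.

## Architecture

`vit_config()` describes a pre-norm vision transformer with a class token and
four *register tokens* — extra tokens not tied to any patch that give the
model somewhere to put global context. The reference configuration is the
small-model operating point: 392×392 input, 14-pixel patches (392 is not
divisible by 16), embedding dimension 384, so
$(392/14)^2 + 1 + 4 = 789$ tokens. The image embedding is the class token by
default (`pooling = "mean_patch"` is available); the pooling rule for this
family of models is a genuine open choice and is therefore a config option
rather than a constant.

Because no deep-learning framework is available to R, the forward pass,
backward pass, AdamW, gradient clipping and the schedule are implemented
directly in matrix code in this package. The backward pass is validated
against central finite differences in `test-model.R` (relative error below
$10^{-3}$ on every parameter tensor, typically $10^{-5}$).

## Training recipe

`train_config()` defaults: 120 epochs, batch size 128, AdamW with peak
learning rate $5\times10^{-5}$, $\beta_1 = 0.9$, $\beta_2 = 0.99$, weight
decay $5\times10^{-4}$ with **no decay on bias parameters**; cosine schedule
with 10 warmup epochs rising linearly from the minimum $5\times10^{-9}$ and a
final 20-epoch cool-down held at the minimum; global gradient norm clipped
to 0.1. All reference numerics are double precision; mixed precision is a GPU
concern that does not apply here.

Three details are underdetermined by the recipe and fixed here as documented
choices: the corruption ratio is drawn **per image** (maximises within-batch
diversity), pixel noise is added **after** normalisation (σ = 0.2 is
scale-meaningful on the normalised range), and the loss averages over tokens
before averaging over the batch. The teacher is strictly frozen — no momentum
or EMA update — and the suite asserts its parameters are bit-identical before
and after training.

## Preprocessing and augmentation

The cache pipeline (`detect_fundus_region()`, `standardize_to_square()`)
detects the fundus disc as the largest 4-connected component of pixels above
5% of the maximum grey intensity, crops black side space, pads the shorter
dimension symmetrically with black (an odd leftover row goes to the bottom),
and resizes to 1024². The detection algorithm and threshold are not
prescribed anywhere; grey-mean + threshold + largest component is the
simplest robust choice for dark-background fundus photographs and both knobs
are exposed. Downstream evaluation deliberately uses plain resize +
`normalize_channels()` only, so every backbone sees identically prepared
inputs; the green scheme is mean = sd = 0.5 per channel, the alternative is
the ImageNet constants.

Training-time augmentation (`augment_config()`): colour jitter and rotation
25% of the time (strength ±0.1, ±10° — "slight" is unquantified upstream, so
both are configurable), black side padding of 33–150 px per side 10% of the
time (left and right widths drawn independently), global rescale by 80–120%,
then one of three resize modes chosen uniformly: plain resize, random resized
crop keeping 70–100% of the area, or a centre crop after 1.3× upscale. The
stochastic plan is sampled separately (`sample_augment_plan()`) from its
application, so branch frequencies are audited cheaply: the suite checks
25% ± 2, 10% ± 1, and a χ² test of mode uniformity over 30,000 draws.

## Evaluation protocol

* **Linear probing** (`fit_linear_probe()`): ridge logistic regression on
  standardised embeddings, standardisation estimated on the training set
  only. The penalty is `lambda = 1/n`, the exact algebraic image of a
  unit-strength L2 penalty in the scikit-learn parameterisation the protocol
  references; the probe is deterministic because the penalised likelihood is
  strictly concave. A binary probe on 384-dimensional embeddings has exactly
  385 parameters. Graded targets (5-way retinopathy, 3-way macular edema) get
  a single multinomial fit; per-grade AUCs are then computed one-vs-rest from
  its predicted probabilities (how the reference protocol derives per-class
  AUCs from the multinomial fit is unstated; this is the package's choice).
* **2-D projections** (`fit_projection()`): PCA (first two components,
  verified against an eigendecomposition oracle) and UMAP with cosine metric,
  fixed `random_state` and single-threaded layout for determinism; the
  sensitivity variant runs UMAP on the first 100 principal components. UMAP
  itself is delegated to the `umap-learn` implementation through the system
  `python`; the package only marshals matrices in and out, and
  `predict_projection()` re-fits deterministically from the stored training
  rows before transforming unseen rows, so the transform is frozen.
  2-D probes (`probe_2d()`) are a single binary logistic model on the raw
  coordinates — deliberately *not* rescaled, since distances in the
  projection are meaningful — and KNN with k = 5.
* **Transport** (`transport_evaluate()`): scaler, projection and classifier
  fitted on dataset A are applied frozen to dataset B; nothing is refitted.
* **Class filtering** (`select_nontrivial_classes()`): a class is kept iff at
  least one model scores strictly below AUC 0.95 on it; classes at exactly
  the threshold are dropped (strict reading of "less than"), and dropped
  classes remain in evaluation sets as negatives.

## Statistical comparison

`bootstrap_auc()` resamples the test set 100 times at full size, with the
*same* index sets for every model, and reports median AUCs; resamples missing
a class are redrawn (plain, non-stratified resampling otherwise — stratification
is not part of the protocol). `compare_best_vs_second()` ranks models by
median AUC and runs a two-sided Wilcoxon signed-rank test across the 100
paired bootstrap AUCs of the top two; p < 0.05 is a win, otherwise a tie.
Zero differences are discarded (the classic signed-rank policy); if all 100
differences are zero the methods are indistinguishable and p = 1 by
definition. The implementation is checked against exact enumeration of all
$2^n$ sign assignments for n ≤ 12. Wins and ties are tallied per target and
never aggregated across targets, and no confidence intervals are produced:
across shared bootstrap resamples the per-model metrics are strongly
dependent, so overlapping intervals would not mean what readers expect.

## Resource accounting

`a100_day_equivalent()` converts GPU hours to reference-GPU days via
`(hours/24) × n_gpus × relative_throughput`; `training_cost()` prices them at
an 8-GPU machine's hourly rate (default $30). The arithmetic reproduces the
canonical worked conversions (112 and 163 A100 days; 0.27 days for 8 hours on
a consumer card at 0.82 relative throughput; $10,080, $14,670, $24.30).
Emission conversion is exposed only as a hook taking a user-supplied
kg-CO₂-per-kWh factor — emission factors are provider-, region- and
time-specific and shipping one would be false precision.

## The synthetic generator, and what passing tests show

`generate_fundus_image()` renders what matters for exercising this pipeline:
a circular retina disc on black, dark vessel polylines (cosmetic,
label-free), a bright optic disc, grade-dependent lesion specks of 2–4 px
radius, and the two cropping artifacts common in public datasets (black side
bars; top/bottom truncation), with exact geometry recorded as ground truth.
Two generator choices are deliberate: per-image illumination varies by
U(0.75, 1.05), and lesions are low-contrast relative to the retina under the
same illumination — so grade information lives in *small structure*, not in
global brightness statistics, mirroring the domain. Patients contribute
multiple images sharing one grade, which is what patient-level splitting
needs to be tested against.

What the fixtures do **not** emulate: photorealistic texture, camera colour
profiles, multi-camera cluster structure, image-quality failures, or
label noise. Passing probes on these fixtures demonstrates that the
machinery is correct — leakage-free standardisation, frozen transforms,
paired bootstraps — not that any particular AUC would be obtained on real
fundus data.

Desk-scale study conditions (stated here as the package's choices): the
training-progress check uses 256 synthetic 64² images from 128 patients, a
backbone with embedding dimension 32, depth 2, patch 8, batch 16, 200
optimisation steps, fixed seed. Under these conditions the corrupted-batch
loss falls well below half its initial value, and the linear probe on the
trained embeddings beats the probe on the same architecture's embeddings *at
initialisation* on the lesion-presence target. That baseline is the
standard "does pretraining help" ablation; at this miniature scale the
improvement is small and seed-dependent (where the fixture task saturates
near AUC 1 it can vanish), which is the honest picture — the large effects
reported for full-scale models are out of desk-scale reach.

## Numerical choices and degenerate inputs

* LayerNorm uses ε = 1e-6; GELU is exact (`x·Φ(x)`).
* Truncated-normal init (sd 0.02, clipped at ±2 sd); projector scale exactly
  zero; the checkpoint loader restores tensors by name and reports every
  shape mismatch in one error.
* `round()` converts the corruption ratio to a count, so the masked fraction
  can exceed 1/3 by at most `1/(2 n_patches)`.
* Odd crop/pad splits: the extra row or column goes to the bottom/right.
* All-black images raise an "empty fundus" error; degenerate crop boxes are
  rejected; tiny augmentation inputs are upscaled to 32 px before the
  pipeline; embeddings of unreadable images are skipped with a warning.
* Checkpoint stripping keeps exactly the inference tensors (dropping
  optimizer moments, the projector head and the corruption token) and is
  idempotent; embeddings are bitwise unchanged.

## Limitations

The transformer runs on CPU in R: it is intended for method verification,
small-scale experimentation and teaching, not for pretraining at the
full 75,000-image scale, which needs GPU tooling. UMAP requires a Python
runtime with `umap-learn` on the PATH. The synthetic generator is a test
harness, not a simulator of real retinal pathology.
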