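# fundistill

Self-supervised pretraining of a small vision transformer on colour fundus
photographs by **token reconstruction**, with the full evaluation workflow
around it — implemented in R, end to end.

## The idea

Masked-autoencoder pretraining reconstructs the *pixels* of masked patches.
Under mean squared error the optimal pixel prediction is the average of all
plausible patches — a blur — so the presence of a few tiny lesions, which is
what separates a healthy retina from a diseased one, barely moves the loss.
`fundistill` trains in *feature space* instead:

* a **teacher** — a frozen copy of the network at its initial parameters —
  sees clean images and emits output tokens;
* a **student** — the trainable copy — sees corrupted versions of the same
  images: a per-image fraction `r ~ U(0, 1/3)` of patch embeddings replaced
  by a trainable *corruption token*, plus pixel-wise Gaussian noise
  (σ = 0.2); the last image of each batch stays clean;
* the loss is the mean squared error between student and teacher tokens,
  with a zero-initialised residual projector head (LayerNorm → linear →
  GELU → linear, scaled element-wise) on the student side.

To predict the teacher's tokens for an erased patch the student must use the
surrounding context — the structure and co-dependencies of retinal images.
The backbone is a pre-norm vision transformer with a class token and four
register tokens: at the default 392×392 / patch 14 / dim 384 configuration,
`(392/14)² + 1 + 4 = 789` tokens and ~22M parameters. Forward pass, backward
pass, AdamW (no weight decay on biases), gradient clipping and the
warmup–cosine–cooldown schedule are written directly in R matrix code and
verified against finite differences; preprocessing, probing, projection and
statistics lean on EBImage, glmnet, pROC, class and `umap-learn`.

The package also ships the surrounding workflow: a deterministic synthetic
fundus generator (so everything is testable without data downloads),
fundus-area detection and square crop/pad preprocessing, the training-time
augmentation recipe, embedding extraction/persistence and checkpoint
stripping, linear probing with train-only standardisation, PCA/UMAP 2-D
projections with frozen transforms, external-transport evaluation, paired
100-bootstrap median AUC with two-sided Wilcoxon signed-rank comparison, and
GPU-day/cost accounting.

## Worked example

Fit a 385-parameter linear probe on embeddings, compare two models with the
paired bootstrap + Wilcoxon machinery, and account for training resources:

```r
library(fundistill)
set.seed(1)

blobs <- generate_embedding_blobs(n_per_class = 500, d = 384, separation = 3, seed = 1)
split <- c(rep(TRUE, 400), rep(FALSE, 100), rep(TRUE, 400), rep(FALSE, 100))

probe <- fit_linear_probe(blobs$embeddings[split, ], blobs$labels[split])
n_parameters(probe)
#> [1] 385

scores_a <- predict_probe(probe, blobs$embeddings[!split, ])
scores_b <- scores_a + rnorm(200, 0, 0.35)        # a deliberately noisier model
boot <- bootstrap_auc(cbind(probe = scores_a, noisy = scores_b),
                      blobs$labels[!split], n_boot = 100, seed = 7)
round(median_auc(boot), 4)
#>  probe  noisy
#> 0.9444 0.8599
compare_best_vs_second(boot)
#> probe (median AUC 0.9444) vs noisy (0.8599): p = 3.96e-18 -> win

embedding_storage(1e6, 384)$fold_ratio            # vs a 1024-d reference
#> [1] 2.67
a100_day_equivalent(compute_spec(8, 1, 0.82))     # 8 h on a consumer GPU
#> [1] 0.27
training_cost(0.27)
#> [1] 24.3
```

The 385 parameters are one weight per embedding dimension plus an intercept.
The two models are compared on *identical* bootstrap resamples, so the
Wilcoxon signed-rank test across the 100 paired AUCs is decisive even when
the bootstrap spread is wide; `p < 0.05` counts as a win, otherwise a tie.

Pretraining itself runs the same way at any scale:

```r
spec <- synthetic_spec(image_side = 64, bar_prob = 0, crop_prob = 0, seed = 42)
ds   <- generate_dataset(spec, n_patients = 128, images_per_patient = 2, seed = 42)
cfg  <- vit_config(image_side = 64, patch_side = 8, embed_dim = 32, depth = 2, heads = 4)
run  <- train_token_reconstruction(build_student(cfg, seed = 42), ds$images,
                                   train_config(batch_size = 16, seed = 42),
                                   corruption_spec(), n_steps = 200)
emb  <- compute_embeddings(run$model, ds$images)   # one 32-d vector per image
```

A thin command-line front end for the same operations (synthesis, prep,
pretraining, embedding, checkpoint stripping, probing, comparison, resource
accounting) is installed at `inst/cli/fundistill`.

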