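# Token-reconstruction pretraining --------------------------------------------
#
# The objective: a frozen copy of the network (the teacher) sees clean images
# and emits output tokens; the trainable student sees corrupted versions of
# the same images -- a per-image random fraction of patch embeddings replaced
# by a trainable corruption token, plus pixel-wise Gaussian noise -- and is
# penalised with the mean squared error between its output tokens (backbone
# final tokens plus the scaled projector residual) and the teacher's. The last
# image in every batch is fed to the student uncorrupted so the model stays
# robust to the absence of corruption tokens.

#' Corruption specification
#'
#' @param ratio_upper Upper bound of the per-image corruption ratio; the ratio
#'   is drawn from `Uniform(0, ratio_upper)` (default 1/3).
#' @param noise_sigma Standard deviation of the pixel-wise Gaussian noise,
#'   applied in normalised intensity space (default 0.2).
#' @param keep_last_clean Feed the last image of each batch uncorrupted
#'   (default TRUE).
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(ratio_upper = 1 / 3, noise_sigma = 0.2,
                            keep_last_clean = TRUE) {
  stopifnot(ratio_upper >= 0, ratio_upper <= 1, noise_sigma >= 0)
  structure(list(ratio_upper = ratio_upper, noise_sigma = noise_sigma,
                 keep_last_clean = isTRUE(keep_last_clean)),
            class = "corruption_spec")
}

#' Sample a per-image corruption mask
#'
#' Draws a ratio `r ~ Uniform(0, ratio_upper)` and marks `round(r * n_patches)`
#' patch positions, chosen uniformly without replacement.
#'
#' @param n_patches Number of patch tokens.
#' @param spec A [corruption_spec()].
#' @return Logical vector of length `n_patches`; the drawn ratio is attached
#'   as attribute `"ratio"`.
#' @export
sample_corruption_mask <- function(n_patches, spec = corruption_spec()) {
  stopifnot(n_patches > 0)
  r <- stats::runif(1, 0, spec$ratio_upper)
  k <- round(r * n_patches)
  mask <- rep(FALSE, n_patches)
  if (k > 0) mask[sample.int(n_patches, k)] <- TRUE
  attr(mask, "ratio") <- r
  mask
}

#' Add pixel-wise Gaussian noise
#'
#' @param x Numeric array (normalised image tensor).
#' @param sigma Noise standard deviation (>= 0).
#' @return `x` plus i.i.d. `N(0, sigma^2)` noise; `x` unchanged when
#'   `sigma = 0`.
#' @export
add_pixel_noise <- function(x, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  x + array(stats::rnorm(length(x), 0, sigma), dim(x))
}

#' Mean-squared token reconstruction loss
#'
#' Mean over all tokens and all dimensions of the squared difference between
#' the student and teacher token matrices.
#'
#' @param student,teacher Numeric matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
token_reconstruction_loss <- function(student, teacher) {
  if (!identical(dim(student), dim(teacher))) {
    stop("student and teacher token sets differ in shape", call. = FALSE)
  }
  mean((student - teacher)^2)
}

#' Training configuration
#'
#' Defaults follow the published recipe: 120 epochs at batch size 128 with
#' AdamW (peak learning rate 5e-5, betas 0.9/0.99, weight decay 5e-4 with none
#' on biases), a cosine schedule with 10 linear warmup epochs from the minimum
#' 5e-9 and a final 20-epoch cool-down held at the minimum, and the global
#' gradient norm clipped to 0.1.
#'
#' @param epochs,batch_size,peak_lr,min_lr,beta1,beta2,weight_decay,warmup_epochs,cooldown_epochs,grad_clip_norm
#'   Scalars as described above.
#' @param seed Integer seed for batching, corruption and noise.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 120L, batch_size = 128L, peak_lr = 5e-5,
                         min_lr = 5e-9, beta1 = 0.9, beta2 = 0.99,
                         weight_decay = 5e-4, warmup_epochs = 10L,
                         cooldown_epochs = 20L, grad_clip_norm = 0.1,
                         seed = 1L) {
  stopifnot(warmup_epochs + cooldown_epochs < epochs, min_lr <= peak_lr,
            batch_size >= 1, grad_clip_norm > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 peak_lr = peak_lr, min_lr = min_lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 cooldown_epochs = as.integer(cooldown_epochs),
                 grad_clip_norm = grad_clip_norm, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear from `min_lr` to `peak_lr` over the warmup epochs, cosine decay from
#' `peak_lr` back to `min_lr` until `epochs - cooldown_epochs`, then constant
#' at `min_lr` for the final cool-down epochs.
#'
#' @param epoch Zero-based epoch index, `0 <= epoch < epochs`.
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  if (any(epoch < 0) || any(epoch >= config$epochs)) {
    stop("`epoch` out of range [0, epochs)", call. = FALSE)
  }
  cos_end <- config$epochs - config$cooldown_epochs
  vapply(epoch, function(e) {
    if (e < config$warmup_epochs) {
      config$min_lr + (config$peak_lr - config$min_lr) * e / config$warmup_epochs
    } else if (e >= cos_end) {
      config$min_lr
    } else {
      t <- (e - config$warmup_epochs) / (cos_end - config$warmup_epochs)
      config$min_lr + 0.5 * (config$peak_lr - config$min_lr) * (1 + cos(pi * t))
    }
  }, numeric(1))
}

#' Train a student by token reconstruction
#'
#' The teacher is a frozen, parameter-identical copy of the student at
#' initialisation (taken automatically when `teacher = NULL`) and is never
#' updated. Per step: a batch is drawn; every image is (optionally) augmented
#' and normalised; the teacher receives the clean tensor; the student receives
#' the same tensor with pixel noise added and a sampled corruption mask,
#' except the batch's last image which is fed clean; MSE token gradients are
#' backpropagated, globally clipped, and applied with AdamW (no weight decay
#' on biases).
#'
#' @param model A `vit_model` student.
#' @param images List of `fundus_image`s or `[0,1]` arrays (any size; resized
#'   to the model's input side).
#' @param train_cfg A [train_config()].
#' @param corr_spec A [corruption_spec()].
#' @param aug_cfg Optional [augment_config()] applied before normalisation;
#'   its `target_side` must equal the model's `image_side`.
#' @param scheme [norm_scheme()] used for both teacher and student inputs.
#' @param n_steps Number of optimisation steps.
#' @param steps_per_epoch Steps mapped to one schedule epoch (default
#'   `ceiling(length(images) / batch_size)`).
#' @param teacher Optional explicit teacher `vit_model` (must match shapes).
#' @param seed Integer seed; overrides `train_cfg$seed` when given.
#' @return List with `model` (trained student), `teacher` (untouched), and
#'   `history`: a data.frame with step, epoch, lr, loss and post-clip gradient
#'   norm.
#' @export
train_token_reconstruction <- function(model, images,
                                       train_cfg = train_config(),
                                       corr_spec = corruption_spec(),
                                       aug_cfg = NULL,
                                       scheme = norm_scheme("green"),
                                       n_steps = 100L,
                                       steps_per_epoch = NULL,
                                       teacher = NULL,
                                       seed = train_cfg$seed) {
  stopifnot(inherits(model, "vit_model"), length(images) >= 1)
  if (is.null(teacher)) {
    teacher <- model
  } else {
    for (nm in names(model$params)) {
      if (!identical(dim_or_len(model$params[[nm]]), dim_or_len(teacher$params[[nm]]))) {
        stop("teacher/student shape mismatch at ", nm, call. = FALSE)
      }
    }
  }
  cfg <- model$config
  lay <- token_layout(cfg)
  if (is.null(steps_per_epoch)) {
    steps_per_epoch <- max(1L, ceiling(length(images) / train_cfg$batch_size))
  }
  B <- min(train_cfg$batch_size, length(images))
  decay_mask <- weight_decay_mask(model)

  opt_m <- lapply(model$params, function(x) x * 0)
  opt_v <- opt_m
  hist <- data.frame(step = integer(n_steps), epoch = integer(n_steps),
                     lr = numeric(n_steps), loss = numeric(n_steps),
                     grad_norm = numeric(n_steps))

  prep_one <- function(img) {
    px <- pixels_of(img)
    if (!is.null(aug_cfg)) {
      px <- augment_image(px, aug_cfg)
    } else if (!identical(dim(px)[1:2], c(cfg$image_side, cfg$image_side))) {
      px <- resize_image(px, cfg$image_side, cfg$image_side)
    }
    normalize_channels(px, scheme)
  }

  with_seed(seed, {
    for (step in seq_len(n_steps)) {
      epoch <- min((step - 1L) %/% steps_per_epoch, train_cfg$epochs - 1L)
      lr <- lr_at_epoch(epoch, train_cfg)
      idx <- sample.int(length(images), B, replace = length(images) < B)
      grads <- NULL
      loss_sum <- 0
      for (b in seq_len(B)) {
        xn <- prep_one(images[[idx[b]]])
        Yt <- vit_forward(teacher, xn)$XF
        clean <- corr_spec$keep_last_clean && b == B
        if (clean) {
          xs <- xn; mask <- NULL
        } else {
          xs <- add_pixel_noise(xn, corr_spec$noise_sigma)
          mask <- sample_corruption_mask(lay$n_patches, corr_spec)
          if (!any(mask)) mask <- NULL
        }
        fw <- vit_forward(model, xs, mask = mask, projector = TRUE, cache = TRUE)
        diff <- fw$Y - Yt
        loss_sum <- loss_sum + mean(diff^2)
        dY <- 2 * diff / (length(diff) * B)
        gb <- vit_backward(model, fw$cache, dY)
        if (is.null(grads)) {
          grads <- gb
        } else {
          for (nm in names(gb)) grads[[nm]] <- grads[[nm]] + gb[[nm]]
        }
      }
      # global-norm clipping
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (gn > train_cfg$grad_clip_norm) {
        sc <- train_cfg$grad_clip_norm / gn
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] * sc
      }
      # AdamW with decoupled weight decay, none on biases
      bc1 <- 1 - train_cfg$beta1^step
      bc2 <- 1 - train_cfg$beta2^step
      for (nm in names(grads)) {
        opt_m[[nm]] <- train_cfg$beta1 * opt_m[[nm]] + (1 - train_cfg$beta1) * grads[[nm]]
        opt_v[[nm]] <- train_cfg$beta2 * opt_v[[nm]] + (1 - train_cfg$beta2) * grads[[nm]]^2
        upd <- (opt_m[[nm]] / bc1) / (sqrt(opt_v[[nm]] / bc2) + 1e-8)
        wd <- if (decay_mask[[nm]]) train_cfg$weight_decay else 0
        model$params[[nm]] <- model$params[[nm]] - lr * (upd + wd * model$params[[nm]])
      }
      hist$step[step] <- step
      hist$epoch[step] <- epoch
      hist$lr[step] <- lr
      hist$loss[step] <- loss_sum / B
      hist$grad_norm[step] <- min(gn, train_cfg$grad_clip_norm)
    }
  })
  list(model = model, teacher = teacher, history = hist)
}
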