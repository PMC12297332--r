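# Vision transformer student --------------------------------------------------
#
# A pre-norm vision transformer with a class token, extra "register" tokens
# that are not tied to any image patch, a trainable corruption token that can
# replace patch embeddings, and a residual MLP projector head whose output is
# scaled by a learnable element-wise vector (initialised to zero, so the head
# is an exact identity at initialisation). Forward and backward passes are
# written out explicitly in matrix form; gradients are verified against finite
# differences in the test suite.

#' Backbone configuration
#'
#' Token count is `has_class_token + n_registers + (image_side / patch_side)^2`;
#' the default 392/14 grid with one class and four register tokens gives 789
#' tokens of dimension 384.
#'
#' @param image_side Input side in pixels (default 392).
#' @param patch_side Patch side in pixels (default 14; must divide
#'   `image_side`).
#' @param embed_dim Token dimension (default 384; must be divisible by
#'   `heads`).
#' @param depth Number of transformer blocks (default 12).
#' @param heads Attention heads (default 6).
#' @param n_registers Register tokens (default 4).
#' @param has_class_token Whether a class token is prepended (default TRUE).
#' @param mlp_ratio Hidden width of the block MLP relative to `embed_dim`.
#' @param pooling Which tokens form the image embedding: the class token
#'   (default) or the mean over patch tokens.
#' @return An object of class `vit_config`.
#' @export
vit_config <- function(image_side = 392L, patch_side = 14L, embed_dim = 384L,
                       depth = 12L, heads = 6L, n_registers = 4L,
                       has_class_token = TRUE, mlp_ratio = 4L,
                       pooling = c("class_token", "mean_patch")) {
  if (image_side %% patch_side != 0) {
    stop("`image_side` must be divisible by `patch_side`", call. = FALSE)
  }
  if (embed_dim %% heads != 0) {
    stop("`embed_dim` must be divisible by `heads`", call. = FALSE)
  }
  stopifnot(depth >= 1, n_registers >= 0)
  structure(list(image_side = as.integer(image_side),
                 patch_side = as.integer(patch_side),
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 heads = as.integer(heads), n_registers = as.integer(n_registers),
                 has_class_token = isTRUE(has_class_token),
                 mlp_ratio = as.integer(mlp_ratio),
                 pooling = match.arg(pooling)),
            class = "vit_config")
}

#' Token count and block layout for a configuration
#' @param config A [vit_config()].
#' @return List with `n_tokens`, `n_patches`, and index vectors `class`,
#'   `register`, `patch` into the token matrix rows.
#' @export
token_layout <- function(config) {
  np <- (config$image_side %/% config$patch_side)^2
  ncls <- as.integer(config$has_class_token)
  list(n_tokens = ncls + config$n_registers + np,
       n_patches = np,
       class = if (ncls) 1L else integer(0),
       register = if (config$n_registers > 0) ncls + seq_len(config$n_registers) else integer(0),
       patch = ncls + config$n_registers + seq_len(np))
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

#' Build a student model
#'
#' Initialises all backbone tensors (truncated-normal weights, zero biases,
#' unit LayerNorm gains), the corruption token, and the residual projector
#' head with its learnable scale set exactly to zero, so the projector has no
#' effect at initialisation. When `init_weights` is supplied (a named list of
#' arrays, e.g. from [load_checkpoint()]), tensors are loaded by name and any
#' shape mismatch is reported listing the offending tensors; parameters absent
#' from `init_weights` keep their fresh initialisation.
#'
#' @param config A [vit_config()].
#' @param init_weights Optional named list of arrays.
#' @param seed Integer seed for the fresh initialisation.
#' @return An object of class `vit_model` with elements `config` and `params`.
#' @export
build_student <- function(config = vit_config(), init_weights = NULL, seed = 1L) {
  lay <- token_layout(config)
  d <- config$embed_dim
  pdim <- config$patch_side^2 * 3L
  hid <- d * config$mlp_ratio
  params <- with_seed(seed, {
    p <- list(
      patch_W = matrix(trunc_normal(pdim * d), pdim, d),
      patch_b = numeric(d),
      pos_embed = matrix(trunc_normal(lay$n_tokens * d), lay$n_tokens, d),
      corruption_token = trunc_normal(d)
    )
    if (config$has_class_token) p$cls_token <- trunc_normal(d)
    if (config$n_registers > 0) {
      p$reg_tokens <- matrix(trunc_normal(config$n_registers * d),
                             config$n_registers, d)
    }
    for (l in seq_len(config$depth)) {
      pre <- sprintf("L%02d_", l)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      p[[paste0(pre, "qkv_W")]] <- matrix(trunc_normal(d * 3 * d), d, 3 * d)
      p[[paste0(pre, "qkv_b")]] <- numeric(3 * d)
      p[[paste0(pre, "proj_W")]] <- matrix(trunc_normal(d * d), d, d)
      p[[paste0(pre, "proj_b")]] <- numeric(d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
      p[[paste0(pre, "fc1_W")]] <- matrix(trunc_normal(d * hid), d, hid)
      p[[paste0(pre, "fc1_b")]] <- numeric(hid)
      p[[paste0(pre, "fc2_W")]] <- matrix(trunc_normal(hid * d), hid, d)
      p[[paste0(pre, "fc2_b")]] <- numeric(d)
    }
    p$lnf_g <- rep(1, d); p$lnf_b <- numeric(d)
    p$prj_ln_g <- rep(1, d); p$prj_ln_b <- numeric(d)
    p$prj_W1 <- matrix(trunc_normal(d * d), d, d); p$prj_b1 <- numeric(d)
    p$prj_W2 <- matrix(trunc_normal(d * d), d, d); p$prj_b2 <- numeric(d)
    p$prj_scale <- numeric(d)   # zero: residual head is an exact identity
    p
  })
  if (!is.null(init_weights)) {
    bad <- character(0)
    for (nm in names(init_weights)) {
      if (!nm %in% names(params)) next
      if (!identical(dim_or_len(params[[nm]]), dim_or_len(init_weights[[nm]]))) {
        bad <- c(bad, sprintf("%s: have %s, got %s", nm,
                              paste(dim_or_len(params[[nm]]), collapse = "x"),
                              paste(dim_or_len(init_weights[[nm]]), collapse = "x")))
      } else {
        params[[nm]] <- init_weights[[nm]]
      }
    }
    if (length(bad)) {
      stop("shape mismatch loading weights:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
    }
  }
  structure(list(config = config, params = params), class = "vit_model")
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @exportS3Method base::print
print.vit_model <- function(x, ...) {
  lay <- token_layout(x$config)
  np <- sum(vapply(x$params, function(p) length(p), numeric(1)))
  cat(sprintf("<vit_model %dx%d/%d, dim %d, depth %d, %d tokens, %s parameters>\n",
              x$config$image_side, x$config$image_side, x$config$patch_side,
              x$config$embed_dim, x$config$depth, lay$n_tokens,
              format(np, big.mark = ",")))
  invisible(x)
}

# --- primitive ops with hand-derived backward passes -------------------------

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_f <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_b <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dX = cache$inv * (dxhat - m1 - cache$xhat * m2),
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# Extract non-overlapping patches as a [n_patches x patch_side^2*3] matrix,
# patch rows ordered row-major over the patch grid.
patchify <- function(x, patch_side) {
  h <- dim(x)[1]
  n <- h %/% patch_side
  arr <- array(x, c(patch_side, n, patch_side, n, 3))
  pm <- aperm(arr, c(2, 4, 1, 3, 5))          # (grid row, grid col, a, b, ch)
  M <- matrix(pm, nrow = n * n)               # grid row varies fastest
  perm <- as.vector(t(matrix(seq_len(n * n), n, n)))
  M[perm, , drop = FALSE]
}

#' Replace selected patch embeddings with the corruption token
#'
#' Class and register tokens are never touched: corruption operates on the
#' patch block only, after the patch projection and before positional
#' embeddings are added, so position is retained while content is erased.
#'
#' @param patch_embeddings `n_patches x d` matrix.
#' @param mask Logical vector of length `n_patches`.
#' @param corruption_token Numeric `d`-vector.
#' @return The matrix with masked rows set to `corruption_token`.
#' @export
apply_corruption <- function(patch_embeddings, mask, corruption_token) {
  if (length(mask) != nrow(patch_embeddings)) {
    stop("mask length must equal the number of patches", call. = FALSE)
  }
  if (any(mask)) {
    patch_embeddings[mask, ] <- rep(corruption_token, each = sum(mask))
  }
  patch_embeddings
}

# Full forward pass. `x` is a normalised image_side^2 x 3 array. Returns the
# final-LN token matrix XF, the projector-residual output Y, and (optionally)
# every intermediate needed for the backward pass.
vit_forward <- function(model, x, mask = NULL, projector = FALSE, cache = FALSE) {
  cfg <- model$config; p <- model$params
  if (!identical(dim(x)[1:2], c(cfg$image_side, cfg$image_side))) {
    stop(sprintf("image must be %d x %d", cfg$image_side, cfg$image_side),
         call. = FALSE)
  }
  lay <- token_layout(cfg)
  d <- cfg$embed_dim; H <- cfg$heads; dh <- d %/% H
  patches <- patchify(x, cfg$patch_side)
  E <- patches %*% p$patch_W + rep(p$patch_b, each = lay$n_patches)
  if (!is.null(mask)) E <- apply_corruption(E, mask, p$corruption_token)
  X <- matrix(0, lay$n_tokens, d)
  if (cfg$has_class_token) X[lay$class, ] <- p$cls_token
  if (cfg$n_registers > 0) X[lay$register, ] <- p$reg_tokens
  X[lay$patch, ] <- E
  X <- X + p$pos_embed

  cc <- if (cache) list(patches = patches, mask = mask, X0 = X, layers = vector("list", cfg$depth))
  for (l in seq_len(cfg$depth)) {
    pre <- sprintf("L%02d_", l)
    lc <- list(Xin = X)
    ln1 <- layernorm_f(X, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    QKV <- ln1$Y %*% p[[paste0(pre, "qkv_W")]] +
      rep(p[[paste0(pre, "qkv_b")]], each = lay$n_tokens)
    O <- matrix(0, lay$n_tokens, d)
    A_list <- vector("list", H)
    for (h in seq_len(H)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      Q <- QKV[, idx, drop = FALSE]
      K <- QKV[, d + idx, drop = FALSE]
      V <- QKV[, 2 * d + idx, drop = FALSE]
      A <- softmax_rows(Q %*% t(K) / sqrt(dh))
      O[, idx] <- A %*% V
      if (cache) A_list[[h]] <- A
    }
    attn <- O %*% p[[paste0(pre, "proj_W")]] +
      rep(p[[paste0(pre, "proj_b")]], each = lay$n_tokens)
    X2 <- X + attn
    ln2 <- layernorm_f(X2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    H1 <- ln2$Y %*% p[[paste0(pre, "fc1_W")]] +
      rep(p[[paste0(pre, "fc1_b")]], each = lay$n_tokens)
    G <- gelu(H1)
    X <- X2 + G %*% p[[paste0(pre, "fc2_W")]] +
      rep(p[[paste0(pre, "fc2_b")]], each = lay$n_tokens)
    if (cache) {
      lc$ln1 <- ln1; lc$QKV <- QKV; lc$A <- A_list; lc$O <- O
      lc$X2 <- X2; lc$ln2 <- ln2; lc$H1 <- H1; lc$G <- G
      cc$layers[[l]] <- lc
    }
  }
  lnf <- layernorm_f(X, p$lnf_g, p$lnf_b)
  XF <- lnf$Y
  out <- list(XF = XF)
  if (cache) { cc$Xpre_lnf <- X; cc$lnf <- lnf }
  if (projector) {
    pln <- layernorm_f(XF, p$prj_ln_g, p$prj_ln_b)
    PH1 <- pln$Y %*% p$prj_W1 + rep(p$prj_b1, each = lay$n_tokens)
    PG <- gelu(PH1)
    P <- PG %*% p$prj_W2 + rep(p$prj_b2, each = lay$n_tokens)
    out$Y <- XF + sweep(P, 2, p$prj_scale, `*`)
    if (cache) { cc$pln <- pln; cc$PH1 <- PH1; cc$PG <- PG; cc$P <- P }
  }
  if (cache) out$cache <- cc
  out
}

# Backward pass for vit_forward(..., projector = TRUE, cache = TRUE), given
# the gradient of the loss with respect to the projector output Y. Returns a
# named list of gradients matching the parameter list.
vit_backward <- function(model, cache, dY) {
  cfg <- model$config; p <- model$params
  lay <- token_layout(cfg)
  d <- cfg$embed_dim; H <- cfg$heads; dh <- d %/% H
  g <- list()

  # projector residual: Y = XF + scale * P(XF)
  dXF <- dY
  g$prj_scale <- colSums(dY * cache$P)
  dP <- sweep(dY, 2, p$prj_scale, `*`)
  g$prj_W2 <- t(cache$PG) %*% dP
  g$prj_b2 <- colSums(dP)
  dPG <- dP %*% t(p$prj_W2)
  dPH1 <- dPG * gelu_grad(cache$PH1)
  g$prj_W1 <- t(cache$pln$Y) %*% dPH1
  g$prj_b1 <- colSums(dPH1)
  dpln <- dPH1 %*% t(p$prj_W1)
  lb <- layernorm_b(dpln, cache$pln, p$prj_ln_g)
  g$prj_ln_g <- lb$dg; g$prj_ln_b <- lb$db
  dXF <- dXF + lb$dX

  lb <- layernorm_b(dXF, cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX

  for (l in rev(seq_len(cfg$depth))) {
    pre <- sprintf("L%02d_", l)
    lc <- cache$layers[[l]]
    # MLP block: X = X2 + gelu(LN2(X2) W1 + b1) W2 + b2
    dmlp <- dX
    g[[paste0(pre, "fc2_W")]] <- t(lc$G) %*% dmlp
    g[[paste0(pre, "fc2_b")]] <- colSums(dmlp)
    dG <- dmlp %*% t(p[[paste0(pre, "fc2_W")]])
    dH1 <- dG * gelu_grad(lc$H1)
    g[[paste0(pre, "fc1_W")]] <- t(lc$ln2$Y) %*% dH1
    g[[paste0(pre, "fc1_b")]] <- colSums(dH1)
    dXn2 <- dH1 %*% t(p[[paste0(pre, "fc1_W")]])
    lb <- layernorm_b(dXn2, lc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb$dg; g[[paste0(pre, "ln2_b")]] <- lb$db
    dX2 <- dX + lb$dX
    # attention block: X2 = Xin + attn(LN1(Xin))
    dattn <- dX2
    g[[paste0(pre, "proj_W")]] <- t(lc$O) %*% dattn
    g[[paste0(pre, "proj_b")]] <- colSums(dattn)
    dO <- dattn %*% t(p[[paste0(pre, "proj_W")]])
    dQKV <- matrix(0, lay$n_tokens, 3 * d)
    for (h in seq_len(H)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      Q <- lc$QKV[, idx, drop = FALSE]
      K <- lc$QKV[, d + idx, drop = FALSE]
      V <- lc$QKV[, 2 * d + idx, drop = FALSE]
      A <- lc$A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(V)
      dS <- (dA - rowSums(dA * A)) * A
      dQKV[, idx] <- dS %*% K / sqrt(dh)
      dQKV[, d + idx] <- t(dS) %*% Q / sqrt(dh)
      dQKV[, 2 * d + idx] <- t(A) %*% dOh
    }
    g[[paste0(pre, "qkv_W")]] <- t(lc$ln1$Y) %*% dQKV
    g[[paste0(pre, "qkv_b")]] <- colSums(dQKV)
    dXn1 <- dQKV %*% t(p[[paste0(pre, "qkv_W")]])
    lb <- layernorm_b(dXn1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb$dg; g[[paste0(pre, "ln1_b")]] <- lb$db
    dX <- dX2 + lb$dX
  }

  g$pos_embed <- dX
  if (cfg$has_class_token) g$cls_token <- dX[lay$class, ]
  if (cfg$n_registers > 0) {
    g$reg_tokens <- dX[lay$register, , drop = FALSE]
  }
  dE <- dX[lay$patch, , drop = FALSE]
  mask <- cache$mask
  if (is.null(mask)) mask <- rep(FALSE, lay$n_patches)
  g$corruption_token <- if (any(mask)) colSums(dE[mask, , drop = FALSE]) else numeric(d)
  keep <- !mask
  g$patch_W <- t(cache$patches[keep, , drop = FALSE]) %*% dE[keep, , drop = FALSE]
  g$patch_b <- colSums(dE[keep, , drop = FALSE])
  g
}

#' Backbone output tokens for images
#'
#' Runs the backbone in evaluation mode (no corruption, no projector) and
#' returns the final-LayerNorm token matrix, the quantity the frozen teacher
#' produces and the student must reconstruct.
#'
#' @param model A `vit_model`.
#' @param images A single normalised `side x side x 3` array or a list of
#'   them.
#' @return For a single image, an `n_tokens x embed_dim` matrix with attribute
#'   `"layout"`; for a list, a list of such matrices.
#' @export
forward_tokens <- function(model, images) {
  one <- function(x) {
    out <- vit_forward(model, x)$XF
    attr(out, "layout") <- token_layout(model$config)
    out
  }
  if (is.list(images) && !is.array(images)) lapply(images, one) else one(images)
}

#' Student output: backbone tokens plus the scaled projector residual
#'
#' Computes `XF + scale * projector(XF)` where `XF` are the final backbone
#' tokens. With the learnable scale at its zero initialisation this equals
#' [forward_tokens()] exactly.
#'
#' @param model A `vit_model`.
#' @param image A normalised `side x side x 3` array.
#' @param mask Optional logical corruption mask over patches (see
#'   [sample_corruption_mask()]).
#' @return An `n_tokens x embed_dim` matrix with attribute `"layout"`.
#' @export
student_output <- function(model, image, mask = NULL) {
  out <- vit_forward(model, image, mask = mask, projector = TRUE)$Y
  attr(out, "layout") <- token_layout(model$config)
  out
}

# Parameters that count as biases (no weight decay): additive offsets of
# linear layers and LayerNorms.
is_bias_param <- function(names) grepl("(_b|_b1|_b2|ln1_b|ln2_b)$", names)

#' Weight-decay mask for a model
#'
#' TRUE for parameters that receive weight decay under AdamW; bias parameters
#' (linear and LayerNorm offsets) are excluded.
#'
#' @param model A `vit_model`.
#' @return Named logical vector over parameter tensors.
#' @export
weight_decay_mask <- function(model) {
  nm <- names(model$params)
  stats::setNames(!is_bias_param(nm), nm)
}
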