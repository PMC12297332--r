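# Embedding extraction and storage --------------------------------------------
#
# Downstream adaptation never touches the backbone: images are embedded once
# (one d-vector per image, d = 384 by default) and everything else -- probing,
# projection, comparison -- operates on the embedding matrix. Embeddings are
# persisted as 32-bit floats with a plain-text index so they can back a simple
# vector database; checkpoints can be stripped of training-only tensors
# (optimizer moments, the projector head, the corruption token) without
# changing inference output.

#' Compute image embeddings
#'
#' Runs the backbone in evaluation mode and pools tokens per the model's
#' `pooling` config (class token by default, or the mean over patch tokens).
#' Images are resized to the model's input side and normalised with `scheme`.
#'
#' @param model A `vit_model`.
#' @param images Named list of `fundus_image`s or arrays; names become row
#'   ids.
#' @param scheme A [norm_scheme()].
#' @param batch_size Kept for API symmetry; each image is embedded
#'   independently, so the result does not depend on it.
#' @return `n x d` numeric matrix with image ids as rownames.
#' @export
compute_embeddings <- function(model, images, scheme = norm_scheme("green"),
                               batch_size = 16L) {
  stopifnot(inherits(model, "vit_model"))
  cfg <- model$config
  lay <- token_layout(cfg)
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img_%06d", seq_along(images))
  rows <- vector("list", length(images))
  keep <- rep(TRUE, length(images))
  for (i in seq_along(images)) {
    px <- tryCatch(pixels_of(images[[i]]), error = function(e) NULL)
    if (is.null(px)) {
      warning("skipping unreadable image ", ids[i], call. = FALSE)
      keep[i] <- FALSE
      next
    }
    px <- resize_image(px, cfg$image_side, cfg$image_side)
    XF <- vit_forward(model, normalize_channels(px, scheme))$XF
    rows[[i]] <- if (cfg$pooling == "class_token" && cfg$has_class_token) {
      XF[lay$class, ]
    } else {
      colMeans(XF[lay$patch, , drop = FALSE])
    }
  }
  emb <- do.call(rbind, rows[keep])
  rownames(emb) <- ids[keep]
  emb
}

#' Persist an embedding matrix
#'
#' Values are written row-major as 32-bit floats to `path`, preceded by two
#' 32-bit integers (n, d); the image-id index goes to a sidecar CSV
#' (`<path>.index.csv`).
#'
#' @param embeddings Numeric matrix with rownames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(dim(embeddings)), con, size = 4L)
  writeBin(as.vector(t(embeddings)), con, size = 4L)
  utils::write.csv(data.frame(row = seq_len(nrow(embeddings)),
                              image_id = rownames(embeddings)),
                   paste0(path, ".index.csv"), row.names = FALSE)
  invisible(path)
}

#' Load an embedding matrix written by [save_embeddings()]
#' @param path File written by [save_embeddings()].
#' @return Numeric matrix with image-id rownames (32-bit precision).
#' @export
load_embeddings <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nd <- readBin(con, "integer", 2L, size = 4L)
  vals <- readBin(con, "numeric", nd[1] * nd[2], size = 4L)
  emb <- matrix(vals, nd[1], nd[2], byrow = TRUE)
  idx <- utils::read.csv(paste0(path, ".index.csv"), stringsAsFactors = FALSE)
  rownames(emb) <- idx$image_id[order(idx$row)]
  emb
}

#' Save a model checkpoint
#'
#' A flat named-tensor archive (uncompressed RDS) holding the config, the
#' parameter list, and optionally optimizer state and training history.
#'
#' @param model A `vit_model`.
#' @param path Output file.
#' @param optimizer_state,history Optional training-only payloads.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, optimizer_state = NULL, history = NULL) {
  saveRDS(list(config = model$config, params = model$params,
               optimizer = optimizer_state, history = history),
          path, compress = FALSE)
  invisible(path)
}

#' Load a checkpoint into a model
#'
#' Backbone tensors are restored by name; tensors absent from the checkpoint
#' (e.g. the projector head after [strip_checkpoint()]) are freshly
#' initialised with a fixed seed, which leaves inference output unchanged
#' because embeddings use the backbone only.
#'
#' @param path Checkpoint file.
#' @return A `vit_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$params) || is.null(ck$config)) {
    stop("no recognizable weight block in checkpoint", call. = FALSE)
  }
  cfg <- ck$config
  class(cfg) <- "vit_config"
  build_student(cfg, init_weights = ck$params, seed = 0L)
}

#' Checkpoint manifest
#' @param path Checkpoint file.
#' @return data.frame of tensor names, shapes, and lengths.
#' @export
checkpoint_manifest <- function(path) {
  ck <- readRDS(path)
  nm <- names(ck$params)
  data.frame(tensor = nm,
             shape = vapply(ck$params, function(p)
               paste(dim_or_len(p), collapse = "x"), character(1)),
             length = vapply(ck$params, length, numeric(1)),
             row.names = NULL)
}

# Tensors required for inference: everything except the projector head and
# the corruption token, which only exist for training.
is_backbone_tensor <- function(names) {
  !grepl("^prj_", names) & names != "corruption_token"
}

#' Strip a checkpoint to its inference weights
#'
#' Removes optimizer state (which stores two extra copies of every parameter),
#' the projector head, the corruption token, and any training history, leaving
#' only the backbone tensors. Embeddings computed from the stripped checkpoint
#' are identical to those from the original; stripping is idempotent.
#'
#' @param in_path Checkpoint to strip.
#' @param out_path Output path (default `<in_path>.stripped`).
#' @return `out_path`, invisibly, with attribute `"bytes"` giving
#'   `c(original, stripped)` file sizes.
#' @export
strip_checkpoint <- function(in_path, out_path = paste0(in_path, ".stripped")) {
  ck <- readRDS(in_path)
  if (is.null(ck$params) || !length(ck$params)) {
    stop("no recognizable weight block in checkpoint", call. = FALSE)
  }
  keep <- is_backbone_tensor(names(ck$params))
  saveRDS(list(config = ck$config, params = ck$params[keep],
               optimizer = NULL, history = NULL),
          out_path, compress = FALSE)
  res <- out_path
  attr(res, "bytes") <- c(original = file.size(in_path),
                          stripped = file.size(out_path))
  invisible(res)
}

#' Embedding storage arithmetic
#'
#' Total storage is `n_vectors * d * bytes_per_value`; the fold ratio against
#' a reference dimension is `d_reference / d` rounded to two decimals (1024
#' versus 384 gives 2.67).
#'
#' @param n_vectors Number of embeddings.
#' @param d Embedding dimension.
#' @param bytes_per_value Bytes per stored value (default 4, 32-bit floats).
#' @param d_reference Reference dimension for the fold ratio (default 1024).
#' @return List with `total_bytes` and `fold_ratio`.
#' @export
embedding_storage <- function(n_vectors, d, bytes_per_value = 4, d_reference = 1024) {
  stopifnot(n_vectors > 0, d > 0, bytes_per_value > 0, d_reference > 0)
  list(total_bytes = n_vectors * d * bytes_per_value,
       fold_ratio = round(d_reference / d, 2))
}
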