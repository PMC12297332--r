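# Fundus preprocessing --------------------------------------------------------
#
# Public fundus datasets often carry considerable horizontal black space or are
# cropped slightly at the top and bottom. The cache pipeline detects the fundus
# area, crops the black side space or pads the top and bottom so the image is
# square with the disc aspect ratio intact, then resizes to the cache
# resolution (default 1024 x 1024). Downstream evaluation deliberately uses
# plain resize + normalise only, so all backbones see identically prepared
# inputs; the square pipeline is exposed for building the training cache.

#' Preprocessing configuration
#'
#' @param target_side Output side length in pixels (default 1024, the cache
#'   resolution).
#' @param detection_threshold Fraction of the maximum grey intensity above
#'   which a pixel counts as fundus (default 0.05).
#' @param jpeg_quality Quality for an optional JPEG cache, 1--100 (default 98,
#'   "very high").
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(target_side = 1024L, detection_threshold = 0.05,
                        jpeg_quality = 98L, interpolation = c("bilinear", "nearest")) {
  stopifnot(target_side > 0, detection_threshold > 0, detection_threshold < 1,
            jpeg_quality >= 1, jpeg_quality <= 100)
  structure(list(target_side = as.integer(target_side),
                 detection_threshold = detection_threshold,
                 jpeg_quality = as.integer(jpeg_quality),
                 interpolation = match.arg(interpolation)),
            class = "prep_config")
}

#' Per-model channel normalisation schemes
#'
#' `"green"` uses mean and standard deviation 0.5 on all three channels;
#' `"imagenet"` uses the ImageNet statistics (means 0.485, 0.456, 0.406 and
#' standard deviations 0.229, 0.224, 0.225).
#'
#' @param name `"green"` or `"imagenet"`, or pass `mean`/`std` directly.
#' @param mean,std Numeric 3-vectors; `std` strictly positive.
#' @return An object of class `norm_scheme`.
#' @export
norm_scheme <- function(name = c("green", "imagenet"), mean = NULL, std = NULL) {
  if (is.null(mean)) {
    name <- match.arg(name)
    if (name == "green") {
      mean <- rep(0.5, 3); std <- rep(0.5, 3)
    } else {
      mean <- c(0.485, 0.456, 0.406); std <- c(0.229, 0.224, 0.225)
    }
  } else {
    name <- "custom"
  }
  stopifnot(length(mean) == 3L, length(std) == 3L, all(std > 0))
  structure(list(name = name, mean = mean, std = std), class = "norm_scheme")
}

#' Detect the fundus area of an image
#'
#' Grey intensity is the channel mean; pixels above
#' `threshold * max(intensity)` are foreground, and the tightest bounding box
#' of the largest 4-connected foreground component is returned.
#'
#' @param image A `fundus_image` or an `H x W x 3` array in `[0, 1]`.
#' @param threshold Intensity fraction (default 0.05).
#' @return A list of class `crop_box` with 1-based inclusive `row_start`,
#'   `row_end`, `col_start`, `col_end`.
#' @export
detect_fundus_region <- function(image, threshold = 0.05) {
  px <- pixels_of(image)
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  mx <- max(gray)
  mask <- gray > threshold * mx
  if (mx <= 0 || !any(mask)) {
    stop("empty fundus: no pixel above the detection threshold", call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  rows <- which(apply(keep, 1, any))
  cols <- which(apply(keep, 2, any))
  structure(list(row_start = min(rows), row_end = max(rows),
                 col_start = min(cols), col_end = max(cols)),
            class = "crop_box")
}

pixels_of <- function(image) {
  if (inherits(image, "fundus_image")) image$pixels else image
}

#' Crop/pad an image to a square and resize
#'
#' Rows and columns outside `box` are removed; the shorter dimension is then
#' padded symmetrically with black to make the result square (an odd leftover
#' row or column goes to the bottom/right), and the square is resized to
#' `config$target_side`. The disc aspect ratio is preserved throughout.
#'
#' @param image A `fundus_image` or array.
#' @param box A `crop_box` from [detect_fundus_region()]; detected
#'   automatically when `NULL`.
#' @param config A [prep_config()].
#' @return A `fundus_image` of side `config$target_side`.
#' @export
standardize_to_square <- function(image, box = NULL, config = prep_config()) {
  px <- pixels_of(image)
  if (is.null(box)) box <- detect_fundus_region(px, config$detection_threshold)
  d <- dim(px)
  if (box$row_start < 1 || box$col_start < 1 ||
      box$row_end > d[1] || box$col_end > d[2] ||
      box$row_end <= box$row_start || box$col_end <= box$col_start) {
    stop("degenerate or out-of-range crop box", call. = FALSE)
  }
  px <- px[box$row_start:box$row_end, box$col_start:box$col_end, , drop = FALSE]
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < w) {                       # wider than tall: pad rows with black
    pad <- w - h
    top <- pad %/% 2L
    px <- rbind_rows(array(0, c(top, w, 3)), px, array(0, c(pad - top, w, 3)))
  } else if (w < h) {                # taller than wide: pad columns
    pad <- h - w
    left <- pad %/% 2L
    px <- abind_cols(array(0, c(h, left, 3)), px, array(0, c(h, pad - left, 3)))
  }
  out <- resize_image(px, config$target_side, config$target_side, config$interpolation)
  new_fundus_image(clamp01(out), meta = list(box = unclass(box)))
}

rbind_rows <- function(...) {
  parts <- list(...)
  w <- dim(parts[[1]])[2]
  h <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(h, w, 3))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

resize_image <- function(px, h, w, interpolation = "bilinear") {
  if (dim(px)[1] == h && dim(px)[2] == w) return(px)
  filt <- if (interpolation == "nearest") "none" else "bilinear"
  out <- EBImage::resize(px, w = h, h = w, filter = filt)
  array(out, c(h, w, 3))
}

#' Per-channel normalisation
#'
#' Maps pixel values in `[0, 1]` to `(x - mean) / std` per channel. Under the
#' green scheme (mean = std = 0.5) a pixel of 0.5 maps to 0 and 1.0 maps to 1.
#'
#' @param image A `fundus_image` or array with values in `[0, 1]`.
#' @param scheme A [norm_scheme()].
#' @return An `H x W x 3` numeric array.
#' @export
normalize_channels <- function(image, scheme = norm_scheme("green")) {
  px <- pixels_of(image)
  for (ch in 1:3) px[, , ch] <- (px[, , ch] - scheme$mean[ch]) / scheme$std[ch]
  px
}

#' Inverse of [normalize_channels()]
#' @inheritParams normalize_channels
#' @return Array on the original `[0, 1]` scale (not clamped).
#' @export
denormalize_channels <- function(image, scheme = norm_scheme("green")) {
  px <- pixels_of(image)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * scheme$std[ch] + scheme$mean[ch]
  px
}

#' Patient-level train/test split
#'
#' Splits over distinct `patient_id`s so that no patient contributes images to
#' both sides. The number of training patients is `round(train_fraction * n)`
#' (kept within 1 and n - 1).
#'
#' @param label_table Data frame with columns `image_id` and `patient_id`.
#' @param train_fraction Fraction of patients assigned to training
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with `train_ids` and `test_ids` (image ids), plus
#'   `train_patients` / `test_patients`.
#' @export
patient_level_split <- function(label_table, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(label_table),
            all(c("image_id", "patient_id") %in% names(label_table)))
  stopifnot_prob(train_fraction, "train_fraction")
  patients <- unique(label_table$patient_id)
  if (length(patients) < 2L) stop("need at least 2 patients to split", call. = FALSE)
  n_train <- round(train_fraction * length(patients))
  n_train <- min(max(n_train, 1L), length(patients) - 1L)
  with_seed(seed, {
    train_p <- sample(patients, n_train)
    test_p <- setdiff(patients, train_p)
    list(train_ids = label_table$image_id[label_table$patient_id %in% train_p],
         test_ids = label_table$image_id[label_table$patient_id %in% test_p],
         train_patients = train_p, test_patients = test_p)
  })
}
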