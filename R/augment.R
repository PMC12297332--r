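# Training-time augmentation --------------------------------------------------
#
# The pretraining recipe: slight colour jitter and rotation 25% of the time;
# 10% of the time the image sides are padded with black by 33--150 px to
# simulate poorly cropped photographs; the image is rescaled by a factor drawn
# from 80--120%; and one of three resize modes, chosen uniformly, produces the
# target square: plain resize, a random resized crop keeping 70--100% of the
# area, or a centre crop after upscaling by 30%. Because the stochastic plan is
# sampled separately from its application, branch frequencies can be audited
# cheaply.

#' Augmentation configuration
#'
#' @param jitter_rot_prob Probability of the colour-jitter + rotation branch
#'   (default 0.25).
#' @param side_pad_prob Probability of black side padding (default 0.10).
#' @param side_pad_range Pixel range for each side pad, inclusive
#'   (default `c(33, 150)`).
#' @param scale_range Global rescale factor range (default `c(0.8, 1.2)`).
#' @param modes Resize modes in play; one is drawn uniformly per image.
#' @param rrc_scale Area fraction range for the random resized crop
#'   (default `c(0.7, 1.0)`).
#' @param upscale_factor Upscale before the centre crop (default 1.3).
#' @param target_side Output side in pixels (default 392).
#' @param jitter_strength Max relative brightness/contrast/saturation change
#'   (default 0.1; the recipe says "slight" without a number).
#' @param rot_range Max absolute rotation in degrees (default 10; likewise
#'   unquantified upstream).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(jitter_rot_prob = 0.25,
                           side_pad_prob = 0.10,
                           side_pad_range = c(33L, 150L),
                           scale_range = c(0.8, 1.2),
                           modes = c("standard", "random_resized_crop", "center_crop"),
                           rrc_scale = c(0.7, 1.0),
                           upscale_factor = 1.3,
                           target_side = 392L,
                           jitter_strength = 0.1,
                           rot_range = 10) {
  stopifnot_prob(jitter_rot_prob, "jitter_rot_prob")
  stopifnot_prob(side_pad_prob, "side_pad_prob")
  stopifnot(length(side_pad_range) == 2L, side_pad_range[1] <= side_pad_range[2],
            length(scale_range) == 2L, scale_range[1] <= scale_range[2],
            length(rrc_scale) == 2L, rrc_scale[1] <= rrc_scale[2],
            rrc_scale[1] > 0, rrc_scale[2] <= 1,
            upscale_factor >= 1, target_side >= 16)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(jitter_rot_prob = jitter_rot_prob, side_pad_prob = side_pad_prob,
                 side_pad_range = as.integer(side_pad_range),
                 scale_range = scale_range, modes = modes, rrc_scale = rrc_scale,
                 upscale_factor = upscale_factor, target_side = as.integer(target_side),
                 jitter_strength = jitter_strength, rot_range = rot_range),
            class = "augment_config")
}

#' Sample a stochastic augmentation plan
#'
#' Draws every random decision of [augment_image()] from the current RNG
#' stream: the jitter/rotation branch, side padding and its widths (left and
#' right sampled independently), the global scale factor, the resize mode
#' (uniform over `config$modes`), and the mode's own parameters.
#'
#' @param config An [augment_config()].
#' @return A list of class `augment_plan`.
#' @export
sample_augment_plan <- function(config = augment_config()) {
  jitter <- runif(1) < config$jitter_rot_prob
  jit <- NULL
  if (jitter) {
    s <- config$jitter_strength
    jit <- list(brightness = runif(1, 1 - s, 1 + s),
                contrast = runif(1, 1 - s, 1 + s),
                saturation = runif(1, 1 - s, 1 + s),
                angle = runif(1, -config$rot_range, config$rot_range))
  }
  side_pad <- runif(1) < config$side_pad_prob
  pads <- if (side_pad) {
    c(sample(config$side_pad_range[1]:config$side_pad_range[2], 1L),
      sample(config$side_pad_range[1]:config$side_pad_range[2], 1L))
  } else c(0L, 0L)
  scale <- runif(1, config$scale_range[1], config$scale_range[2])
  mode <- config$modes[sample.int(length(config$modes), 1L)]
  mode_par <- switch(mode,
    standard = list(),
    random_resized_crop = list(area = runif(1, config$rrc_scale[1], config$rrc_scale[2]),
                               u = runif(2)),
    center_crop = list())
  structure(list(jitter = jitter, jit = jit, side_pad = side_pad, pads = pads,
                 scale = scale, mode = mode, mode_par = mode_par),
            class = "augment_plan")
}

#' Apply the training augmentation pipeline to one image
#'
#' @param image A `fundus_image` or `H x W x 3` array in `[0, 1]`.
#' @param config An [augment_config()].
#' @param plan Optional pre-sampled [sample_augment_plan()]; when `NULL` a
#'   fresh plan is drawn (seeded via `seed`).
#' @param seed Optional integer seed for the plan draw.
#' @return A `target_side x target_side x 3` array in `[0, 1]`, with the plan
#'   attached as attribute `"plan"`.
#' @export
augment_image <- function(image, config = augment_config(), plan = NULL, seed = NULL) {
  px <- pixels_of(image)
  stopifnot(min(dim(px)[1:2]) >= 1)
  if (is.null(plan)) {
    plan <- if (is.null(seed)) sample_augment_plan(config)
            else with_seed(seed, sample_augment_plan(config))
  }
  # degenerate tiny inputs are upscaled before anything else
  if (min(dim(px)[1:2]) < 32) {
    f <- ceiling(32 / min(dim(px)[1:2]))
    px <- resize_image(px, dim(px)[1] * f, dim(px)[2] * f)
  }

  if (plan$jitter) {
    j <- plan$jit
    px <- clamp01(px * j$brightness)
    px <- clamp01((px - 0.5) * j$contrast + 0.5)
    gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    for (ch in 1:3) px[, , ch] <- clamp01(gray + (px[, , ch] - gray) * j$saturation)
    rot <- EBImage::rotate(px, j$angle, bg.col = "black")
    px <- array(rot, dim(rot))
  }

  if (plan$side_pad) {
    h <- dim(px)[1]
    px <- abind_cols(array(0, c(h, plan$pads[1], 3)), px,
                     array(0, c(h, plan$pads[2], 3)))
  }

  if (abs(plan$scale - 1) > 1e-12) {
    px <- resize_image(px, max(1L, round(dim(px)[1] * plan$scale)),
                       max(1L, round(dim(px)[2] * plan$scale)))
  }

  t <- config$target_side
  px <- switch(plan$mode,
    standard = resize_image(px, t, t),
    random_resized_crop = {
      h <- dim(px)[1]; w <- dim(px)[2]
      side <- max(8L, round(sqrt(plan$mode_par$area * h * w)))
      side <- min(side, h, w)
      r0 <- 1L + floor(plan$mode_par$u[1] * (h - side + 1L))
      c0 <- 1L + floor(plan$mode_par$u[2] * (w - side + 1L))
      resize_image(px[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE], t, t)
    },
    center_crop = {
      big <- ceiling(t * config$upscale_factor)
      h <- dim(px)[1]; w <- dim(px)[2]
      f <- big / min(h, w)
      px <- resize_image(px, max(big, round(h * f)), max(big, round(w * f)))
      h <- dim(px)[1]; w <- dim(px)[2]
      r0 <- 1L + (h - t) %/% 2L
      c0 <- 1L + (w - t) %/% 2L
      px[r0:(r0 + t - 1L), c0:(c0 + t - 1L), , drop = FALSE]
    })
  out <- clamp01(array(px, c(t, t, 3)))
  attr(out, "plan") <- plan
  out
}
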