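# Shared tiny fixtures. Everything is generated in code at test time.

tiny_vit_config <- function(...) {
  defaults <- list(image_side = 16L, patch_side = 8L, embed_dim = 8L,
                   depth = 2L, heads = 2L, n_registers = 2L, mlp_ratio = 2L)
  do.call(vit_config, utils::modifyList(defaults, list(...)))
}

tiny_model <- function(seed = 3L, ...) build_student(tiny_vit_config(...), seed = seed)

tiny_image <- function(seed = 9L, side = 16L) {
  set.seed(seed)
  array(runif(side * side * 3), c(side, side, 3))
}

clean_spec <- function(side = 64L, seed = 5L) {
  synthetic_spec(image_side = side, bar_prob = 0, crop_prob = 0, seed = seed)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# bounding box of non-black pixels (oracle used against GroundTruth geometry)
pixel_bbox <- function(px, eps = 1e-6) {
  on <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3 > eps
  list(rows = range(which(apply(on, 1, any))),
       cols = range(which(apply(on, 2, any))))
}
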