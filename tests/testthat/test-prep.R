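test_that("fundus detection recovers the generator's disc bounds", {
  res <- generate_fundus_image(clean_spec(side = 96), grade = 0, seed = 3)
  box <- detect_fundus_region(res$image)
  ctr <- res$truth$disc_center; r <- res$truth$disc_radius
  expect_lte(abs(box$row_start - (ctr[1] - r)), 2)
  expect_lte(abs(box$row_end - (ctr[1] + r)), 2)
  expect_lte(abs(box$col_start - (ctr[2] - r)), 2)
  expect_lte(abs(box$col_end - (ctr[2] + r)), 2)
})

test_that("detection handles degenerate inputs", {
  white <- array(1, c(20, 30, 3))
  box <- detect_fundus_region(white)
  expect_equal(unclass(box), list(row_start = 1, row_end = 20,
                                  col_start = 1, col_end = 30),
               ignore_attr = TRUE)
  expect_error(detect_fundus_region(array(0, c(10, 10, 3))), "empty fundus")
})

test_that("square standardisation preserves the disc aspect ratio", {
  spec <- synthetic_spec(image_side = 100, bar_prob = 1, crop_prob = 0, seed = 2)
  res <- generate_fundus_image(spec, grade = 0, seed = 15)
  cfg <- prep_config(target_side = 256)
  sq <- standardize_to_square(res$image, config = cfg)
  expect_equal(dim(sq$pixels), c(256, 256, 3))
  # disc was circular before: its bounding box must stay square within 1%
  bb <- pixel_bbox(sq$pixels, eps = 0.02)
  h <- diff(bb$rows) + 1; w <- diff(bb$cols) + 1
  expect_lt(abs(h / w - 1), 0.01)
})

test_that("vertically truncated discs are padded, losing no disc pixels", {
  spec <- synthetic_spec(image_side = 100, bar_prob = 0, crop_prob = 1, seed = 2)
  res <- generate_fundus_image(spec, grade = 0, seed = 8)
  px <- res$image$pixels
  expect_lt(dim(px)[1], dim(px)[2])           # truncated: shorter than wide
  n_disc_in <- sum((px[, , 1] + px[, , 2] + px[, , 3]) / 3 > 0.02)
  cfg <- prep_config(target_side = dim(px)[2])  # no downscale: count pixels
  sq <- standardize_to_square(res$image, config = cfg)
  spx <- sq$pixels
  n_disc_out <- sum((spx[, , 1] + spx[, , 2] + spx[, , 3]) / 3 > 0.02)
  expect_gte(n_disc_out, 0.99 * n_disc_in)
})

test_that("standardisation is idempotent up to interpolation noise", {
  res <- generate_fundus_image(clean_spec(side = 80), grade = 1, seed = 4)
  cfg <- prep_config(target_side = 128)
  once <- standardize_to_square(res$image, config = cfg)
  twice <- standardize_to_square(once, config = cfg)
  expect_lt(max(abs(twice$pixels - once$pixels)), 1 / 255)
})

test_that("degenerate crop boxes are rejected", {
  img <- array(1, c(10, 10, 3))
  box <- structure(list(row_start = 5, row_end = 5, col_start = 2, col_end = 8),
                   class = "crop_box")
  expect_error(standardize_to_square(img, box), "degenerate")
})

test_that("normalisation matches the per-model constants", {
  green <- norm_scheme("green")
  px <- array(0.5, c(2, 2, 3))
  expect_equal(normalize_channels(px, green), array(0, c(2, 2, 3)))
  expect_equal(normalize_channels(array(1, c(2, 2, 3)), green),
               array(1, c(2, 2, 3)))
  inet <- norm_scheme("imagenet")
  px <- array(0, c(1, 1, 3)); px[1, 1, 1] <- 0.485
  expect_equal(normalize_channels(px, inet)[1, 1, 1], 0)
  # round trip
  x <- array(runif(12), c(2, 2, 3))
  expect_equal(denormalize_channels(normalize_channels(x, inet), inet), x)
  expect_error(norm_scheme(mean = rep(0.5, 3), std = c(1, 1, 0)))
})

test_that("patient-level split is exact and leak-free", {
  tab <- data.frame(image_id = sprintf("i%02d", 1:20),
                    patient_id = rep(sprintf("p%02d", 1:10), each = 2))
  sp <- patient_level_split(tab, 0.8, seed = 1)
  expect_equal(length(sp$train_ids), 16)
  expect_equal(length(sp$test_ids), 4)
  expect_length(intersect(sp$train_patients, sp$test_patients), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), tab$image_id)
  expect_error(patient_level_split(tab[1:2, ][tab$patient_id[1:2] == "p01", ]),
               "at least 2 patients")
})

test_that("train image fraction tracks the patient fraction over random tables", {
  set.seed(99)
  fracs <- replicate(1000, {
    n_pat <- sample(10:40, 1)
    per <- sample(1:4, n_pat, replace = TRUE)
    tab <- data.frame(image_id = as.character(seq_len(sum(per))),
                      patient_id = rep(seq_len(n_pat), times = per))
    sp <- patient_level_split(tab, 0.8, seed = sample.int(1e6, 1))
    length(sp$train_ids) / nrow(tab)
  })
  expect_lt(abs(mean(fracs) - 0.8), 0.05)
})
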