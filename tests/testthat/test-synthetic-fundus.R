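test_that("spec validation rejects inconsistent settings", {
  expect_error(synthetic_spec(bar_prob = 1.5), "bar_prob")
  expect_error(synthetic_spec(lesion_counts_per_grade = c(0, 4, 4, 9, 12)),
               "strictly increasing")
  expect_error(synthetic_spec(disc_radius_frac = 0.55, bar_prob = 0.3),
               "exceed the frame")
  expect_error(generate_fundus_image(clean_spec(), grade = 5), "0..4")
})

test_that("rendering is deterministic and grade 0 carries no lesions", {
  spec <- clean_spec()
  a <- generate_fundus_image(spec, grade = 2, seed = 7)
  b <- generate_fundus_image(spec, grade = 2, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)

  g0 <- generate_fundus_image(spec, grade = 0, seed = 7)
  expect_identical(g0$truth$n_lesions, 0L)
  expect_identical(g0$truth$binary_label, 0L)
  g3 <- generate_fundus_image(spec, grade = 3, seed = 7)
  expect_identical(g3$truth$n_lesions, spec$lesion_counts_per_grade[4])
  expect_identical(g3$truth$binary_label, 1L)
})

test_that("rendered disc geometry matches the recorded ground truth", {
  spec <- clean_spec(side = 96)
  for (seed in c(2, 13, 44)) {
    res <- generate_fundus_image(spec, grade = 1, seed = seed)
    bb <- pixel_bbox(res$image$pixels)
    ctr <- res$truth$disc_center; r <- res$truth$disc_radius
    expect_lte(abs(bb$rows[1] - ceiling(ctr[1] - r)), 1)
    expect_lte(abs(bb$rows[2] - floor(ctr[1] + r)), 1)
    expect_lte(abs(bb$cols[1] - ceiling(ctr[2] - r)), 1)
    expect_lte(abs(bb$cols[2] - floor(ctr[2] + r)), 1)
  }
})

test_that("cropping artifacts shift the recorded geometry consistently", {
  spec <- synthetic_spec(image_side = 64, bar_prob = 1, crop_prob = 1, seed = 1)
  res <- generate_fundus_image(spec, grade = 0, seed = 21)
  d <- dim(res$image$pixels)
  expect_gt(d[2], d[1])                       # bars widen, crop shortens
  # disc centre column sits under the disc, not under a bar
  ctr <- res$truth$disc_center
  col <- res$image$pixels[round(ctr[1]), round(ctr[2]), ]
  expect_gt(mean(col), 0.05)
})

test_that("dataset generation respects shape and patient structure", {
  spec <- clean_spec(side = 32)
  ds <- generate_dataset(spec, n_patients = 10, images_per_patient = 2, seed = 3)
  expect_equal(nrow(ds$labels), 20)
  expect_equal(length(unique(ds$labels$patient_id)), 10)
  expect_setequal(names(ds$images), ds$labels$image_id)
  # images of one patient share the grade
  per <- tapply(ds$labels$grade, ds$labels$patient_id, function(g) length(unique(g)))
  expect_true(all(per == 1))

  all0 <- generate_dataset(spec, 5, 1, grade_distribution = c(1, 0, 0, 0, 0), seed = 4)
  expect_true(all(all0$labels$grade == 0))

  expect_error(generate_dataset(spec, 5, 1, grade_distribution = numeric(0)),
               "non-empty")
  expect_error(generate_dataset(spec, 5, 1, grade_distribution = c(0.5, 0.5)),
               "summing to 1")
})

test_that("empirical grade frequencies match the sampling distribution", {
  spec <- clean_spec(side = 32)
  dist <- c(0.35, 0.25, 0.2, 0.12, 0.08)
  ds <- generate_dataset(spec, n_patients = 5000, images_per_patient = 1,
                         grade_distribution = dist, seed = 8)
  freq <- as.numeric(table(factor(ds$labels$grade, levels = 0:4)) / 5000)
  expect_true(all(abs(freq - dist) <= 0.02))
})

test_that("embedding blobs have the designed separability", {
  expect_error(generate_embedding_blobs(1, d = 4), ">= 2")
  b0 <- generate_embedding_blobs(200, d = 16, separation = 0, seed = 2)
  b0b <- generate_embedding_blobs(200, d = 16, separation = 0, seed = 2)
  expect_identical(b0$embeddings, b0b$embeddings)

  # mean distance equals the requested separation (law of large numbers)
  bs <- generate_embedding_blobs(2000, d = 32, separation = 6, seed = 3)
  mu0 <- colMeans(bs$embeddings[bs$labels == 0, ])
  mu1 <- colMeans(bs$embeddings[bs$labels == 1, ])
  expect_lt(abs(sqrt(sum((mu1 - mu0)^2)) - 6), 0.2)
})

test_that("datasets round-trip through PNG and CSV", {
  spec <- clean_spec(side = 32)
  ds <- generate_dataset(spec, n_patients = 3, images_per_patient = 1, seed = 6)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$labels, ds$labels)
  # 8-bit quantisation on write
  expect_lt(max(abs(back$images[[1]]$pixels - ds$images[[1]]$pixels)), 1 / 255)
})
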