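# Synthetic fundus fixtures ---------------------------------------------------
#
# Colour fundus photographs are circular retina discs on a black background;
# disease severity shows up as small bright lesions (microaneurysms, exudates)
# of only a few pixels. The generator emulates exactly those properties --
# a shaded disc, dark vessel polylines, a bright optic disc, grade-dependent
# lesion specks, and the two cropping artifacts common in public datasets
# (black side bars; images truncated at top and bottom) -- so that every other
# module can be exercised without any real data.

#' Specification for the synthetic fundus generator
#'
#' @param image_side Side length of the (pre-artifact) square canvas, pixels.
#' @param disc_radius_frac Retina disc radius as a fraction of `image_side`.
#' @param vessel_count Number of dark vessel polylines radiating from the
#'   optic disc. Cosmetic only; carries no label signal.
#' @param lesion_counts_per_grade Integer vector of length 5 giving the number
#'   of bright lesion specks rendered for grades 0 to 4. Must be strictly
#'   increasing so the grade is identifiable from the image.
#' @param bar_prob Probability that black side bars (horizontal black space)
#'   are appended left and right of the disc.
#' @param crop_prob Probability that the image is truncated at top and bottom,
#'   cutting into the disc.
#' @param seed Integer seed; together with the per-image seed it fully
#'   determines the rendered pixels.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_side = 256L,
                           disc_radius_frac = 0.45,
                           vessel_count = 6L,
                           lesion_counts_per_grade = c(0L, 4L, 9L, 16L, 26L),
                           bar_prob = 0.3,
                           crop_prob = 0.2,
                           seed = 1L) {
  stopifnot(image_side >= 32, disc_radius_frac > 0)
  stopifnot_prob(bar_prob, "bar_prob")
  stopifnot_prob(crop_prob, "crop_prob")
  if (length(lesion_counts_per_grade) != 5L ||
      any(diff(lesion_counts_per_grade) <= 0)) {
    stop("`lesion_counts_per_grade` must be 5 strictly increasing counts (grades 0..4)",
         call. = FALSE)
  }
  if (disc_radius_frac >= 0.5 && bar_prob > 0) {
    stop("disc_radius_frac >= 0.5 with side bars enabled: disc would exceed the frame",
         call. = FALSE)
  }
  structure(list(image_side = as.integer(image_side),
                 disc_radius_frac = disc_radius_frac,
                 vessel_count = as.integer(vessel_count),
                 lesion_counts_per_grade = as.integer(lesion_counts_per_grade),
                 bar_prob = bar_prob, crop_prob = crop_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

new_fundus_image <- function(pixels, meta = list()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(list(pixels = pixels, meta = meta), class = "fundus_image")
}

#' @exportS3Method base::print
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %d x %d x 3, range [%.3f, %.3f]>\n",
              d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Paint a filled circle into an HxWx3 array (vectorised distance test).
paint_disc <- function(px, center, radius, colour, blend = 1) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[inside] <- (1 - blend) * plane[inside] + blend * colour[ch]
    px[, , ch] <- plane
  }
  px
}

#' Render one synthetic fundus image
#'
#' Draws a shaded circular retina disc on black, vessels, an optic disc, and
#' `lesion_counts_per_grade[grade + 1]` bright lesion specks of 2--4 px
#' radius. With the spec's probabilities, black side bars are appended and/or
#' top and bottom rows are truncated, mimicking poorly cropped photographs.
#'
#' @param spec A [synthetic_spec()].
#' @param grade Integer severity grade 0--4; determines the lesion count.
#' @param seed Integer seed for this image.
#' @return A list with `image` (class `fundus_image`, values in `[0, 1]`) and
#'   `truth`: disc centre (row, col), disc radius (pixels, final coordinates),
#'   grade, `binary_label` (= grade >= 1), and the rendered lesion count.
#' @export
generate_fundus_image <- function(spec, grade, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!(grade %in% 0:4)) stop("`grade` must be in 0..4", call. = FALSE)
  with_seed(seed, {
    side <- spec$image_side
    px <- array(0, c(side, side, 3))
    center <- c(side / 2 + 0.5, side / 2 + 0.5)
    radius <- spec$disc_radius_frac * side

    # per-image illumination: global intensity varies between photographs, so
    # grade information cannot be read off global brightness statistics
    illum <- runif(1, 0.75, 1.05)

    # retina disc with a slight radial falloff
    px <- paint_disc(px, center, radius, illum * c(0.80, 0.34, 0.10))
    rr <- matrix(seq_len(side), side, side)
    cc <- matrix(seq_len(side), side, side, byrow = TRUE)
    dist <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
    fall <- pmax(0, 1 - 0.35 * (dist / radius)^2)
    inside <- dist <= radius
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[inside] <- plane[inside] * fall[inside]
      px[, , ch] <- plane
    }

    # optic disc: bright circle offset to one side
    od_center <- center + c(0, 0.55 * radius) * sample(c(-1, 1), 1)
    od_radius <- 0.16 * radius
    px <- paint_disc(px, od_center, od_radius, illum * c(0.95, 0.82, 0.55))

    # vessels: dark random-walk polylines from the optic disc
    for (v in seq_len(spec$vessel_count)) {
      pos <- od_center
      ang <- runif(1, 0, 2 * pi)
      for (step in seq_len(as.integer(1.8 * radius))) {
        ang <- ang + rnorm(1, 0, 0.15)
        pos <- pos + c(sin(ang), cos(ang))
        if (sqrt(sum((pos - center)^2)) > 0.95 * radius) break
        r0 <- max(1L, as.integer(round(pos[1]))); c0 <- max(1L, as.integer(round(pos[2])))
        if (r0 >= side || c0 >= side) break
        px[r0:(r0 + 1L), c0, 1] <- 0.45
        px[r0:(r0 + 1L), c0, 2] <- 0.08
        px[r0:(r0 + 1L), c0, 3] <- 0.05
      }
    }

    # lesion specks: small blobs of subtle local contrast (slightly brighter
    # and yellower than the surrounding retina under the same illumination),
    # count encodes the grade; the signal lives in small structure, not in
    # global intensity
    n_lesions <- spec$lesion_counts_per_grade[grade + 1L]
    if (n_lesions > 0) {
      for (l in seq_len(n_lesions)) {
        repeat {
          off <- runif(2, -0.8, 0.8) * radius
          if (sum(off^2) <= (0.8 * radius)^2 &&
              sqrt(sum((center + off - od_center)^2)) > od_radius + 5) break
        }
        px <- paint_disc(px, center + off, runif(1, 2, 4),
                         illum * c(0.88, 0.52, 0.25))
      }
    }

    truth_center <- center
    truth_radius <- radius

    # artifact: black side bars (image becomes wider than tall)
    if (runif(1) < spec$bar_prob) {
      bw <- as.integer(round(runif(2, 0.08, 0.22) * side))
      px <- abind_cols(array(0, c(side, bw[1], 3)), px, array(0, c(side, bw[2], 3)))
      truth_center[2] <- truth_center[2] + bw[1]
    }

    # artifact: truncate top and bottom rows, cutting into the disc
    if (runif(1) < spec$crop_prob) {
      cut <- as.integer(round(runif(1, 0.03, 0.10) * side))
      keep <- (cut + 1L):(dim(px)[1] - cut)
      px <- px[keep, , , drop = FALSE]
      truth_center[1] <- truth_center[1] - cut
    }

    truth <- list(disc_center = truth_center, disc_radius = truth_radius,
                  grade = as.integer(grade),
                  binary_label = as.integer(grade >= 1L),
                  n_lesions = n_lesions)
    list(image = new_fundus_image(clamp01(px), meta = list(seed = seed)),
         truth = truth)
  })
}

# cbind for HxWx3 arrays
abind_cols <- function(...) {
  parts <- list(...)
  h <- dim(parts[[1]])[1]
  w <- sum(vapply(parts, function(p) dim(p)[2], integer(1)))
  out <- array(0, c(h, w, 3))
  at <- 0L
  for (p in parts) {
    out[, at + seq_len(dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  out
}

#' Generate a patient-structured synthetic dataset
#'
#' Each patient is assigned one severity grade drawn from `grade_distribution`
#' and contributes `images_per_patient` images (e.g. both eyes), all sharing
#' that grade -- the structure needed to test patient-level splitting.
#'
#' @param spec A [synthetic_spec()].
#' @param n_patients,images_per_patient Dataset shape.
#' @param grade_distribution Probability vector over grades 0--4 (sums to 1).
#' @param seed Integer seed.
#' @return A list with `images` (named list of `fundus_image`) and `labels`,
#'   a data.frame with columns image_id, patient_id, grade, binary_label.
#' @export
generate_dataset <- function(spec, n_patients, images_per_patient = 2L,
                             grade_distribution = c(0.5, 0.2, 0.15, 0.1, 0.05),
                             seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), n_patients >= 1, images_per_patient >= 1)
  if (length(grade_distribution) == 0L) {
    stop("`grade_distribution` must be a non-empty probability vector", call. = FALSE)
  }
  if (length(grade_distribution) != 5L || abs(sum(grade_distribution) - 1) > 1e-8 ||
      any(grade_distribution < 0)) {
    stop("`grade_distribution` must be 5 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  with_seed(seed, {
    grades <- sample(0:4, n_patients, replace = TRUE, prob = grade_distribution)
    images <- vector("list", n_patients * images_per_patient)
    rows <- vector("list", n_patients * images_per_patient)
    k <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("pat_%05d", p)
      for (i in seq_len(images_per_patient)) {
        k <- k + 1L
        iid <- sprintf("img_%06d", k)
        res <- generate_fundus_image(spec, grades[p], seed = derive_seed(seed, k))
        images[[k]] <- res$image
        rows[[k]] <- data.frame(image_id = iid, patient_id = pid,
                                grade = grades[p],
                                binary_label = as.integer(grades[p] >= 1L),
                                stringsAsFactors = FALSE)
      }
    }
    labels <- do.call(rbind, rows)
    names(images) <- labels$image_id
    list(images = images, labels = labels)
  })
}

#' Two-class Gaussian embedding fixture
#'
#' Two isotropic unit-variance Gaussian clouds in `d` dimensions whose means
#' are `separation` apart, used to exercise probing and bootstrap machinery
#' with a known difficulty.
#'
#' @param n_per_class Points per class (>= 2).
#' @param d Embedding dimension (>= 2).
#' @param separation Euclidean distance between class means (>= 0).
#' @param seed Integer seed.
#' @return List with `embeddings` (`2 n_per_class x d` matrix, rownames are
#'   synthetic image ids) and `labels` (0/1 integer vector).
#' @export
generate_embedding_blobs <- function(n_per_class, d = 384L, separation = 10, seed = 1L) {
  if (n_per_class < 2) stop("`n_per_class` must be >= 2", call. = FALSE)
  stopifnot(d >= 2, separation >= 0)
  with_seed(seed, {
    u <- rnorm(d); u <- u / sqrt(sum(u^2))
    x0 <- matrix(rnorm(n_per_class * d), n_per_class, d)
    x1 <- matrix(rnorm(n_per_class * d), n_per_class, d) +
      matrix(u * separation, n_per_class, d, byrow = TRUE)
    emb <- rbind(x0, x1)
    rownames(emb) <- sprintf("img_%06d", seq_len(2L * n_per_class))
    list(embeddings = emb, labels = rep(c(0L, 1L), each = n_per_class))
  })
}

#' Write a synthetic dataset to disk
#'
#' Images as 8-bit PNG, labels as CSV (image_id, patient_id, grade,
#' binary_label).
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$images)) {
    png::writePNG(dataset$images[[id]]$pixels, file.path(dir, paste0(id, ".png")))
  }
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory holding PNGs and labels.csv.
#' @return Same shape as [generate_dataset()] output.
#' @export
read_dataset <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  images <- lapply(labels$image_id, function(id) {
    px <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    new_fundus_image(px[, , 1:3, drop = FALSE])
  })
  names(images) <- labels$image_id
  list(images = images, labels = labels)
}
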