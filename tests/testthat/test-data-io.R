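test_that("index_dataset pairs images with masks, grouped and sorted", {
  dir <- withr::local_tempdir()
  generate_phantom_dataset(2, 3, dir, seed = 4, image_size = 16)
  idx <- index_dataset(dir)
  expect_equal(nrow(idx), 6)
  expect_equal(dplyr::n_distinct(idx$patient_id), 2)
  expect_true(all(grepl("_mask\\.png$", idx$mask_path)))
  expect_identical(idx$patient_id, sort(idx$patient_id))
  expect_identical(idx$slice_index,
                   unlist(tapply(idx$slice_index, idx$patient_id, sort),
                          use.names = FALSE))
})

test_that("index_dataset errors on empty roots and orphan images", {
  empty <- withr::local_tempdir()
  expect_error(index_dataset(empty), "no patients found")

  dir <- withr::local_tempdir()
  generate_phantom_dataset(1, 2, dir, seed = 4, image_size = 16)
  orphan <- file.path(dir, "phantom_001", "phantom_001_9.png")
  png::writePNG(matrix(0.5, 16, 16), orphan)
  expect_error(index_dataset(dir), "phantom_001_9")
})

test_that("split sizes follow the floor-then-remainder-to-test rule", {
  fake <- tibble::tibble(patient_id = sprintf("p%03d", 1:110))
  sp <- split_patients(fake, c(0.90, 0.05, 0.05), seed = 1)
  expect_equal(lengths(sp[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 99L, val_ids = 5L, test_ids = 6L))

  fake20 <- tibble::tibble(patient_id = sprintf("p%02d", 1:20))
  sp20 <- split_patients(fake20, seed = 1)
  expect_equal(lengths(sp20[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 18L, val_ids = 1L, test_ids = 1L))

  expect_error(split_patients(tibble::tibble(patient_id = c("a", "b"))),
               class = "sonoseg_split_error")
})

test_that("splits are patient-disjoint, exhaustive and seed-deterministic", {
  fake <- tibble::tibble(patient_id = sprintf("p%02d", 1:23))
  for (seed in 1:100) {
    sp <- split_patients(fake, seed = seed)
    all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_equal(sort(all_ids), fake$patient_id)
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_identical(split_patients(fake, seed = 77),
                   split_patients(fake, seed = 77))
  expect_false(identical(split_patients(fake, seed = 1)$train_ids,
                         split_patients(fake, seed = 2)$train_ids))
})

test_that("preprocess scales by the fixed 8-bit divisor and crops/pads centrally", {
  big <- matrix(0, 300, 300)
  big[150, 150] <- 255
  out <- preprocess(big, size = 256)
  expect_equal(dim(out), c(256, 256))
  expect_equal(out[150 - 22, 150 - 22], 1)   # 300 -> 256 crops 22 leading

  small <- matrix(255, 200, 200)
  out2 <- preprocess(small, size = 256)
  expect_equal(dim(out2), c(256, 256))
  expect_true(all(out2[1:28, ] == 0))
  expect_true(all(out2[, 1:28] == 0))
  expect_true(all(out2[29:228, 29:228] == 1))

  const <- matrix(128, 64, 64)
  expect_equal(unique(as.vector(preprocess(const, 64))), 128 / 255)

  # idempotence: a second pass leaves a unit-scaled slice unchanged
  once <- preprocess(big, 256)
  expect_identical(preprocess(once, 256), once)

  expect_error(preprocess(matrix(numeric(0), 0, 0)),
               class = "sonoseg_io_error")
})

test_that("masks load as exact 0/1 regardless of 8-bit encoding", {
  dir <- withr::local_tempdir()
  img <- file.path(dir, "s1.png")
  msk <- file.path(dir, "s1_mask.png")
  png::writePNG(matrix(runif(64), 8, 8), img)
  png::writePNG(matrix(c(0, 1, 0, 1), 8, 8), msk)   # writes 0 / 255
  sp <- load_slice_pair(img, msk)
  expect_setequal(unique(as.vector(sp$mask)), c(0, 1))
  expect_equal(dim(sp$image), c(8, 8, 3))
  expect_true(all(sp$image >= 0 & sp$image <= 255))
})

test_that("augmentation is the identity when every gate is off", {
  ph <- generate_phantom(phantom_params(image_size = 32, tumor_radius = 6,
                                        seed = 1))
  cfg <- augmentation_config(flip_probability = 0, p_rotation = 0,
                             p_elastic = 0, p_noise = 0, p_intensity = 0,
                             p_blur = 0)
  out <- augment_slice(ph, cfg)
  expect_identical(out$image, ph$image)
  expect_identical(out$mask, ph$mask)
})

test_that("a forced flip mirrors image and mask jointly", {
  ph <- generate_phantom(phantom_params(image_size = 32, tumor_radius = 6,
                                        tumor_center = c(16, 10), seed = 1))
  cfg <- augmentation_config(flip_probability = 1, p_rotation = 0,
                             p_elastic = 0, p_noise = 0, p_intensity = 0,
                             p_blur = 0)
  out <- augment_slice(ph, cfg)
  expect_identical(out$image, ph$image[, 32:1])
  expect_identical(out$mask, ph$mask[, 32:1])
})

test_that("the flip gate is Bernoulli(0.5) within the exact binomial 99% interval", {
  ph <- list(image = matrix(0.5, 2, 2), mask = matrix(0, 2, 2))
  cfg <- augmentation_config(flip_probability = 0.5, p_rotation = 0,
                             p_elastic = 0, p_noise = 0, p_intensity = 0,
                             p_blur = 0)
  ph$image[1, 1] <- 1   # asymmetric so a flip is observable
  set.seed(42)
  n <- 10000
  flips <- 0L
  for (i in seq_len(n)) {
    out <- augment_slice(ph, cfg)
    if (!identical(out$image, ph$image)) flips <- flips + 1L
  }
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(flips, bounds[1])
  expect_lte(flips, bounds[2])
})

test_that("random augmentation preserves label binarity and image range", {
  ph <- generate_phantom(phantom_params(image_size = 32, tumor_radius = 7,
                                        boundary_jitter = 0.2, seed = 3))
  cfg <- augmentation_config()
  set.seed(11)
  for (i in 1:20) {
    out <- augment_slice(ph, cfg)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_identical(dim(out$image), dim(ph$image))
  }
})
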