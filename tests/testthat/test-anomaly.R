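test_that("z-score maps standardize against the reference statistics", {
  img <- matrix(0.5, 4, 4)
  img[1, 1:3] <- c(0.4, 0.5, 0.6)   # reference: mean 0.5, sd 0.1
  img[4, 4] <- 0.8
  ref <- matrix(0, 4, 4)
  ref[1, 1:3] <- 1
  z <- zscore_map(img, ref)
  expect_equal(z[4, 4], 3.0)
  expect_equal(z[1, 2], 0)

  expect_warning(zc <- zscore_map(matrix(0.5, 3, 3),
                                  matrix(1, 3, 3)), "zero variance")
  expect_true(all(zc == 0))
  expect_error(zscore_map(img, matrix(0, 4, 4)),
               class = "sonoseg_anomaly_error")
  expect_error(zscore_map(img, matrix(1, 2, 2)),
               class = "sonoseg_shape_error")
})

test_that("a solid square yields the hand-counted morphology", {
  mask <- matrix(0, 12, 12)
  mask[4:8, 5:9] <- 1   # 5x5 square
  reg <- extract_regions(mask)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$area, 25)
  expect_equal(reg$perimeter, 20)
  expect_equal(reg$complexity, 400 / (4 * pi * 25))
  expect_equal(reg$centroid_row, 6)
  expect_equal(reg$centroid_col, 7)
})

test_that("components are 8-connected and sorted by descending area", {
  mask <- matrix(0, 10, 10)
  mask[1:2, 1:2] <- 1
  mask[3, 3] <- 1          # touches (2,2) diagonally -> same region
  mask[7:9, 7:9] <- 1      # separate blob
  reg <- extract_regions(mask, min_size = 1)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$area, c(9, 5))         # sorted by descending area
  expect_equal(reg$region_id, c(1L, 2L))

  expect_equal(nrow(extract_regions(matrix(0, 5, 5))), 0)
})

test_that("region areas conserve the mask positive count (min_size 1)", {
  set.seed(12)
  for (rep in 1:10) {
    mask <- matrix(rbinom(400, 1, 0.3), 20, 20)
    reg <- extract_regions(mask, min_size = 1)
    expect_equal(sum(reg$area), sum(mask))
  }
})

test_that("centroids are translation-equivariant; area and complexity invariant", {
  mask <- matrix(0, 20, 20)
  mask[3:7, 4:6] <- 1
  mask[5, 7] <- 1
  img <- matrix(runif(400), 20, 20)
  r1 <- extract_regions(mask, image = img)
  shift <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  r2 <- extract_regions(shift(mask, 5, 3), image = shift(img, 5, 3))
  expect_equal(r2$centroid_row, r1$centroid_row + 5)
  expect_equal(r2$centroid_col, r1$centroid_col + 3)
  expect_equal(r2$area, r1$area)
  expect_equal(r2$complexity, r1$complexity)
  expect_equal(r2$mean_intensity, r1$mean_intensity)
})

test_that("severity classification is monotone in the peak z-score", {
  expect_equal(classify_severity(3.5), "high")
  expect_equal(classify_severity(2.5), "moderate")
  expect_equal(classify_severity(0), "none")
  expect_equal(classify_severity(c(0, 2.1, 4)), c("none", "moderate", "high"))
  expect_error(classify_severity(1, thresholds = c(moderate = 3, high = 2)),
               class = "sonoseg_anomaly_error")
})

test_that("hyperintense phantom tumors are classified high across seeds", {
  for (seed in 1:10) {
    rep_ <- tiny_report(image_size = 64, tumor_radius = 8, seed = seed)
    expect_gte(nrow(rep_$regions), 1)
    expect_equal(rep_$regions$severity[1], "high")
  }
})

test_that("anomaly reports serialize to JSON with reference statistics", {
  rep_ <- tiny_report(seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_anomaly_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$regions), nrow(rep_$regions))
  expect_equal(back$reference$mean, rep_$reference$mean, tolerance = 1e-12)
  expect_s3_class(tidy(rep_), "tbl_df")
})

test_that("small regions below min_size are suppressed as speckle", {
  mask <- matrix(0, 10, 10)
  mask[1:3, 1:3] <- 1   # area 9
  mask[9, 9] <- 1       # area 1 speckle
  expect_equal(nrow(extract_regions(mask, min_size = 5)), 1)
  expect_equal(nrow(extract_regions(mask, min_size = 1)), 2)
})
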