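test_that("dice and iou match the set-counting oracle on random masks", {
  set.seed(7)
  for (rep in 1:200) {
    h <- sample(2:32, 1)
    w <- sample(2:32, 1)
    p <- matrix(rbinom(h * w, 1, runif(1, 0.05, 0.6)), h, w)
    t <- matrix(rbinom(h * w, 1, runif(1, 0.05, 0.6)), h, w)
    expect_identical(dice_coefficient(p, t), set_dice(p, t))
    expect_identical(iou(p, t), set_iou(p, t))
    # Dice-IoU identity d = 2j/(1+j), exact in pixel counts
    j <- iou(p, t)
    expect_equal(dice_coefficient(p, t), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("dice/iou handle the worked confusion example and edge cases", {
  cm <- confusion_masks(tp = 93, fp = 5, fn = 5)
  expect_equal(dice_coefficient(cm$pred, cm$truth), 186 / 196)
  expect_equal(iou(cm$pred, cm$truth), 93 / 103)

  a <- matrix(1, 4, 4)
  expect_identical(dice_coefficient(a, a), 1)
  expect_identical(iou(a, a), 1)

  checker <- matrix(rep(c(1, 0), 8), 4, 4)
  expect_identical(dice_coefficient(checker, 1 - checker), 0)
  expect_identical(iou(checker, 1 - checker), 0)

  z <- matrix(0, 3, 3)
  expect_identical(dice_coefficient(z, z), 1)
  expect_identical(iou(z, z), 1)

  expect_error(dice_coefficient(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "sonoseg_shape_error")
  expect_error(iou(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "sonoseg_shape_error")
})

test_that("soft dice loss matches closed-form values and decreases toward truth", {
  ones <- matrix(1, 2, 2)
  expect_equal(soft_dice_loss(ones, ones), 0)
  z <- matrix(0, 2, 2)
  expect_equal(soft_dice_loss(z, z), 0)   # smooth rescues 0/0
  half <- matrix(0.5, 2, 2)
  expect_equal(soft_dice_loss(half, ones, smooth = 1), 2 / 7)

  set.seed(3)
  truth <- matrix(rbinom(64, 1, 0.3), 8, 8)
  worst <- 1 - truth
  prev <- Inf
  for (t in seq(0, 1, length.out = 11)) {
    cur <- soft_dice_loss(worst * (1 - t) + truth * t, truth)
    expect_gte(cur, 0)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("jaccard distance follows the smooth-scaled formulation", {
  a <- matrix(1, 10, 10)
  expect_equal(jaccard_distance(a, a), 0)
  z <- matrix(0, 10, 10)
  expect_equal(jaccard_distance(z, a, smooth = 100), 50)
  expect_equal(jaccard_distance(z, z), 0)
  # smooth -> Inf limit kills the loss for any masks
  expect_lt(jaccard_distance(z, a, smooth = 1e8, scaled = FALSE), 1e-5)
  # unscaled variant lives in [0, 1]
  expect_equal(jaccard_distance(z, a, smooth = 100, scaled = FALSE), 0.5)
})

test_that("binary accuracy counts thresholded agreement with ties positive", {
  t <- matrix(0, 10, 10)
  t[1, 1] <- 1
  expect_equal(binary_accuracy(t, t), 1)
  expect_equal(binary_accuracy(matrix(0, 10, 10), t), 0.99)
  # exactly 0.5 counts as positive
  expect_equal(binary_accuracy(matrix(0.5, 10, 10), matrix(1, 10, 10)), 1)
  expect_equal(binary_accuracy(matrix(0.5, 10, 10), matrix(0, 10, 10)), 0)
})
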