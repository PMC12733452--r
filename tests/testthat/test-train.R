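
test_that("the plateau scheduler multiplies the learning rate by 0.2 after 5 stale epochs", {
  fit <- frozen_toy_fit(max_epochs = 12)
  h <- fit$history
  expect_equal(h$lr[1:6], rep(1e-4, 6))
  expect_equal(h$lr[7], 2e-5)               # 1e-4 * 0.2 after the 5-epoch plateau
  expect_equal(h$lr[12], 1e-4 * 0.2^2)      # second reduction 5 stale epochs later
})

test_that("early stopping halts after 20 non-improving epochs with periodic checkpoints", {
  ckdir <- withr::local_tempdir()
  fit <- frozen_toy_fit(max_epochs = 40, ckdir = ckdir)
  expect_equal(nrow(fit$history), 21)       # 1 improving + 20 stale epochs
  expect_true(fit$stopped_early)
  expect_equal(fit$best_epoch, 1L)
  cks <- list.files(ckdir, pattern = "^epoch_")
  expect_setequal(cks, sprintf("epoch_%03d.rds", c(5, 10, 15, 20)))
  expect_true(file.exists(file.path(ckdir, "best.rds")))
})

test_that("training is deterministic per seed and lowers the dice loss", {
  stack <- phantom_slice_stack(16, image_size = 16, seed = 8)
  va <- phantom_slice_stack(4, image_size = 16, seed = 9)
  cfg <- train_config(batch_size = 8, learning_rate = 1e-3, max_epochs = 2,
                      seed = 7)
  f1 <- train(build_unet(model_spec("unet", input_size = c(16, 16, 3),
                                    base_width = 4, depth = 2, seed = 2)),
              stack, va, cfg)
  f2 <- train(build_unet(model_spec("unet", input_size = c(16, 16, 3),
                                    base_width = 4, depth = 2, seed = 2)),
              stack, va, cfg)
  expect_identical(f1$history$loss[1], f2$history$loss[1])
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$loss[2], f1$history$loss[1])
  # history records the auxiliary jaccard loss alongside
  expect_true(all(is.finite(f1$history$jaccard)))
})

test_that("only the training loader augments (call audit)", {
  stack <- phantom_slice_stack(8, image_size = 16, seed = 4)
  va <- phantom_slice_stack(4, image_size = 16, seed = 5)
  cfg <- train_config(batch_size = 4, learning_rate = 1e-3, max_epochs = 2,
                      seed = 3)
  reset_augment_audit()
  fit <- train(build_unet(model_spec("unet", input_size = c(16, 16, 3),
                                     base_width = 2, depth = 2, seed = 1)),
               stack, va, cfg, augment = augmentation_config())
  expect_equal(augment_calls(), 2L * 8L)    # epochs x training slices
  reset_augment_audit()
  evaluate(fit$model, va)
  predict_probs(fit$model, va$images)
  expect_equal(augment_calls(), 0L)         # val/test paths never augment
})

test_that("train rejects an empty training set", {
  va <- phantom_slice_stack(2, image_size = 16, seed = 5)
  empty <- list(images = array(0, c(16, 16, 3, 0)),
                masks = array(0, c(16, 16, 0)))
  m <- build_unet(model_spec("unet", input_size = c(16, 16, 3),
                             base_width = 2, depth = 2))
  expect_error(train(m, empty, va, train_config(max_epochs = 1)),
               class = "sonoseg_train_error")
})

test_that("evaluate applies the both-empty convention and macro averaging", {
  # all-zero model on all-empty masks: perfect by convention
  data <- list(images = array(0.1, c(8, 8, 3, 3)),
               masks = array(0, c(8, 8, 3)))
  zero_model <- function(images) array(0.01, dim(images)[c(1, 2, 4)])
  rep_ <- evaluate(zero_model, data)
  expect_equal(attr(rep_, "aggregate")$mean_dice, 1)

  # macro mean equals the hand-computed average of per-slice dice
  masks <- array(0, c(4, 4, 3))
  masks[1:2, 1:2, 1] <- 1
  masks[1:3, 1:3, 2] <- 1
  masks[1, 1, 3] <- 1
  preds <- array(0, c(4, 4, 3))
  preds[1:2, 1:2, ] <- 1
  pm <- function(images) preds
  rep2 <- evaluate(pm, list(images = array(0, c(4, 4, 3, 3)), masks = masks))
  d_hand <- mean(c(1, 2 * 4 / (4 + 9), 2 * 1 / (4 + 1)))
  expect_equal(attr(rep2, "aggregate")$mean_dice, d_hand)
  expect_s3_class(glance(rep2), "tbl_df")
  expect_equal(glance(rep2)$mean_dice, d_hand)
})

test_that("the optional jaccard-weighted objective matches its finite differences", {
  # internal auxiliary-loss gradient check at a random point
  set.seed(1)
  P <- array(runif(16), c(4, 4, 1, 1))
  Tm <- array(rbinom(16, 1, 0.4), c(4, 4, 1, 1))
  tp <- sonoseg:::tp_new()
  pid <- sonoseg:::tp_param(tp, P, "p")
  lid <- sonoseg:::nn_jaccard_loss(tp, pid, Tm, smooth = 100)
  g <- sonoseg:::tp_backward(tp, lid)$p
  eps <- 1e-6
  for (i in c(1, 7, 16)) {
    Pp <- P; Pp[i] <- Pp[i] + eps
    Pm <- P; Pm[i] <- Pm[i] - eps
    num <- (jaccard_distance(Pp, Tm) - jaccard_distance(Pm, Tm)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})
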