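test_that("the default U-Net has exactly 31,043,521 trainable parameters", {
  m <- build_unet(model_spec("unet"))
  expect_identical(count_trainable_parameters(m), 31043521L)
})

test_that("parameter accounting counts elements and honors freezing", {
  # a single biased 3x3 conv, 3 -> 64 channels
  fake <- list(params = list2env(list(w = array(0, c(3, 3, 3, 64)),
                                      b = numeric(64))),
               param_order = c("w", "b"),
               trainable = list2env(list(w = TRUE, b = TRUE)))
  expect_identical(count_trainable_parameters(fake), 1792L)

  m <- build_unet(model_spec("unet", input_size = c(16, 16, 3),
                             base_width = 4, depth = 2))
  expect_gt(count_trainable_parameters(m), 0L)
  freeze_parameters(m)
  expect_identical(count_trainable_parameters(m), 0L)

  man <- parameter_manifest(m)
  expect_true(all(c("name", "shape", "n", "trainable") %in% names(man)))
  expect_equal(sum(man$n), length(unlist(as.list(m$params))))
})

test_that("spec validation rejects inconsistent geometry", {
  expect_error(model_spec("unet", input_size = c(100, 100, 3), depth = 4),
               class = "sonoseg_spec_error")
  expect_error(model_spec("deeplab", aspp_rates = integer(0)),
               class = "sonoseg_spec_error")
  expect_error(model_spec("sgnn", input_size = c(64, 64, 3),
                          graph_grid = c(8, 8), top_k = 64),
               class = "sonoseg_spec_error")
  expect_error(model_spec("gat", input_size = c(64, 64, 3),
                          graph_grid = c(7, 7)),
               class = "sonoseg_spec_error")
})

test_that("all four builders emit sigmoid maps of the input spatial shape", {
  set.seed(1)
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 3, 2))
  specs <- list(
    model_spec("unet", input_size = c(32, 32, 3), base_width = 8, depth = 3),
    model_spec("deeplab", input_size = c(32, 32, 3), base_width = 8),
    model_spec("gat", input_size = c(32, 32, 3), graph_grid = c(8, 8)),
    model_spec("sgnn", input_size = c(32, 32, 3), graph_grid = c(8, 8),
               top_k = 6))
  for (sp in specs) {
    m <- build_model(sp)
    p <- predict_probs(m, x)
    expect_equal(dim(p), c(32, 32, 2))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("the DeepLab variant carries one ASPP branch per rate plus a 1x1", {
  m <- build_deeplab(model_spec("deeplab", input_size = c(32, 32, 3),
                                base_width = 8))
  nms <- parameter_manifest(m)$name
  expect_true("aspp0_w" %in% nms)                      # 1x1 branch
  expect_length(grep("^aspp[1-9]_w$", nms), 3)         # rates {6, 12, 18}
})

test_that("concatenated heads set the node embedding width K * F'", {
  sp <- model_spec("gat", input_size = c(64, 64, 3), graph_grid = c(8, 8),
                   heads = 8, head_dim = 8)
  m <- build_gat_segmenter(sp)
  man <- parameter_manifest(m)
  # first decoder transposed conv consumes the 64-wide node embedding
  expect_equal(man$shape[man$name == "dec1_w"], "2x2x64x32")
})

test_that("sgnn with k = N - 1 reproduces the dense gat output", {
  set.seed(4)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  for (seed in 1:3) {
    mg <- build_gat_segmenter(model_spec("gat", input_size = c(32, 32, 3),
                                         graph_grid = c(4, 4), seed = seed))
    ms <- build_sgnn_segmenter(model_spec("sgnn", input_size = c(32, 32, 3),
                                          graph_grid = c(4, 4), top_k = 15,
                                          seed = seed))
    expect_lt(max(abs(predict_probs(mg, x) - predict_probs(ms, x))), 1e-5)
  }
})

test_that("checkpoints round-trip the full model state", {
  m <- build_unet(model_spec("unet", input_size = c(16, 16, 3),
                             base_width = 4, depth = 2, seed = 6))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  p1 <- predict_probs(m, x)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_equal(predict_probs(m2, x), p1, tolerance = 1e-14)
})

test_that("weight initialization is deterministic per spec seed", {
  a <- build_unet(model_spec("unet", input_size = c(16, 16, 3),
                             base_width = 4, depth = 2, seed = 3))
  b <- build_unet(model_spec("unet", input_size = c(16, 16, 3),
                             base_width = 4, depth = 2, seed = 3))
  expect_identical(as.list(a$params), as.list(b$params))
})

test_that("model specs round-trip through YAML", {
  sp <- model_spec("sgnn", input_size = c(64, 64, 3), graph_grid = c(8, 8),
                   top_k = 8, seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(sp, path)
  expect_equal(read_model_spec(path), sp)
})
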