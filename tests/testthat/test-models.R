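test_that("presets reproduce the published hyperparameter tables", {
  r <- model_config(preset = "rvit")
  expect_identical(
    unclass(r)[c("image_size", "patch_size", "embed_dim", "depth", "heads",
                 "mlp_size", "attention_dropout", "rotations")],
    list(image_size = 224L, patch_size = 16L, embed_dim = 142L, depth = 10L,
         heads = 10L, mlp_size = 480L, attention_dropout = 0.1,
         rotations = 4L))
  expect_true(r$use_rotated_embedding && r$use_depthwise_stem)
  b <- model_config(preset = "base_vit")
  expect_identical(
    unclass(b)[c("embed_dim", "depth", "heads", "mlp_size")],
    list(embed_dim = 768L, depth = 12L, heads = 12L, mlp_size = 1024L))
  expect_false(b$use_rotated_embedding || b$use_depthwise_stem)
  v1 <- model_config(preset = "rvit_variant1")
  expect_false(v1$use_rotated_embedding)
  expect_true(v1$use_depthwise_stem)
  v2 <- model_config(preset = "rvit_variant2")
  expect_true(v2$use_rotated_embedding)
  expect_false(v2$use_depthwise_stem)
  expect_error(model_config(preset = "nope"), "unknown preset")
  expect_error(model_config(image_size = 30, patch_size = 16), "divisible")
  expect_error(model_config(rotations = 3), "1, 2, 4")
})

test_that("base_vit has a 196-token grid at the published geometry", {
  b <- model_config(preset = "base_vit")
  expect_identical(rvit:::n_patches(b), 196)
})

test_that("rotation averaging adds no parameters, the stem does", {
  # the published configuration
  expect_identical(count_parameters(build_model("rvit", seed = 1)),
                   count_parameters(build_model("rvit_variant1", seed = 2)))
  expect_lt(count_parameters(build_model("rvit_variant2", seed = 3)),
            count_parameters(build_model("rvit", seed = 3)))
  # five random scaled-down configurations
  withr::with_seed(40, {
    for (i in 1:5) {
      D <- sample(c(16L, 24L, 32L), 1)
      h <- sample(2:5, 1)
      args <- list(image_size = 32L, patch_size = sample(c(4L, 8L), 1),
                   embed_dim = D, depth = sample(1:3, 1), heads = h,
                   mlp_size = sample(c(24L, 48L), 1),
                   rotations = sample(c(1L, 2L, 4L), 1), channels = 1L)
      cfg_r <- do.call(model_config, c(args, list(
        use_rotated_embedding = TRUE, use_depthwise_stem = TRUE)))
      cfg_v1 <- do.call(model_config, c(args, list(
        use_rotated_embedding = FALSE, use_depthwise_stem = TRUE)))
      cfg_v2 <- do.call(model_config, c(args, list(
        use_rotated_embedding = TRUE, use_depthwise_stem = FALSE)))
      expect_identical(count_parameters(build_model(cfg_r, seed = i)),
                       count_parameters(build_model(cfg_v1, seed = i + 1)))
      expect_lt(count_parameters(build_model(cfg_v2, seed = i)),
                count_parameters(build_model(cfg_r, seed = i)))
    }
  })
})

test_that("the parameter count is independent of the rotation count", {
  for (k in c(1L, 2L, 4L)) {
    m <- build_model(small_config(rotations = k), seed = 9)
    expect_identical(count_parameters(m),
                     count_parameters(build_model(small_config(), seed = 10)))
  }
})

test_that("an affine map counts d_in * d_out + d_out parameters", {
  proj <- new_patch_projector(7, 5)
  expect_identical(length(proj$W) + length(proj$b), 7L * 5L + 5L)
})

test_that("rotation-averaged models are exactly invariant, ablations are not", {
  imgs <- lapply(1:3, function(i) rand_image(64, seed = 50 + i))
  m_r <- build_model(small_config("rvit"), seed = 51)
  expect_lt(max_rotation_deviation(m_r, imgs), 1e-4)
  m_v2 <- build_model(small_config("rvit_variant2"), seed = 52)
  expect_lt(max_rotation_deviation(m_v2, imgs), 1e-4)
  m_v1 <- build_model(small_config("rvit_variant1"), seed = 53)
  expect_gt(max_rotation_deviation(m_v1, imgs), 1e-3)
  m_b <- build_model(small_config("base_vit"), seed = 54)
  expect_gt(max_rotation_deviation(m_b, imgs), 1e-3)
})

test_that("forcing k = 1 reproduces the no-rotation variant bit-exactly", {
  cfg_k1 <- small_config("rvit", rotations = 1L)
  cfg_v1 <- small_config("rvit_variant1")
  m_k1 <- build_model(cfg_k1, seed = 60)
  m_v1 <- build_model(cfg_v1, seed = 61)
  m_v1$params <- m_k1$params          # identical weights
  imgs <- lapply(1:4, function(i) rand_image(64, seed = 70 + i))
  expect_identical(model_logits(m_k1, imgs), model_logits(m_v1, imgs))
})

test_that("checkpoints round-trip the configuration and weights losslessly", {
  m <- build_model(tiny_config(), seed = 80)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(unclass(m2$config), unclass(m$config))
  expect_identical(m2$params, m$params)
  img <- rand_image(16, seed = 81)
  expect_identical(model_logits(m, img), model_logits(m2, img))
  expect_error(load_checkpoint(tempfile()), "not found")
})

test_that("images with the wrong geometry or channels are rejected", {
  m <- build_model(tiny_config(), seed = 82)
  expect_error(model_logits(m, matrix(0, 8, 8)), "expects 16 x 16")
  m3 <- build_model(tiny_config(channels = 3L), seed = 83)
  # grayscale input is replicated to the expected channel count
  expect_silent(model_logits(m3, rand_image(16, seed = 84)))
})
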