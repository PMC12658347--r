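test_that("configuration validation names the violated invariant", {
  expect_error(model_config(stage_channels = c(64, 32, 16, 8)),
               "monotone nondecreasing")
  expect_error(model_config(enc_blocks = c(1, 1)), "enc_blocks")
  expect_error(model_config(heads = c(3, 4, 8, 8)), "heads")
  expect_error(model_config(input_size = 100), "divisible")
  expect_silent(validate_config(model_config()))
})

test_that("the network restores input resolution for any valid size", {
  set.seed(51)
  net <- build_model(tiny_model_config())
  x <- rand_arr(2, 3, 64, 64)
  y <- forward(net, x)
  expect_identical(dim(y), c(2L, 1L, 64L, 64L))
  expect_true(all(is.finite(y)))
  y2 <- forward(net, rand_arr(1, 3, 128, 128))   # size-agnostic contract
  expect_identical(dim(y2), c(1L, 1L, 128L, 128L))
  expect_error(forward(net, rand_arr(1, 3, 48, 48)), "divisible by 64")
})

test_that("skip fusion is an element-wise sum", {
  a <- rand_arr(1, 4, 8, 8)
  expect_identical(fuse_skip(a, a * 0), a)
  expect_equal(max(abs(fuse_skip(a, -a))), 0)
  b <- rand_arr(1, 4, 8, 8)
  want <- array(0, dim(a))
  for (i in seq_along(a)) want[i] <- a[i] + b[i]
  expect_equal(fuse_skip(a, b), want, tolerance = 1e-15)
  expect_error(fuse_skip(a, rand_arr(1, 4, 8, 4)), "share shape")
})

test_that("gradients flow to every trainable tensor of the full network", {
  set.seed(52)
  net <- build_model(micro_model_config())
  x <- dermseg:::as_chwb(rand_arr(2, 3, 32, 32))
  zero_grads(net)
  y <- mod_forward(net, x, training = TRUE)
  mod_backward(net, array(1, dim(y)))
  for (r in param_refs(net)) {
    g <- r$mod$gr[[r$name]]
    expect_true(all(is.finite(g)), info = r$path)
    expect_gt(sum(abs(g)), 0)
  }
})

test_that("ablation switches control component presence in the profile", {
  base <- tiny_model_config()
  pr <- profile_network(base)
  expect_gt(pr$components$params[["encoder_msq"]], 0)
  expect_gt(pr$components$params[["decoder_msq"]], 0)
  expect_gt(pr$components$params[["warm"]], 0)

  no_msq <- modifyList(base, list(use_msqformer = "none"))
  class(no_msq) <- "dermseg_config"
  pr2 <- profile_network(no_msq)
  expect_equal(pr2$components$params[["encoder_msq"]], 0)
  expect_equal(pr2$components$params[["decoder_msq"]], 0)

  enc_only <- modifyList(base, list(use_msqformer = "encoder_only"))
  class(enc_only) <- "dermseg_config"
  pr3 <- profile_network(enc_only)
  expect_gt(pr3$components$params[["encoder_msq"]], 0)
  expect_equal(pr3$components$params[["decoder_msq"]], 0)

  dec_only <- modifyList(base, list(use_msqformer = "decoder_only"))
  class(dec_only) <- "dermseg_config"
  pr4 <- profile_network(dec_only)
  expect_equal(pr4$components$params[["encoder_msq"]], 0)
  expect_gt(pr4$components$params[["decoder_msq"]], 0)

  no_cnn <- modifyList(base, list(use_cnn_block = FALSE))
  class(no_cnn) <- "dermseg_config"
  pr5 <- profile_network(no_cnn)
  expect_equal(pr5$components$params[["encoder_cnn"]], 0)

  no_warm <- modifyList(base, list(use_warm = FALSE))
  class(no_warm) <- "dermseg_config"
  expect_equal(profile_network(no_warm)$components$params[["warm"]], 0)

  ss <- modifyList(base, list(msq_single_scale = TRUE))
  class(ss) <- "dermseg_config"
  expect_lt(profile_network(ss)$components$params[["encoder_msq"]],
            pr$components$params[["encoder_msq"]])
})

test_that("parameter counts are input-size invariant and scale quadratically in width", {
  cfg <- tiny_model_config()
  p64 <- profile_network(cfg, input_size = 64)
  p128 <- profile_network(cfg, input_size = 128)
  expect_identical(p64$params, p128$params)
  # MACs of the convolutional parts scale linearly with pixel count
  expect_equal(p128$components$macs[["encoder_cnn"]] /
                 p64$components$macs[["encoder_cnn"]], 4)
  # doubled widths roughly quadruple the parameter count
  cfg2 <- model_config(input_size = 64, stage_channels = c(16, 32, 64),
                       enc_blocks = c(1, 1, 1), dec_blocks = c(1, 1),
                       heads = c(2, 2, 4), gate_width = 8)
  ratio <- profile_network(cfg2)$params[["total"]] / p64$params[["total"]]
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("a 1x1 convolution with bias has cin*cout + cout parameters", {
  expect_equal(count_params(dermseg:::conv1x1(8, 4)), 36)
})

test_that("checkpoints round-trip weights and validate their config", {
  set.seed(53)
  net <- build_model(micro_model_config())
  x <- rand_arr(1, 3, 32, 32)
  y1 <- forward(net, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  ck <- load_checkpoint(path)
  expect_equal(forward(ck$model, x), y1, tolerance = 1e-12)
  # tampering with the stored config is rejected
  raw <- readRDS(path)
  raw$config$gate_width <- 99L
  saveRDS(raw, path)
  expect_error(load_checkpoint(path), "hash mismatch")
})
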