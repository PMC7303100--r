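test_that("parameter counting matches closed-form expectations", {
  expect_equal(count_parameters(list(w = matrix(0, 3, 70), b = numeric(3))), 213)
  expect_equal(count_parameters(list(w = array(0, c(3, 3, 3, 1, 1, 8)),
                                     b = numeric(8))), 224)
  expect_equal(count_parameters(list()), 0L)
})

test_that("pairwise reuse of the two-path network shares every parameter", {
  cfg <- tiny_config()
  a <- build_model("two_path_3d", cfg, seed = 5)
  b <- build_model("s_two_path_3d", cfg, seed = 5)
  expect_identical(count_parameters(a), count_parameters(b))
  expect_identical(names(a$params), names(b$params))
})

test_that("multi-path models differ from two-path only through the fusion width", {
  cfg <- model_config(initial_channels = c(2L, 3L, 4L), growth_rate = 5L,
                      path_pool = 2L)
  two <- build_model("two_path_3d", cfg, seed = 5)
  five <- build_model("five_path_3d", cfg, seed = 5)
  c3 <- cfg$initial_channels[3]
  delta_c0 <- (5L - 2L) * c3
  k3 <- cfg$spatial_kernel^3
  # every trunk layer's input widens by delta_c0; the head gains 3 * delta_c0
  n_layers <- cfg$n_blocks * cfg$layers_per_block
  expected <- n_layers * delta_c0 * k3 * cfg$growth_rate + 3L * delta_c0
  expect_equal(count_parameters(five) - count_parameters(two), expected)
})

test_that("dense blocks grow channels by layers x growth rate", {
  cfg <- model_config(initial_channels = c(2L, 2L, 20L), growth_rate = 10L)
  x <- array(rnorm(8 * 8 * 8 * 1 * 20 * 1), c(8, 8, 8, 1, 20, 1))
  # rebuild a block with 20 input channels to match the first trunk block
  prm <- list(block1_layer1_w = oct4dmotion:::glorot_conv(3, 1, 20, 10),
              block1_layer1_b = numeric(10),
              block1_layer2_w = oct4dmotion:::glorot_conv(3, 1, 30, 10),
              block1_layer2_b = numeric(10))
  out <- oct4dmotion:::dense_block_fwd(prm, x, 1, cfg, single = FALSE)$out
  expect_equal(dim(out)[5], 40L)     # 20 + 2 layers x growth 10
})

test_that("the trunk pools twice and yields input-plus-60 GAP features", {
  cfg <- model_config(initial_channels = c(2L, 2L, 3L), growth_rate = 10L)
  m <- build_model("five_path_3d", cfg, seed = 2, precision = "double")
  # trunk input: five paths x 3 channels at full 32^3 resolution
  x <- array(rnorm(32^3 * 15), c(32, 32, 32, 1, 15, 1))
  tr <- oct4dmotion:::trunk_fwd(m$params, x, cfg, dim4d = FALSE,
                                single = FALSE)
  expect_equal(tr$gap_dim[1:3], c(8L, 8L, 8L))      # 32 / 2 / 2
  expect_equal(nrow(tr$features), 15L + 60L)        # 3 blocks x 2 x 10
  expect_equal(m$n_features, 75L)
})

test_that("every architecture forwards to a finite 3-vector", {
  X <- array(runif(32^3 * 5 * 2), c(32, 32, 32, 5, 1, 2))
  for (arch in oct4dmotion:::arch_names()) {
    m <- build_model(arch, tiny_config(aux_outputs = TRUE), seed = 3)
    out <- oct4dmotion:::net_forward(m, X)$pred
    expect_equal(dim(out$y_tn), c(3L, 2L))
    expect_true(all(is.finite(out$y_tn)))
    expect_equal(dim(out$y_tn1), c(3L, 2L))
    expect_equal(dim(out$y_tn2), c(3L, 2L))
  }
})

test_that("forward validates its input contract", {
  m <- build_model("five_path_4d", tiny_config(), seed = 3)
  s <- tiny_dataset()$sequences[[1]]
  pred <- forward(m, s)
  expect_s3_class(pred, "oct_prediction")
  expect_length(pred$y_tn, 3)
  expect_null(pred$y_tn1)              # no auxiliary heads on this model
  expect_error(forward(m, aperm(s$volumes, c(4, 1, 2, 3))), "32 x 32 x 32 x 5")
  expect_error(forward(m, s$volumes[, , , 1:2]), "32 x 32 x 32 x 5")
})

test_that("auxiliary heads appear exactly when enabled", {
  m <- build_model("five_path_4d", tiny_config(aux_outputs = TRUE), seed = 4)
  pred <- forward(m, tiny_dataset()$sequences[[2]])
  expect_length(pred$y_tn1, 3)
  expect_length(pred$y_tn2, 3)
  expect_true(all(c("head_n1_w", "head_n2_w") %in% names(m$params)))
})

test_that("path weights are shared: one mutation moves all paths together", {
  m <- build_model("five_path_3d", tiny_config(), seed = 6,
                   precision = "double")
  s <- tiny_dataset()$sequences[[1]]
  base <- forward(m, s)$y_tn
  m$params$path1_w <- m$params$path1_w * 0    # kills every path at once
  dead <- forward(m, s)$y_tn
  # with all paths silenced the prediction collapses to the head bias
  expect_equal(dead, forward(m, {
    s2 <- s; s2$volumes[] <- 0; s2
  })$y_tn, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(base, dead)))
})

test_that("gradients flow through every architecture end-to-end", {
  set.seed(41)
  X <- array(runif(32^3 * 5 * 2), c(32, 32, 32, 5, 1, 2))
  tg <- list(tn = matrix(rnorm(6), 2, 3), tn1 = matrix(rnorm(6), 2, 3),
             tn2 = matrix(rnorm(6), 2, 3))
  for (arch in oct4dmotion:::arch_names()) {
    m <- build_model(arch, tiny_config(aux_outputs = TRUE), seed = 7,
                     precision = "double")
    fw <- oct4dmotion:::net_forward(m, X, keep = TRUE)
    dp <- oct4dmotion:::motion_loss_grad(fw$pred, tg, 0.5, 0.25)
    gr <- oct4dmotion:::net_backward(m, fw$cache, dp)
    expect_setequal(names(gr), names(m$params))
    gnorm <- vapply(gr, function(g) max(abs(g)), numeric(1))
    expect_true(all(is.finite(gnorm)))
    expect_true(all(gnorm > 0))        # no dead parameter blocks at init
  }
})
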