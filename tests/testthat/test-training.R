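test_that("the loss reproduces hand-computed values", {
  p <- list(y_tn = matrix(c(0, 0, 0), 3, 1))
  t1 <- list(tn = matrix(c(1, 0, 0), 1, 3))
  expect_equal(motion_loss(p, t1), 1.0)

  # adding a weighted auxiliary term with squared error 4
  p2 <- list(y_tn = matrix(c(0, 0, 0), 3, 1), y_tn1 = matrix(c(0, 0, 0), 3, 1))
  t2 <- list(tn = matrix(c(1, 0, 0), 1, 3), tn1 = matrix(c(2, 0, 0), 1, 3))
  expect_equal(motion_loss(p2, t2, w_n1 = 0.5), 1 + 0.5 * 4)

  expect_equal(motion_loss(list(y_tn = t1$tn), t1), 0)
})

test_that("the regularized loss collapses bit-exactly to plain MSE at zero weights", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    preds <- list(y_tn = matrix(rnorm(3 * n), 3, n),
                  y_tn1 = matrix(rnorm(3 * n), 3, n),
                  y_tn2 = matrix(rnorm(3 * n), 3, n))
    tg <- list(tn = matrix(rnorm(3 * n), n, 3),
               tn1 = matrix(rnorm(3 * n), n, 3),
               tn2 = matrix(rnorm(3 * n), n, 3))
    plain <- motion_loss(list(y_tn = preds$y_tn), tg)
    reg0 <- motion_loss(preds, tg, w_n1 = 0, w_n2 = 0)
    expect_identical(reg0, plain)
  }
})

test_that("the loss is invariant to batch order", {
  set.seed(52)
  n <- 8
  preds <- list(y_tn = matrix(rnorm(3 * n), 3, n))
  tg <- list(tn = matrix(rnorm(3 * n), n, 3))
  perm <- sample(n)
  expect_equal(motion_loss(preds, tg),
               motion_loss(list(y_tn = preds$y_tn[, perm]),
                           list(tn = tg$tn[perm, ])),
               tolerance = 1e-12)
})

test_that("loss contracts are enforced", {
  p <- list(y_tn = matrix(0, 3, 2))
  tg <- list(tn = matrix(0, 2, 3))
  expect_error(motion_loss(p, tg, w_n1 = 0.5), "auxiliary")
  expect_error(motion_loss(p, tg, w_n1 = 1.5), "0, 1")
  expect_error(motion_loss(list(y_tn = matrix(0, 3, 3)), tg), "batch sizes")
})

test_that("ROI splits are disjoint, covering, leak-free and reproducible", {
  sp <- split_rois(0:39, n_test = 5, n_val = 5, seed = 3)
  expect_length(sp$train, 30)
  expect_length(sp$val, 5)
  expect_length(sp$test, 5)
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), 0:39)
  expect_identical(sp, split_rois(0:39, 5, 5, seed = 3))

  desk <- split_rois(0:7, n_test = 2, n_val = 2, seed = 1)
  expect_equal(lengths(desk[c("train", "val", "test")]),
               c(train = 4L, val = 2L, test = 2L))
  expect_error(split_rois(0:7, 4, 4), "more than")
})

test_that("training records history, checkpoints and stays deterministic", {
  ds <- tiny_dataset()
  sp <- split_rois(0:2, n_test = 1, n_val = 1, seed = 2)
  tc <- train_config(epochs = 3, batch_size = 2, learning_rate = 1e-3,
                     seed = 5, microbatch = 2)
  m <- build_model("two_path_3d", tiny_config(), seed = 5)
  t1 <- train_model(m, ds, sp, tc)
  expect_equal(nrow(t1$history), 3)
  expect_true(all(is.finite(t1$history$train_loss)))
  expect_true(t1$best_epoch %in% 1:3)
  expect_identical(t1$history,
                   train_model(m, ds, sp, tc)$history)
})

test_that("loss weights require matching auxiliary heads and both settings run", {
  ds <- tiny_dataset()
  sp <- split_rois(0:2, n_test = 1, n_val = 1, seed = 2)
  tc <- train_config(epochs = 1, batch_size = 2, learning_rate = 1e-3,
                     seed = 5, microbatch = 2)
  plain <- build_model("five_path_4d", tiny_config(), seed = 5)
  expect_error(train_model(plain, ds, sp, tc, w_n1 = 0.75, w_n2 = 0.75),
               "aux_outputs")
  aux <- build_model("five_path_4d", tiny_config(aux_outputs = TRUE), seed = 5)
  t_aux <- train_model(aux, ds, sp, tc, w_n1 = 0.75, w_n2 = 0.75)
  t_plain <- train_model(aux, ds, sp, tc, w_n1 = 0, w_n2 = 0)
  expect_equal(nrow(t_aux$history), 1)
  expect_equal(nrow(t_plain$history), 1)
  # the auxiliary targets contribute iff the weights are non-zero
  expect_gt(t_aux$history$train_loss, t_plain$history$train_loss)
})

test_that("a small network overfits a handful of sequences", {
  ds <- tiny_dataset()
  tg <- oct4dmotion:::dataset_targets(ds)
  idx <- 1:4
  tc <- train_config(epochs = 1, batch_size = 4, learning_rate = 3e-3,
                     seed = 8, microbatch = 4)
  m <- build_model("two_path_3d", desk_model_config(), seed = 8)
  opt <- oct4dmotion:::adam_init(m$params, tc$learning_rate)
  set.seed(8)
  loss <- NA
  for (step in 1:300) {
    st <- oct4dmotion:::train_step(m, ds, tg, idx, tc, 0, 0, NULL)
    m$params <- oct4dmotion:::adam_update(opt, m$params, st$grads)
    loss <- st$loss
  }
  expect_lt(loss, 1e-3)
})

test_that("pairwise summation predicts near zero on static sequences after training", {
  # the s-two-path network sums four pairwise estimates; trained on static
  # sequences it must learn to output (0, 0, 0) for identical volumes
  p <- make_phantom(77)
  tr0 <- sample_trajectory()
  tr0$shifts[] <- 0
  seqs <- lapply(1:8, function(i) {
    set.seed(100 + i)
    origin <- runif(3, -1, 1)
    make_sequence(p, tr0, roi_id = i %% 2L, origin_mm = origin)
  })
  ds <- structure(list(sequences = seqs,
                       manifest = data.frame(roi_id = sapply(seqs, `[[`, "roi_id")),
                       seed = 1L), class = "oct_dataset")
  tg <- oct4dmotion:::dataset_targets(ds)
  tc <- train_config(epochs = 1, batch_size = 8, learning_rate = 3e-3,
                     seed = 9, microbatch = 8)
  m <- build_model("s_two_path_3d", tiny_config(), seed = 9)
  opt <- oct4dmotion:::adam_init(m$params, tc$learning_rate)
  set.seed(9)
  for (step in 1:60) {
    st <- oct4dmotion:::train_step(m, ds, tg, 1:8, tc, 0, 0, NULL)
    m$params <- oct4dmotion:::adam_update(opt, m$params, st$grads)
  }
  pred <- forward(m, seqs[[1]])$y_tn
  expect_lt(max(abs(pred)), 0.05)
})

test_that("training-time augmentation hooks into batch assembly", {
  ds <- tiny_dataset()
  sp <- split_rois(0:2, n_test = 1, n_val = 1, seed = 2)
  tc <- train_config(epochs = 1, batch_size = 2, learning_rate = 1e-3,
                     seed = 5, microbatch = 2)
  m <- build_model("two_path_3d", tiny_config(), seed = 5)
  t_plain <- train_model(m, ds, sp, tc)
  t_aug <- train_model(m, ds, sp, tc, augment = random_flip_sequence)
  expect_false(identical(t_plain$history$train_loss, t_aug$history$train_loss))
})
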