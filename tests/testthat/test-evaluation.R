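test_that("per-axis MAE matches hand arithmetic and degenerate conventions", {
  preds <- rbind(c(0.1, 0, 0), c(0.3, 0, 0))
  targets <- rbind(c(0.2, 0, 0), c(0.1, 0, 0))
  m <- mae_per_axis(preds, targets)
  expect_equal(m$mae[1], 0.15)
  expect_equal(m$mae[2:3], c(0, 0))

  perfect <- mae_per_axis(targets, targets)
  expect_equal(perfect$mae, c(0, 0, 0))

  single <- mae_per_axis(matrix(c(1, 2, 3), 1), matrix(c(0, 0, 0), 1))
  expect_equal(single$sd, c(0, 0, 0))
  expect_error(mae_per_axis(preds, targets[1, , drop = FALSE]), "equal")
})

test_that("rMAE normalizes by the per-axis target spread", {
  targets <- rbind(c(1, 0.5, 2), c(-1, -0.5, -2))
  preds <- rbind(c(0.8, 0.5, 2), c(-0.6, -0.5, -2))
  r <- rmae(preds, targets)
  # x-axis errors 0.2 and 0.4 against sd sqrt(2); other axes exact
  expect_equal(mean(abs(c(0.2, 0.4)) / sd(c(1, -1))) / 3, r$mean,
               tolerance = 1e-10)
  expect_equal(r$per_sample, c(0.2 / sqrt(2) / 3, 0.4 / sqrt(2) / 3),
               tolerance = 1e-10)

  # the worked single-axis example: errors (0.2, 0.4), sd(targets) = 1.41421
  ax <- abs(c(0.8, -0.6) - c(1, -1)) / sd(c(1, -1))
  expect_equal(mean(ax), 0.2121, tolerance = 1e-3)

  expect_equal(rmae(targets, targets)$mean, 0)
  # constant offset: per-axis rMAE = |c| / sd
  off <- sweep(targets, 2, c(0.3, 0.1, 0.2), `+`)
  expect_equal(rmae(off, targets)$mean,
               mean(c(0.3, 0.1, 0.2) / apply(targets, 2, sd)),
               tolerance = 1e-10)
  expect_error(rmae(cbind(1:3, 1:3, 1:3), cbind(1:3, rep(1, 3), 1:3)),
               "variance")
})

test_that("the zero predictor's rMAE equals mean |target| over target sd", {
  set.seed(61)
  targets <- matrix(rnorm(300), 100, 3)
  r <- rmae(matrix(0, 100, 3), targets)
  expected <- mean(sweep(abs(targets), 2, apply(targets, 2, sd), `/`))
  expect_equal(r$mean, expected, tolerance = 1e-12)
})

test_that("aCC hits its limits and is invariant to positive affine maps", {
  set.seed(62)
  targets <- matrix(rnorm(60), 20, 3)
  expect_equal(acc_metric(targets, targets), 100)
  expect_equal(acc_metric(-targets, targets), -100)
  noisy <- 2 * targets + 0.3 + 1e-9 * matrix(rnorm(60), 20, 3)
  expect_equal(acc_metric(noisy, targets), 100, tolerance = 1e-4)
  expect_equal(acc_metric(5 * targets + 2, targets), 100, tolerance = 1e-10)
  expect_error(acc_metric(matrix(1, 5, 3), targets[1:5, ]), "degenerate")
})

test_that("the paired Wilcoxon comparison behaves on constructed samples", {
  set.seed(63)
  a <- runif(20)
  same <- wilcoxon_compare(a, a)
  expect_false(same$significant)
  expect_equal(same$p, 1)
  expect_equal(same$n_effective, 0L)

  shifted <- wilcoxon_compare(a + 1.0, a)
  expect_true(shifted$significant)
  expect_lt(shifted$p, 0.05)

  expect_error(wilcoxon_compare(a[1:3], a[1:3]), "6")
  expect_error(wilcoxon_compare(a, a[1:10]), "equal length")
})

test_that("magnitude bins are quantile-balanced and track constructed error growth", {
  set.seed(64)
  n <- 400
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  targets <- dirs * runif(n, 0.2, 2.4)
  binned <- magnitude_binned_mae(targets, targets)
  expect_equal(binned$n, rep(100L, 4), tolerance = 0.011)
  expect_equal(binned$mae, rep(0, 4))

  # error proportional to magnitude gives strictly increasing bin MAE
  preds <- targets * 1.2
  grow <- magnitude_binned_mae(preds, targets)
  expect_true(all(diff(grow$mae) > 0))
  expect_error(magnitude_binned_mae(targets[1:3, ], targets[1:3, ], 4), "fewer")
})

test_that("evaluation reports assemble and serialize", {
  ds <- tiny_dataset()
  m <- build_model("two_path_3d", tiny_config(), seed = 3)
  rep_ <- evaluate_model(m, ds)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n, 6)
  expect_length(rep_$per_sample_rmae, 6)
  expect_true(all(rep_$mae$mae >= 0))

  path <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  write_report(rep_, path, csv)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n, 6)
  expect_equal(parsed$rmae_mean, rep_$rmae_mean, tolerance = 1e-12)
  expect_equal(nrow(read.csv(csv)), 6)
  unlink(c(path, csv))
})

test_that("robustness sweeps produce one report row per perturbation cell", {
  ds <- tiny_dataset()
  m <- build_model("two_path_3d", tiny_config(), seed = 3)
  rot <- robustness_sweep(m, ds, "rotation", levels = c(5, 20))
  expect_equal(nrow(rot), 4)           # 2 angles x {noise, motion}
  expect_setequal(rot$mode, c("noise", "motion"))
  dist <- robustness_sweep(m, ds, "distortion", levels = c(0.1, 0.25, 0.5))
  expect_equal(nrow(dist), 6)          # 3 probabilities x {1, 2} px
  expect_true(all(is.finite(dist$rmae_mean)))
})
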