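test_that("phantom generation is seed-deterministic and seed-sensitive", {
  p1 <- make_phantom(1)
  p2 <- make_phantom(1)
  p3 <- make_phantom(2)
  expect_identical(p1$grid, p2$grid)
  frac_diff <- mean(p1$grid != p3$grid)
  expect_gt(frac_diff, 0.01)
  expect_true(all(is.finite(p1$grid)))
  expect_gte(min(p1$grid), 0)
  expect_lte(max(p1$grid), 1)
})

test_that("degenerate texture gives constant intensity along depth below the surface", {
  p <- make_phantom(3, texture_params = list(attenuation_per_mm = 0,
                                             speckle_sigma = 0,
                                             hetero_sigma = 0,
                                             surface_amp_mm = 0))
  # flat surface, no attenuation, no speckle: below-surface voxels all share
  # one value, above-surface voxels another
  col <- p$grid[48, 48, ]
  below <- col[col > 0.5]
  expect_gt(length(below), 5)
  expect_lt(max(below) - min(below), 1e-12)
})

test_that("phantoms smaller than three FOVs are rejected", {
  expect_error(make_phantom(1, grid_size = c(64, 96, 96)), "96")
})

test_that("the FOV arithmetic maps (5, 5, 3.5) mm to exactly 32 voxels per axis", {
  expect_equal(fov_mm() / fov_pitch_mm(), c(32, 32, 32))
  expect_equal(fov_pitch_mm()[1], 0.15625)
})

test_that("acquisition at zero shift returns the reference crop, in range", {
  p <- make_phantom(4)
  v0 <- acquire_volume(p, c(0, 0, 0))
  expect_equal(dim(v0), c(32L, 32L, 32L))
  expect_identical(v0[1, 1, 1], p$grid[33, 33, 33])
  expect_gte(min(v0), 0)
  expect_lte(max(v0), 1)
})

test_that("a one-pitch shift equals integer re-indexing on the overlap", {
  p <- make_phantom(4)
  v0 <- acquire_volume(p, c(0, 0, 0))
  v1 <- acquire_volume(p, c(0.15625, 0, 0))      # exactly one voxel in x
  expect_equal(v1[1:31, , ], v0[2:32, , ], tolerance = 1e-12)
  vz <- acquire_volume(p, c(0, 0, 3.5 / 32))     # one voxel in z
  expect_equal(vz[, , 1:31], v0[, , 2:32], tolerance = 1e-12)
})

test_that("shifts beyond the phantom margin raise an out-of-bounds error", {
  p <- make_phantom(4)
  expect_error(acquire_volume(p, c(5.2, 0, 0)), "outside")
  expect_error(acquire_volume(p, c(0, 0, -3.6)), "outside")
})

test_that("acquisition is translation-consistent under cross-correlation", {
  p <- make_phantom(5)
  v0 <- acquire_volume(p, c(0, 0, 0))
  pitch <- fov_pitch_mm()
  # zero-padded (non-circular) cross-correlation, normalized by the overlap
  # size, searched over integer lags within +-8 voxels
  recover <- function(v1) {
    pad <- function(v) {
      a <- array(0, c(64, 64, 64)); a[1:32, 1:32, 1:32] <- v - mean(v); a
    }
    msk <- array(0, c(64, 64, 64)); msk[1:32, 1:32, 1:32] <- 1
    f0 <- fft(pad(v0)); f1 <- fft(pad(v1)); fm <- fft(msk)
    cc <- Re(fft(Conj(f0) * f1, inverse = TRUE))
    nn <- Re(fft(Conj(fm) * fm, inverse = TRUE))
    lag <- -8:8
    idx <- ifelse(lag >= 0, lag + 1, 64 + lag + 1)
    sub <- cc[idx, idx, idx] / pmax(nn[idx, idx, idx], 1)
    lag[arrayInd(which.max(sub), dim(sub))]
  }
  for (b in list(c(3, 0, 0), c(0, -5, 2), c(8, 8, -3), c(-6, 4, 7))) {
    v1 <- acquire_volume(p, b * pitch)
    # moving the FOV by +b moves the content by -b
    expect_true(all(abs(recover(v1) + b) <= 0.5 + 1e-9),
                info = paste("shift", paste(b, collapse = ",")))
  }
})

test_that("calibration round-trips mm through motor steps", {
  cal <- make_calibration(motor_steps_per_mm = c(1000, 800, 1250))
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(steps_to_mm(mm_to_steps(x, cal), cal), x, tolerance = 1e-12)
  expect_error(make_calibration(motor_steps_per_mm = c(0, 1, 1)), "positive")
})

test_that("volumes export as 32-page TIFF and read back", {
  p <- make_phantom(6)
  v <- acquire_volume(p, c(0, 0, 0))
  path <- tempfile(fileext = ".tiff")
  export_volume_tiff(v, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 32)
  expect_equal(pages[[5]], v[, , 5], tolerance = 1e-6)
  unlink(path)
})
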