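test_that("region mean series averages exactly the member voxels", {
  arr <- array(0, c(3, 1, 1, 4))
  arr[1, 1, 1, ] <- c(1, 2, 3, 4)
  arr[2, 1, 1, ] <- c(10, 20, 30, 40)
  arr[3, 1, 1, ] <- -c(1, 2, 3, 4)
  one <- array(c(TRUE, FALSE, FALSE), c(3, 1, 1))
  expect_equal(roi_mean_series(arr, one), c(1, 2, 3, 4))
  sym <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
  expect_equal(roi_mean_series(arr, sym), rep(0, 4))
  allm <- array(TRUE, c(3, 1, 1))
  expect_equal(roi_mean_series(arr, allm),
               colMeans(rbind(c(1, 2, 3, 4), c(10, 20, 30, 40), -c(1, 2, 3, 4))))
  expect_error(roi_mean_series(arr, array(FALSE, c(3, 1, 1))), "empty")
})

test_that("erosion removes exactly the exposed one-voxel layer", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  er <- erode_mask(cube)
  expect_equal(sum(er), 1L)
  expect_true(er[3, 3, 3])
  # a one-voxel-thick sheet erodes to nothing
  sheet <- array(FALSE, c(5, 5, 5)); sheet[2:4, 2:4, 3] <- TRUE
  expect_equal(sum(erode_mask(sheet)), 0L)
  # grid boundary counts as background
  full <- array(TRUE, c(3, 3, 3))
  expect_equal(sum(erode_mask(full)), 1L)
  # random blob: eroded subset of original, no eroded voxel touches background
  set.seed(12)
  blob <- array(runif(11 * 9 * 7) < 0.6, c(11, 9, 7))
  er <- erode_mask(blob)
  expect_true(all(blob[er]))
  idx <- which(er, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ni <- i + d[1]; nj <- j + d[2]; nk <- k + d[3]
      inside <- ni >= 1 && ni <= 11 && nj >= 1 && nj <= 9 && nk >= 1 && nk <= 7
      expect_true(inside && blob[ni, nj, nk])
    }
  }
})

test_that("occupancy rasterization keeps voxels at or above the clip", {
  # 2:1 nested grids: hand-enumerated occupancies
  hr <- array(FALSE, c(4, 4, 2))
  hr[1:2, 1:2, 1:2] <- TRUE          # target (1,1,1): occupancy 1
  hr[3, 1:2, 1:2] <- TRUE            # target (2,1,1): 4/8 = 0.5
  hr[1, 3, 1] <- TRUE                # target (1,2,1): 1/8 = 0.125
  hr[3:4, 3, 1:2] <- TRUE            # target (2,2,1): 4/8 = 0.5 - wait 2*1*2=4
  out <- rasterize_roi(hr, c(2, 2, 1), clip = 0.3)
  expect_true(out$voxels[1, 1, 1])   # fully covered survives any clip
  expect_true(out$voxels[2, 1, 1])
  expect_false(out$voxels[1, 2, 1])  # 12.5% < 30% is clipped off
  expect_true(out$voxels[2, 2, 1])
  # 25% occupancy is below a 0.3 clip; exactly at clip is kept
  hr2 <- array(FALSE, c(2, 2, 2)); hr2[1:2, 1, 1] <- TRUE  # 2/8 = 0.25
  expect_false(rasterize_roi(hr2, c(1, 1, 1), clip = 0.3)$voxels[1, 1, 1])
  expect_true(rasterize_roi(hr2, c(1, 1, 1), clip = 0.25)$voxels[1, 1, 1])
  expect_error(rasterize_roi(array(TRUE, c(3, 3, 3)), c(2, 2, 2)), "nested")
  # erosion of a rasterized region stays inside it
  set.seed(3)
  hr3 <- array(runif(8 * 8 * 8) < 0.7, c(8, 8, 8))
  ras <- rasterize_roi(hr3, c(4, 4, 4), clip = 0.3)
  expect_true(all(ras$voxels[erode_mask(ras)$voxels]))
})

test_that("nuisance regression returns residuals orthogonal to the design", {
  set.seed(8)
  n <- 40
  motion <- matrix(rnorm(n * 6), n, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  nu <- nuisance_set(rnorm(n), rnorm(n), motion, runif(n, 1800, 2200))
  X <- cbind(1, nu$wm_mean, nu$csf_mean, nu$motion, nu$tr_duration)
  ser <- array(rnorm(3 * 3 * 2 * n, 100, 5), c(3, 3, 2, n))
  res <- nuisance_regress(ser, nu)
  R <- t(matrix(res, ncol = n))
  for (j in seq_len(ncol(X))) {
    cs <- abs(colSums(R * X[, j])) /
      (sqrt(colSums(R^2)) * sqrt(sum(X[, j]^2)))
    expect_true(all(cs < 1e-8))
  }
  # a series equal to a motion regressor is annihilated
  ser2 <- array(rep(motion[, 3], each = 4), c(2, 2, 1, n))
  expect_equal(max(abs(nuisance_regress(ser2, nu))), 0, tolerance = 1e-10)
  # a zero-mean series orthogonal to all regressors passes through
  y <- qr.resid(qr(X), rnorm(n))
  ser3 <- array(y, c(1, 1, 1, n))
  expect_equal(as.vector(nuisance_regress(ser3, nu)), y, tolerance = 1e-10)
})

test_that("toy residuals match the closed-form normal-equations oracle", {
  set.seed(44)
  n <- 12  # just above the 10-column design
  nu <- nuisance_set(rnorm(n), rnorm(n),
                     matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, paste0("m", 1:6))),
                     runif(n, 1.8, 2.2))  # scaled to keep X'X well-conditioned
  y <- rnorm(n, 3)
  X <- cbind(1, nu$wm_mean, nu$csf_mean, nu$motion, nu$tr_duration)
  beta <- solve(t(X) %*% X, t(X) %*% y)  # normal equations
  expect_equal(as.vector(nuisance_regress(matrix(y), nu)),
               as.vector(y - X %*% beta), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  n <- 30
  wm <- rnorm(n)
  motion <- matrix(rnorm(n * 6), n, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  motion[, 2] <- wm  # duplicate of the WM regressor
  nu <- nuisance_set(wm, rnorm(n), motion, runif(n, 1800, 2200))
  expect_error(nuisance_regress(array(rnorm(n), c(1, 1, 1, n)), nu),
               "rank deficient")
})

test_that("Gaussian smoothing preserves constants, the mean, and its width", {
  vs <- c(1.5, 1.5, 1.9)
  x <- array(rnorm(16 * 16 * 10, 100, 10), c(16, 16, 10))
  expect_identical(smooth_gaussian(x, 0, vs), x)
  cst <- array(7, c(8, 8, 8))
  expect_equal(smooth_gaussian(cst, 3, vs), cst, tolerance = 1e-10)
  sm <- smooth_gaussian(x, 3, vs)
  expect_equal(mean(sm), mean(x), tolerance = 1e-6 * abs(mean(x)))
  expect_lt(sd(sm), sd(x))  # it does smooth
  expect_error(smooth_gaussian(x, -1, vs), ">= 0")

  # impulse response: empirical FWHM within 5% of 3 mm on each axis
  # (width from the second moment of the profile, exact for a Gaussian and
  # free of the linear-interpolation bias at sub-voxel sigmas)
  big <- array(0, c(41, 41, 31)); big[21, 21, 16] <- 1
  r <- smooth_gaussian(big, 3, vs)
  fwhm_axis <- function(prof, step) {
    prof <- prof / sum(prof)
    d <- (seq_along(prof) - which.max(prof)) * step
    2 * sqrt(2 * log(2)) * sqrt(sum(prof * d^2))
  }
  expect_equal(fwhm_axis(r[, 21, 16], 1.5), 3, tolerance = 0.05)
  expect_equal(fwhm_axis(r[21, , 16], 1.5), 3, tolerance = 0.05)
  expect_equal(fwhm_axis(r[21, 21, ], 1.9), 3, tolerance = 0.05)
})

test_that("slice trim drops only the end slices", {
  m <- array(TRUE, c(6, 6, 4))
  tr <- trim_slices(m, axis = 2, width = 1)
  expect_false(any(tr[, c(1, 6), ]))
  expect_true(all(tr[, 2:5, ]))
  expect_error(trim_slices(array(TRUE, c(4, 2, 4)), axis = 2, width = 1),
               "every slice")
})
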