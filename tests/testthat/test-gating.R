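test_that("demodulation inverts the recovery factor", {
  timing <- acquisition_timing(1800)
  expect_equal(demodulate(50, timing, 1325), 50 / (1 - exp(-1800 / 1325)))
  expect_equal(demodulate(50, timing, 1325), 67.30, tolerance = 1e-3)
  # full recovery limit: long intervals leave the signal untouched
  expect_equal(demodulate(50, acquisition_timing(1e9), 1325), 50)
  # constant timing: one shared factor
  tconst <- acquisition_timing(rep(2000, 5))
  s <- c(3, 5, 7, 9, 11)
  a <- demodulate(s, tconst, 1325)
  expect_equal(a / s, rep(a[1] / s[1], 5))
  expect_error(demodulate(50, timing, -1), "positive")
  expect_error(demodulate(50, timing, 0), "positive")
})

test_that("CV cost is zero exactly at the true T1 for exact-model data", {
  v <- noiseless_voxel(t1 = 1325)
  expect_equal(cv_cost(v$signal, v$timing, 1325), 0, tolerance = 1e-12)
  expect_gt(cv_cost(v$signal, v$timing, 2 * 1325), 0)
  # brute-force grid confirms a unique zero at the truth
  expect_equal(cv_grid_oracle(v$signal, v$timing), 1325, tolerance = 1)
  expect_error(cv_cost(c(1, 2), v$timing, 1000), "at least 3")
})

test_that("CV cost approaches noise SD over amplitude for noisy constant voxels", {
  set.seed(31)
  v <- noiseless_voxel(t1 = 1100, amp = 100,
                       intervals = rep(c(1700, 2300), 300))
  noisy <- v$signal + rnorm(length(v$signal), 0, 2) *
    (1 - exp(-v$timing$intervals / v$t1))
  # at the true T1 the demodulated amplitude is 100 + N(0, 2)
  expect_equal(cv_cost(noisy, v$timing, 1100), 2 / 100, tolerance = 0.15)
})

test_that("T1e estimation recovers the truth on noiseless voxels to <1 ms", {
  v <- noiseless_voxel(t1 = 1325)
  arr <- array(rep(v$signal, each = 4), c(2, 2, 1, length(v$signal)))
  fit <- estimate_t1e(arr, array(TRUE, c(2, 2, 1)), timing = v$timing)
  expect_true(all(abs(fit$t1e - 1325) < 1))
  expect_true(all(fit$identifiable))
  expect_true(all(fit$cv_min < 1e-6))
  expect_true(all(fit$t1e >= fit$search_bounds[1] &
                  fit$t1e <= fit$search_bounds[2]))
})

test_that("grid optimality: no coarse-grid T1 beats the returned estimate", {
  v <- noiseless_voxel(t1 = 900, intervals = rep(c(1600, 2000, 2400), 40))
  arr <- array(v$signal, c(1, 1, 1, length(v$signal)))
  fit <- estimate_t1e(arr, array(TRUE, c(1, 1, 1)), timing = v$timing)
  grid <- exp(seq(log(100), log(5000), length.out = 64))
  costs <- vapply(grid, function(g) cv_cost(v$signal, v$timing, g), numeric(1))
  expect_true(all(fit$cv_min[1, 1, 1] <= costs + 1e-12))
})

test_that("degenerate inputs are flagged unidentifiable", {
  tconst <- acquisition_timing(rep(2000, 50))
  arr <- array(rnorm(50, 100, 1), c(1, 1, 1, 50))
  fit <- estimate_t1e(arr, array(TRUE, c(1, 1, 1)), timing = tconst)
  expect_false(any(fit$identifiable))
  expect_equal(fit$t1e[1, 1, 1], 2000)  # t_av fallback
  # non-positive samples are never demodulated
  v <- noiseless_voxel()
  s2 <- v$signal; s2[5] <- -1
  arr2 <- array(s2, c(1, 1, 1, length(s2)))
  fit2 <- estimate_t1e(arr2, array(TRUE, c(1, 1, 1)), timing = v$timing)
  expect_false(any(fit2$identifiable))
  expect_error(estimate_t1e(arr2, array(FALSE, c(1, 1, 1)), timing = v$timing),
               "empty")
})

test_that("noisy recovery: median relative T1 error below 10% at SNR 50", {
  set.seed(77)
  nv <- 200
  tim <- timing_from_beats(simulate_rr_series(1000, 60, 2 * nv, seed = 9), 2)
  nvox <- 500
  t1s <- runif(nvox, 800, 2500)
  S <- vapply(seq_len(nvox), function(i)
    (100 + rnorm(nv, 0, 2)) * (1 - exp(-tim$intervals / t1s[i])),
    numeric(nv))
  arr <- array(t(S), c(nvox, 1, 1, nv))
  fit <- estimate_t1e(arr, array(TRUE, c(nvox, 1, 1)), timing = tim)
  err <- abs(as.vector(fit$t1e) - t1s) / t1s
  expect_lt(median(err), 0.10)
})

test_that("correction chains demodulation and the T_av factor", {
  # worked chain: S = 50 at t_n = 1800 ms, T1e = 1325 ms, T_av = 2000 ms
  a <- demodulate(50, acquisition_timing(1800), 1325)
  sc <- a * (1 - exp(-2000 / 1325))
  expect_equal(sc, 52.4, tolerance = 1e-2)
  # via correct_series on a 2-volume series with mean interval 2000
  timing <- acquisition_timing(c(1800, 2200))
  fit <- list(t1e = array(1325, c(1, 1, 1)), cv_min = array(0, c(1, 1, 1)),
              identifiable = array(TRUE, c(1, 1, 1)),
              search_bounds = c(100, 5000), t_av = 2000)
  class(fit) <- "t1e_map"
  ser <- array(c(50, 60), c(1, 1, 1, 2))
  out <- correct_series(ser, fit, timing = timing)
  expect_equal(out$t_av_used, 2000)
  expect_equal(out$data[1, 1, 1, 1], sc, tolerance = 1e-6)
})

test_that("correction is the identity for constant timing and rescales linearly", {
  tconst <- acquisition_timing(rep(2000, 40))
  s <- 100 * (1 - exp(-2000 / 1500)) + rnorm(40)
  ser <- array(s, c(1, 1, 1, 40))
  fit <- list(t1e = array(1500, c(1, 1, 1)), cv_min = array(0, c(1, 1, 1)),
              identifiable = array(TRUE, c(1, 1, 1)),
              search_bounds = c(100, 5000), t_av = 2000)
  class(fit) <- "t1e_map"
  expect_equal(correct_series(ser, fit, timing = tconst)$data, ser)
  # global rescaling of S rescales Sc by the same factor
  v <- noiseless_voxel()
  arr <- array(v$signal, c(1, 1, 1, length(v$signal)))
  fitv <- estimate_t1e(arr, array(TRUE, c(1, 1, 1)), timing = v$timing)
  sc1 <- correct_series(arr, fitv, timing = v$timing)$data
  sc3 <- correct_series(3 * arr, fitv, timing = v$timing)$data
  expect_equal(sc3, 3 * sc1, tolerance = 1e-12)
  # noiseless exact-model voxel: corrected series is constant (to the
  # sub-0.1 ms accuracy of the T1e refinement)
  expect_lt(diff(range(sc1)) / mean(sc1), 1e-5)
})

test_that("correction never worsens the CV of identifiable synthetic voxels", {
  gt <- test_ground_truth(seed = 21)
  sub <- simulate_gated_dataset(gt, n_volumes = 120L, n_subjects = 1L)[[1]]
  fit <- estimate_t1e(sub$series, sub$masks$brain, timing = sub$timing)
  corr <- correct_series(sub$series, fit, timing = sub$timing)$data
  cv_of <- function(x) apply(matrix(x, ncol = dim(x)[4]), 1,
                             function(v) sd(v) / abs(mean(v)))
  cv0 <- cv_of(sub$series); cv1 <- cv_of(corr)
  id <- as.vector(fit$identifiable)
  expect_true(all(cv1[id] <= cv0[id] + 1e-10))
  # grid mismatch is rejected
  expect_error(correct_series(sub$series[1:5, , , ], fit, timing = sub$timing),
               "grid")
})
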