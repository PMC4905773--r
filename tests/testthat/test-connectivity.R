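test_that("Fisher z is odd, monotone, and matches atanh", {
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0), 0)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))  # clamped below 1
})

test_that("seed extraction averages the cleaned unsmoothed series", {
  arr <- array(rnorm(4 * 1 * 1 * 10), c(4, 1, 1, 10))
  m1 <- roi_mask(array(c(TRUE, FALSE, FALSE, FALSE), c(4, 1, 1)), "one")
  expect_equal(extract_seed(arr, m1), arr[1, 1, 1, ])
  m4 <- roi_mask(array(TRUE, c(4, 1, 1)), "four")
  expect_equal(extract_seed(arr, m4),
               colMeans(matrix(arr, nrow = 4)))
})

test_that("correlation maps clamp, flag, and transform correctly", {
  set.seed(5)
  n <- 50
  seed_series <- rnorm(n)
  dims <- c(3, 2, 1)
  ser <- array(rnorm(prod(dims) * n), c(dims, n))
  ser[1, 1, 1, ] <- seed_series             # self-correlation
  ser[2, 1, 1, ] <- 7                       # zero variance
  zm <- correlation_map(seed_series, ser, array(TRUE, dims))
  expect_equal(zm$z[1, 1, 1], atanh(1 - 1e-12))
  expect_true(zm$flag[1, 1, 1])
  expect_equal(zm$z[2, 1, 1], 0)
  expect_true(zm$flag[2, 1, 1])
  # an ordinary voxel matches cor() exactly
  expect_equal(zm$z[3, 2, 1], atanh(cor(seed_series, ser[3, 2, 1, ])))
  expect_false(zm$flag[3, 2, 1])
  expect_error(correlation_map(rep(1, n), ser, array(TRUE, dims)), "constant")
})

test_that("seed-pair correlation handles identity, nulls, and anticorrelation", {
  x <- rnorm(60)
  self <- seed_pair_correlation(x, x)
  expect_equal(self$r, 1)
  expect_true(self$flagged)
  anti <- seed_pair_correlation(x, -x)
  expect_equal(anti$r, -1)
  expect_equal(anti$z, -self$z)
  set.seed(13)
  z <- replicate(100, seed_pair_correlation(rnorm(80), rnorm(80))$z)
  se <- 1 / sqrt(80 - 3) / sqrt(100)
  expect_lt(abs(mean(z)), 2 * se * 3)  # generous null band
  expect_error(seed_pair_correlation(rep(1, 10), rnorm(10)), "constant")
})

make_zmap <- function(z, id, seed_label = "leftHb") {
  structure(list(z = z, flag = array(FALSE, dim(z)), seed_label = seed_label,
                 subject_id = id), class = "subject_zmap")
}

test_that("group t maps match the hand-computed one-sample statistic", {
  dims <- c(2, 2, 1)
  zs <- lapply(1:3, function(i) make_zmap(array(i / 10, dims), paste0("s", i)))
  g <- group_ttest(zs)
  expect_equal(g$df, 2L)
  expect_equal(g$t[1, 1, 1], 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  # degenerate all-equal maps: infinite t, flagged
  zeq <- lapply(1:3, function(i) make_zmap(array(0.5, dims), paste0("s", i)))
  geq <- group_ttest(zeq)
  expect_true(all(is.infinite(geq$t)))
  expect_true(all(geq$degenerate))
  # antisymmetric values: t = 0
  za <- lapply(c(-1, 0, 1), function(v) make_zmap(array(v, dims), "s"))
  expect_equal(group_ttest(za)$t[1, 1, 1], 0)
  expect_error(group_ttest(zs[1:2]), "at least 3")
})

test_that("paired contrast equals the one-sample test on differences", {
  set.seed(9)
  dims <- c(3, 3, 2)
  n <- 6
  zl <- lapply(1:n, function(i)
    make_zmap(array(0.2 + rnorm(prod(dims), 0, 0.02), dims), paste0("s", i)))
  zr <- lapply(1:n, function(i)
    make_zmap(array(rnorm(prod(dims), 0, 0.02), dims),
              paste0("s", i), "rightHb"))
  pc <- paired_contrast(zl, zr)
  d <- sapply(1:n, function(i) as.vector(zl[[i]]$z - zr[[i]]$z))
  tref <- apply(d, 1, function(v) mean(v) / (sd(v) / sqrt(n)))
  expect_equal(as.vector(pc$t), tref, tolerance = 1e-10)
  expect_equal(pc$df, n - 1L)
  # zero contrast and antisymmetry
  expect_true(all(paired_contrast(zl, zl)$t == 0))
  flip <- paired_contrast(zr, zl)
  expect_equal(flip$t, -pc$t)
  # one-sample map test agrees with contrast against zero maps
  z0 <- lapply(1:n, function(i) make_zmap(array(0, dims), paste0("s", i)))
  # (zero maps are degenerate under one-sample t; compare numerically)
  expect_equal(paired_contrast(zl, z0)$t, group_ttest(zl)$t)
  # subject mismatch rejected
  zr2 <- zr; zr2[[1]]$subject_id <- "other"
  expect_error(paired_contrast(zl, zr2), "mismatch")
})

test_that("outlier removal is a single pass at mean +/- k SD", {
  # {0,0,0,10}: mean 2.5, SD 5 -> bound 12.5 keeps the 10
  out <- remove_outliers(c(0, 0, 0, 10), k = 2)
  expect_equal(out$retained, c(0, 0, 0, 10))
  expect_equal(length(out$dropped), 0L)
  # a genuinely extreme point is dropped without iterating
  v <- c(rnorm(20, 0, 0.1), 5)
  out2 <- remove_outliers(v, k = 2)
  expect_equal(out2$dropped, 21L)
  expect_equal(out2$retained, v[1:20])
  # symmetric in-bound data is untouched
  expect_equal(remove_outliers(c(-1, 0, 1), k = 2)$retained, c(-1, 0, 1))
  expect_error(remove_outliers(c(1, 2), k = 2), "at least 3")
  expect_error(remove_outliers(c(1, 2, 3), k = 0), "> 0")
})

test_that("JZS Bayes factor favors the null at t = 0 and decreases in |t|", {
  expect_gt(jzs_bf01(0, 10), 1)
  expect_gt(jzs_bf01(0, 200, r_scale = 0.5), 1)
  ts <- seq(0, 5, by = 0.5)
  bf <- vapply(ts, jzs_bf01, numeric(1), n = 34)
  expect_true(all(diff(bf) < 0))
  expect_equal(jzs_bf01(2, 34), jzs_bf01(-2, 34), tolerance = 1e-9)
  expect_error(jzs_bf01(Inf, 34), "finite")
  expect_error(jzs_bf01(1, 1), ">= 2")
})

test_that("two independent quadrature schemes agree to 1e-4", {
  # oracle: truncated semi-infinite Simpson rule on the g scale
  jzs_bf01_semiinf <- function(t, n, r_scale = 1) {
    nu <- n - 1
    null_like <- (1 + t^2 / nu)^(-(nu + 1) / 2)
    g <- exp(seq(log(1e-8), log(1e8), length.out = 40001))
    f <- (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (r_scale^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-r_scale^2 / (2 * g))
    # Simpson on the log-g grid: integrand times g (du = dlog g)
    h <- diff(log(g))[1]
    w <- rep(c(2, 4), length.out = length(g)); w[1] <- 1; w[length(g)] <- 1
    alt <- sum(w * f * g) * h / 3
    null_like / alt
  }
  for (t in c(0.5, 1.75, 3)) {
    a <- jzs_bf01(t, 34)
    b <- jzs_bf01_semiinf(t, 34)
    expect_equal(a, b, tolerance = 1e-4)
  }
})
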