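# Seed-based connectivity: seed extraction from cleaned UNSMOOTHED data,
# voxelwise correlation against cleaned SMOOTHED data (the asymmetry keeps the
# tiny seed's series free of partial-volume contamination from neighbours),
# Fisher r-to-z maps, and group random-effects statistics.

R_CLAMP <- 1 - 1e-12

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` with `|r|` clamped just below 1 so self-correlations stay
#' finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) atanh(pmax(pmin(r, R_CLAMP), -R_CLAMP))

#' Extract a seed's mean time series
#'
#' Per-volume mean of the cleaned unsmoothed series over the seed voxels.
#'
#' @param series_clean_unsmoothed 4D array after nuisance regression, before
#'   smoothing.
#' @param seed_mask [roi_mask()].
#' @return Numeric seed series.
#' @export
extract_seed <- function(series_clean_unsmoothed, seed_mask) {
  roi_mean_series(series_clean_unsmoothed, seed_mask)
}

#' Voxelwise seed correlation map with Fisher z transform
#'
#' Pearson correlation of the seed series with every voxel of the cleaned
#' smoothed series, then `z = atanh(r)` with clamping at `1 - 1e-12`.
#' Zero-variance voxels get `z = 0` and are flagged (flagged voxels are later
#' excluded from group maps but keep the grids aligned across subjects).
#'
#' @param seed_series Seed mean time series (non-constant).
#' @param series_smoothed 4D cleaned smoothed series.
#' @param mask Analysis mask; voxels outside get `NA`.
#' @param seed_label,subject_id Labels carried in the result.
#' @return A `subject_zmap`: list with 3D arrays `z` and `flag`, plus labels.
#' @export
correlation_map <- function(seed_series, series_smoothed, mask,
                            seed_label = "seed", subject_id = "subject") {
  n <- length(seed_series)
  if (n < 4L) stopf("need at least 4 volumes")
  if (stats::sd(seed_series) == 0) stopf("seed series is constant")
  m <- as_mask_array(mask)
  dims <- dim(series_smoothed)
  if (dims[4L] != n) stopf("series has %d volumes but seed has %d", dims[4L], n)
  idx <- which(m)
  Y <- matrix(series_smoothed, ncol = n)[idx, , drop = FALSE]
  s <- (seed_series - mean(seed_series)) / stats::sd(seed_series)
  Yc <- Y - rowMeans(Y)
  denom <- sqrt(rowSums(Yc^2))
  r <- as.vector(Yc %*% s) / (denom * sqrt(n - 1))
  zero_var <- denom == 0
  r[zero_var] <- 0
  clamped <- abs(r) >= R_CLAMP
  z <- array(NA_real_, dims[1:3]); fl <- array(FALSE, dims[1:3])
  z[idx] <- fisher_z(r)
  fl[idx] <- zero_var | clamped
  structure(list(z = z, flag = fl, seed_label = seed_label,
                 subject_id = subject_id),
            class = "subject_zmap")
}

#' Correlation between the two seed series
#'
#' Scalar Pearson correlation and Fisher z between the left and right seed
#' mean series of one subject.
#'
#' @param left_seed_series,right_seed_series Seed mean time series.
#' @return List with `r` and `z` (z clamped, with a `flagged` indicator when
#'   `|r|` hit the clamp).
#' @export
seed_pair_correlation <- function(left_seed_series, right_seed_series) {
  if (stats::sd(left_seed_series) == 0 || stats::sd(right_seed_series) == 0)
    stopf("seed series is constant")
  r <- stats::cor(left_seed_series, right_seed_series)
  list(r = r, z = fisher_z(r), flagged = abs(r) >= R_CLAMP)
}

zmap_stack <- function(z_maps) {
  dims <- dim(z_maps[[1]]$z)
  for (zm in z_maps)
    if (!all(dim(zm$z) == dims)) stopf("z maps are not on a common grid")
  list(z = sapply(z_maps, function(zm) as.vector(zm$z)),
       flag = Reduce(`|`, lapply(z_maps, function(zm) zm$flag)),
       dims = dims)
}

one_sample_t <- function(M) {
  # M: voxels x subjects; returns list(t, flagged sd==0)
  n <- ncol(M)
  mu <- rowMeans(M)
  sdv <- sqrt(rowSums((M - mu)^2) / (n - 1))
  t <- mu / (sdv / sqrt(n))
  degen <- !is.na(sdv) & sdv == 0  # NA: voxel outside the analysis mask
  pos <- degen & mu != 0
  t[pos] <- sign(mu[pos]) * Inf
  t[degen & mu == 0] <- 0
  list(t = t, degenerate = degen)
}

#' Group one-sample t-test on subject z maps
#'
#' Voxelwise second-level random-effects test of the Fisher z values against
#' zero. Voxels flagged in any subject (clamped or zero-variance) are excluded
#' (`NA`); voxels with zero between-subject SD get an infinite t and a flag.
#'
#' @param z_maps List of `subject_zmap` objects on a common grid.
#' @return A `group_stat_map`: 3D array `t`, `df = n - 1`, `n_subjects`,
#'   `contrast`, and a `degenerate` flag array.
#' @export
group_ttest <- function(z_maps) {
  if (length(z_maps) < 3L) stopf("need at least 3 subjects")
  st <- zmap_stack(z_maps)
  res <- one_sample_t(st$z)
  t <- array(res$t, st$dims)
  degen <- array(res$degenerate, st$dims)
  t[st$flag] <- NA_real_
  structure(list(t = t, df = length(z_maps) - 1L, n_subjects = length(z_maps),
                 contrast = "single-seed", degenerate = degen),
            class = "group_stat_map")
}

#' Paired left-versus-right contrast
#'
#' Voxelwise paired t-test on the subjectwise difference of left- and
#' right-seed Fisher z maps; equivalent to a one-sample test on the
#' differences. Positive t means stronger left-seed coupling.
#'
#' @param z_left,z_right Lists of `subject_zmap` for the same subjects, in the
#'   same order.
#' @return A `group_stat_map` with `contrast = "left-minus-right"`.
#' @export
paired_contrast <- function(z_left, z_right) {
  if (length(z_left) != length(z_right)) stopf("subject sets differ in size")
  ids_l <- vapply(z_left, function(z) z$subject_id, "")
  ids_r <- vapply(z_right, function(z) z$subject_id, "")
  if (!identical(ids_l, ids_r))
    stopf("subject mismatch between the two map sets")
  sl <- zmap_stack(z_left); sr <- zmap_stack(z_right)
  if (!all(sl$dims == sr$dims)) stopf("z maps are not on a common grid")
  res <- one_sample_t(sl$z - sr$z)
  t <- array(res$t, sl$dims)
  t[sl$flag | sr$flag] <- NA_real_
  structure(list(t = t, df = length(z_left) - 1L, n_subjects = length(z_left),
                 contrast = "left-minus-right",
                 degenerate = array(res$degenerate, sl$dims)),
            class = "group_stat_map")
}

#' Two-tailed p-values for a group map
#'
#' @param stat_map A `group_stat_map`.
#' @return 3D array of two-tailed p-values.
#' @export
group_pvalues <- function(stat_map) {
  2 * stats::pt(-abs(stat_map$t), df = stat_map$df)
}

#' Single-pass outlier removal by SD distance
#'
#' Drops values lying outside `mean +/- k * SD`, both computed once on the
#' full set (no iteration), as done for region-mean z values before post-hoc
#' group tests.
#'
#' @param values Per-subject scalar values (length >= 3).
#' @param k SD multiplier (default 2).
#' @return List with `retained` values and integer `kept`/`dropped` indices.
#' @export
remove_outliers <- function(values, k = 2) {
  if (!is.numeric(k) || k <= 0) stopf("k must be > 0")
  if (length(values) < 3L) stopf("need at least 3 values")
  mu <- mean(values); s <- stats::sd(values)
  keep <- abs(values - mu) <= k * s
  if (!any(keep)) stopf("all values fall outside mean +/- %g SD", k)
  list(retained = values[keep], kept = which(keep), dropped = which(!keep))
}
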