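#' Binary region-of-interest mask
#'
#' @param voxels Logical 3D array marking member voxels.
#' @param label Region name.
#' @return An object of class `roi_mask` with elements `voxels`, `label`,
#'   `n_voxels`.
#' @export
roi_mask <- function(voxels, label = "roi") {
  if (!is.logical(voxels) || length(dim(voxels)) != 3L)
    stopf("voxels must be a logical 3D array")
  structure(list(voxels = voxels, label = label, n_voxels = sum(voxels)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels on %s grid\n", x$label, x$n_voxels,
              paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$voxels
  else if (is.logical(mask) && length(dim(mask)) == 3L) mask
  else stopf("expected an roi_mask or a logical 3D array")
}

#' Mean time series over a region
#'
#' Per-volume arithmetic mean of the (unsmoothed) series over mask voxels;
#' used for the white-matter and CSF nuisance compartments and for seed
#' extraction.
#'
#' @param series 4D array (x, y, z, time).
#' @param mask [roi_mask()] or logical 3D array on the same grid.
#' @return Numeric vector of length `dim(series)[4]`.
#' @export
roi_mean_series <- function(series, mask) {
  m <- as_mask_array(mask)
  if (length(dim(series)) != 4L) stopf("series must be a 4D array")
  if (!all(dim(series)[1:3] == dim(m))) stopf("mask grid does not match series")
  idx <- which(m)
  if (length(idx) == 0L) stopf("mask is empty")
  colMeans(matrix(series, ncol = dim(series)[4L])[idx, , drop = FALSE])
}

#' Erode a mask by one voxel layer
#'
#' Removes every member voxel that has at least one non-member face neighbor
#' (6-connectivity); voxels outside the array count as background, so a mask
#' touching the grid boundary is eroded there too. The result may be empty.
#'
#' @param mask [roi_mask()] or logical 3D array.
#' @return Object of the same type as the input.
#' @export
erode_mask <- function(mask) {
  m <- as_mask_array(mask)
  d <- dim(m)
  keep <- m
  shift_ok <- function(axis, dir) {
    # TRUE where the face neighbor in direction dir along axis is inside the mask
    out <- array(FALSE, d)
    n <- d[axis]
    if (n == 1L) return(out)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    ixs <- ix; ixs[[axis]] <- src
    ixd <- ix; ixd[[axis]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- m[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  for (axis in 1:3) for (dir in c(-1, 1)) keep <- keep & shift_ok(axis, dir)
  if (inherits(mask, "roi_mask")) roi_mask(keep, mask$label) else keep
}

#' Rasterize a high-resolution mask by occupancy
#'
#' Downsamples a mask drawn on a finer, nested grid to the analysis grid: a
#' target voxel is kept iff the fraction of its constituent fine voxels inside
#' the mask is at least `clip` (the boundary case of exactly `clip` is kept).
#' This mirrors occupancy-clip binarization of hand-drawn regions into
#' functional space.
#'
#' @param highres_mask Logical 3D array on the fine grid.
#' @param target_dim Integer triple; each fine dimension must be an integer
#'   multiple of the corresponding target dimension.
#' @param clip Minimum occupied fraction in (0, 1]; default 0.3.
#' @param label Label for the result.
#' @return [roi_mask()] on the target grid.
#' @export
rasterize_roi <- function(highres_mask, target_dim, clip = 0.3, label = "roi") {
  if (!(clip > 0 && clip <= 1)) stopf("clip must be in (0, 1]")
  hd <- dim(highres_mask)
  target_dim <- as.integer(target_dim)
  if (length(hd) != 3L || length(target_dim) != 3L)
    stopf("highres_mask must be 3D and target_dim a triple")
  f <- hd / target_dim
  if (any(f != round(f)) || any(f < 1))
    stopf("grids not nested: %s is not an integer refinement of %s",
          paste(hd, collapse = "x"), paste(target_dim, collapse = "x"))
  f <- as.integer(f)
  blocks <- array(as.numeric(highres_mask),
                  c(f[1], target_dim[1], f[2], target_dim[2], f[3], target_dim[3]))
  occ <- apply(blocks, c(2L, 4L, 6L), mean)
  roi_mask(occ >= clip, label)
}

#' Nuisance regressor set
#'
#' @param wm_mean,csf_mean Compartment mean time series (from the unsmoothed
#'   series over the eroded white-matter and CSF masks).
#' @param motion n x 6 matrix of rigid-body motion parameters.
#' @param tr_duration Per-volume inter-acquisition interval, ms.
#' @return A `nuisance_set` list.
#' @export
nuisance_set <- function(wm_mean, csf_mean, motion, tr_duration) {
  motion <- as.matrix(motion)
  n <- length(wm_mean)
  if (length(csf_mean) != n || nrow(motion) != n || length(tr_duration) != n)
    stopf("all nuisance sequences must share the series length (%d)", n)
  if (ncol(motion) != 6L) stopf("motion must have 6 columns")
  structure(list(wm_mean = as.numeric(wm_mean), csf_mean = as.numeric(csf_mean),
                 motion = motion, tr_duration = as.numeric(tr_duration)),
            class = "nuisance_set")
}

nuisance_design <- function(nuisance) {
  X <- cbind(intercept = 1, wm = nuisance$wm_mean, csf = nuisance$csf_mean,
             nuisance$motion, tr_duration = nuisance$tr_duration)
  mn <- colnames(nuisance$motion)
  if (is.null(mn)) mn <- as.character(1:6)
  colnames(X)[4:9] <- paste0("motion_", mn)
  X
}

#' Regress nuisance signals out of a series
#'
#' Voxelwise ordinary least squares of the series on the 10-column design
#' (intercept, white-matter mean, CSF mean, six motion parameters, and the
#' per-volume acquisition duration); returns the residuals. Residuals are
#' orthogonal to every design column to numerical precision.
#'
#' @param series 4D array (x, y, z, time) or time-by-voxel matrix.
#' @param nuisance [nuisance_set()].
#' @return Residual series with the same shape as the input.
#' @export
nuisance_regress <- function(series, nuisance) {
  X <- nuisance_design(nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("nuisance design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  is4d <- length(dim(series)) == 4L
  Y <- if (is4d) t(matrix(series, ncol = dim(series)[4L])) else as.matrix(series)
  if (nrow(Y) != nrow(X))
    stopf("series has %d volumes but nuisance set has %d", nrow(Y), nrow(X))
  res <- qr.resid(qrX, Y)
  if (is4d) array(t(res), dim(series)) else res
}

# --- Gaussian smoothing ------------------------------------------------------
#
# Separable smoothing along each axis with a truncated (4 sigma) discrete
# Gaussian. The per-axis kernel matrix is balanced to doubly stochastic
# (Sinkhorn), so constant fields AND the volume mean are preserved exactly at
# the boundary; interior rows are the ordinary normalized truncated Gaussian.

gauss_axis_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok]
  }
  for (it in 1:200) {
    K <- K / rowSums(K)
    K <- t(t(K) / colSums(K))
    if (max(abs(rowSums(K) - 1)) < 1e-13) break
  }
  K / rowSums(K)
}

smoothing_matrices <- function(dims, fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  lapply(1:3, function(a) gauss_axis_matrix(dims[a], sigma[a]))
}

# Per-voxel SD of smoothed unit-variance white noise (analytic, from the
# separable kernel rows).
smoothed_sd_map <- function(mats) {
  s <- lapply(mats, function(M) sqrt(rowSums(M^2)))
  outer(outer(s[[1]], s[[2]]), s[[3]])
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  p <- aperm(arr, perm)
  m <- M %*% matrix(p, nrow = d[axis])
  aperm(array(m, d[perm]), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing with `sigma_axis = fwhm / (2 sqrt(2 ln 2) *
#' voxel_size_axis)`, applied volume by volume for 4D input. Kernels are
#' truncated at four sigma and balanced so that both constant fields and the
#' global volume mean are preserved at grid edges. `fwhm = 0` is the identity.
#'
#' @param x 3D volume or 4D series.
#' @param fwhm Full width at half maximum, mm.
#' @param voxel_size Voxel edge lengths, mm (length-3).
#' @param preserve_sd If TRUE, rescale by the analytic per-voxel SD of the
#'   smoothed field so unit-variance white-noise input keeps unit voxelwise
#'   variance (used when generating spatially smooth noise).
#' @return Array of the same shape as `x`.
#' @export
smooth_gaussian <- function(x, fwhm, voxel_size, preserve_sd = FALSE) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm < 0)
    stopf("fwhm must be a single number >= 0")
  d <- dim(x)
  if (!(length(d) %in% c(3L, 4L))) stopf("x must be a 3D or 4D array")
  if (fwhm == 0) return(x)
  mats <- smoothing_matrices(d[1:3], fwhm, voxel_size)
  for (a in 1:3) x <- apply_axis(x, mats[[a]], a)
  if (preserve_sd) {
    sdm <- smoothed_sd_map(mats)
    x <- x / as.vector(sdm)  # recycles over volumes for 4D input
  }
  x
}

#' Drop end slices from an analysis mask
#'
#' End slices of a slab acquisition can shift into unexcited tissue between
#' gated volumes; this removes the first and last `width` slices along the
#' slice axis from a mask.
#'
#' @param mask [roi_mask()] or logical 3D array.
#' @param axis Slice-stacking axis (default 2, the slab's through-slice axis).
#' @param width Number of slices to drop at each end.
#' @return Object of the same type as the input.
#' @export
trim_slices <- function(mask, axis = 2L, width = 1L) {
  m <- as_mask_array(mask)
  d <- dim(m)
  if (width > 0) {
    if (2 * width >= d[axis]) stopf("trim width %d removes every slice", width)
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    drop_ix <- ix; drop_ix[[axis]] <- c(1:width, (d[axis] - width + 1):d[axis])
    m[drop_ix[[1]], drop_ix[[2]], drop_ix[[3]]] <- FALSE
  }
  if (inherits(mask, "roi_mask")) roi_mask(m, mask$label) else m
}
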