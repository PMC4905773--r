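# Cluster-extent familywise-error inference: supra-threshold cluster labeling
# on group maps and Monte-Carlo estimation of the minimum cluster size whose
# familywise false-positive probability under smooth Gaussian noise is <= alpha
# (the simulation behind extent thresholds like "23 voxels at p < 0.005").

# Connected components (face adjacency) among the given linear indices of a
# grid with dimensions `dims`. Returns a list of integer index vectors.
connected_components <- function(lin_idx, dims) {
  if (length(lin_idx) == 0L) return(list())
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  pos <- sort(lin_idx)  # sorted so findInterval gives O(log n) membership
  visited <- logical(length(pos))
  comps <- list()
  for (start in seq_along(pos)) {
    if (visited[start]) next
    stack <- pos[start]
    visited[start] <- TRUE
    comp <- integer(0)
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, q)
      q0 <- q - 1L
      k <- q0 %/% (nx * ny); rem <- q0 %% (nx * ny)
      j <- rem %/% nx; i <- rem %% nx
      nb <- c(if (i > 0L) q - 1L, if (i < nx - 1L) q + 1L,
              if (j > 0L) q - nx, if (j < ny - 1L) q + nx,
              if (k > 0L) q - nx * ny, if (k < nz - 1L) q + nx * ny)
      for (b in nb) {
        jb <- findInterval(b, pos)
        if (jb >= 1L && pos[jb] == b && !visited[jb]) {
          visited[jb] <- TRUE
          stack <- c(stack, b)
        }
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

max_component_size <- function(lin_idx, dims) {
  cc <- connected_components(lin_idx, dims)
  if (length(cc) == 0L) 0L else max(lengths(cc))
}

#' Label supra-threshold clusters in a group t map
#'
#' Thresholds `|t|` at the two-tailed critical value for `voxel_p`, clusters
#' the surviving voxels by face adjacency (6-connectivity) with positive and
#' negative voxels clustered separately, and drops clusters smaller than
#' `min_extent`. Peaks are the maximum-`|t|` voxel of each cluster, ties going
#' to the smallest linear index.
#'
#' @param stat_map `group_stat_map` from [group_ttest()]/[paired_contrast()],
#'   or a bare 3D t array (then `df` is required).
#' @param mask Analysis mask.
#' @param voxel_p Two-tailed voxelwise p threshold (default 0.005).
#' @param df Degrees of freedom (taken from `stat_map` if present).
#' @param min_extent Minimum cluster size in voxels (default 1).
#' @return A `cluster_table`: data frame with columns `label`, `sign`,
#'   `n_voxels`, `peak_stat`, `peak_i`, `peak_j`, `peak_k` (0-based indices),
#'   plus attributes `voxel_p` and `min_extent`.
#' @export
label_clusters <- function(stat_map, mask, voxel_p = 0.005, df = NULL,
                           min_extent = 1L) {
  if (inherits(stat_map, "group_stat_map")) {
    if (is.null(df)) df <- stat_map$df
    tmap <- stat_map$t
  } else tmap <- stat_map
  if (is.null(df) || df <= 0) stopf("df must be a positive integer")
  if (!(voxel_p > 0 && voxel_p < 1)) stopf("voxel_p must be in (0, 1)")
  m <- as_mask_array(mask)
  dims <- dim(tmap)
  tcrit <- stats::qt(1 - voxel_p / 2, df)
  rows <- list()
  for (sgn in c(1, -1)) {
    supra <- which(m & !is.na(tmap) & (sgn * tmap > tcrit))
    for (comp in connected_components(supra, dims)) {
      if (length(comp) < min_extent) next
      comp <- sort(comp)
      vals <- tmap[comp]
      peak_lin <- comp[which.max(abs(vals))]  # ties -> smallest linear index
      pk <- lin_to_ijk(peak_lin, dims)
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        n_voxels = length(comp),
        peak_stat = tmap[peak_lin],
        peak_i = pk[1, "i"] - 1L, peak_j = pk[1, "j"] - 1L,
        peak_k = pk[1, "k"] - 1L)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(), n_voxels = integer(),
               peak_stat = numeric(), peak_i = integer(),
               peak_j = integer(), peak_k = integer())
  tab <- tab[order(-tab$n_voxels, -abs(tab$peak_stat)), , drop = FALSE]
  tab <- cbind(label = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(tab, voxel_p = voxel_p, min_extent = min_extent,
            class = c("cluster_table", "data.frame"))
}

#' Compact (or elongated) blob mask of a given voxel count
#'
#' Builds a mask of exactly `n_vox` voxels by taking the voxels closest (in
#' millimetres) to the centre of a bounding grid - a sphere-like blob on an
#' anisotropic grid. `elongation` stretches the distance metric along x to
#' probe how extent thresholds depend on mask shape.
#'
#' @param n_vox Number of voxels in the mask.
#' @param voxel_size Voxel edge lengths, mm.
#' @param elongation Aspect factor along the first axis (1 = compact;
#'   3 gives a prolate, roughly 3:1 blob).
#' @return [roi_mask()] on a tight bounding grid.
#' @export
make_blob_mask <- function(n_vox, voxel_size = c(1.5, 1.5, 1.9),
                           elongation = 1) {
  if (!is_count(n_vox)) stopf("n_vox must be a positive integer")
  r <- ceiling((n_vox * max(1, elongation))^(1 / 3)) + 2L
  g <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  d <- sqrt((g[, 1] * voxel_size[1] / elongation)^2 +
            (g[, 2] * voxel_size[2])^2 +
            (g[, 3] * voxel_size[3])^2)
  if (n_vox > nrow(g)) stopf("internal bounding box too small")
  ord <- order(d, g[, 1], g[, 2], g[, 3])
  sel <- g[ord[seq_len(n_vox)], , drop = FALSE]
  sel <- sweep(sel, 2L, apply(sel, 2L, min)) + 1L
  dims <- apply(sel, 2L, max)
  m <- array(FALSE, dims)
  m[sel] <- TRUE
  roi_mask(m, sprintf("blob%d", n_vox))
}

#' Monte-Carlo cluster-extent FWE threshold
#'
#' Estimates the minimum cluster size controlling the familywise error at
#' `alpha` for a given mask, voxelwise threshold, and smoothness: per
#' iteration, Gaussian white noise is generated on the mask's bounding grid
#' padded by three FWHM, smoothed to the stated FWHM, standardized within the
#' mask using the exact analytic SD of the smoothed field, thresholded at the
#' `voxel_p` critical value, and the maximum face-connected cluster extent is
#' recorded (positive and negative excursions clustered separately under the
#' default bi-sided rule). The returned extent is the smallest `k` with
#' `P(max extent >= k) <= alpha`.
#'
#' @param mask [roi_mask()] or logical 3D array.
#' @param voxel_size Voxel edge lengths, mm.
#' @param fwhm Smoothness of the simulated noise, mm FWHM; below the smallest
#'   voxel edge a warning is issued and the noise is left unsmoothed.
#' @param voxel_p Voxelwise p threshold (two-tailed under `sided = "bi"`,
#'   one-tailed under `sided = "one"`).
#' @param alpha Familywise error level.
#' @param n_iter Monte-Carlo iterations (>= 1000).
#' @param seed RNG seed.
#' @param sided `"bi"` (threshold `|z|` at the two-tailed critical value,
#'   cluster signs separately) or `"one"` (positive excursions only at the
#'   one-tailed critical value).
#' @return An `mc_threshold`: list with `min_extent`, `alpha`, `n_iter`,
#'   `exceedance` (P(max extent >= k) for k = 1..), `max_extent` (per-iteration
#'   maxima), `seed`, and the threshold parameters.
#' @export
mc_cluster_threshold <- function(mask, voxel_size = c(1.5, 1.5, 1.9), fwhm = 3,
                                 voxel_p = 0.005, alpha = 0.05,
                                 n_iter = 10000L, seed = 1L,
                                 sided = c("bi", "one")) {
  sided <- match.arg(sided)
  m <- as_mask_array(mask)
  if (!any(m)) stopf("mask is empty")
  if (!is_count(n_iter) || n_iter < 1000) stopf("n_iter must be >= 1000")
  if (!(voxel_p > 0 && voxel_p < 1)) stopf("voxel_p must be in (0, 1)")

  smooth <- fwhm > 0
  if (smooth && fwhm < min(voxel_size)) {
    warning("FWHM below voxel size; proceeding with unsmoothed noise",
            call. = FALSE)
    smooth <- FALSE
  }

  # crop to the mask's bounding box, then pad by 3 FWHM so every mask voxel
  # sees a full smoothing neighbourhood
  bb <- apply(which(m, arr.ind = TRUE), 2L, range)
  pad <- if (smooth) ceiling(3 * fwhm / voxel_size) else c(0L, 0L, 0L)
  dims <- (bb[2L, ] - bb[1L, ] + 1L) + 2L * pad
  big <- array(FALSE, dims)
  sel <- which(m, arr.ind = TRUE)
  big[cbind(sel[, 1] - bb[1, 1] + pad[1] + 1L,
            sel[, 2] - bb[1, 2] + pad[2] + 1L,
            sel[, 3] - bb[1, 3] + pad[3] + 1L)] <- TRUE
  midx <- which(big)

  if (smooth) {
    mats <- smoothing_matrices(dims, fwhm, voxel_size)
    sd_in_mask <- smoothed_sd_map(mats)[midx]
  }
  zc <- if (sided == "bi") stats::qnorm(1 - voxel_p / 2) else
    stats::qnorm(1 - voxel_p)

  max_ext <- integer(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      x <- array(stats::rnorm(prod(dims)), dims)
      if (smooth) {
        for (a in 1:3) x <- apply_axis(x, mats[[a]], a)
        z <- x[midx] / sd_in_mask
      } else z <- x[midx]
      if (sided == "bi") {
        max_ext[it] <- max(max_component_size(midx[z > zc], dims),
                           max_component_size(midx[z < -zc], dims))
      } else {
        max_ext[it] <- max_component_size(midx[z > zc], dims)
      }
    }
  })

  kmax <- max(1L, max(max_ext))
  exceed <- vapply(seq_len(kmax + 1L),
                   function(k) mean(max_ext >= k), numeric(1))
  min_extent <- which(exceed <= alpha)[1L]
  structure(list(min_extent = as.integer(min_extent), alpha = alpha,
                 n_iter = as.integer(n_iter), exceedance = exceed,
                 max_extent = max_ext, seed = seed, fwhm = fwhm,
                 voxel_p = voxel_p, sided = sided,
                 n_mask_voxels = length(midx)),
            class = "mc_threshold")
}

#' @export
print.mc_threshold <- function(x, ...) {
  cat(sprintf(
    "mc_threshold: min extent %d voxels (alpha %.3g, voxel p %.3g %s-sided, %d-voxel mask, %d iters)\n",
    x$min_extent, x$alpha, x$voxel_p, x$sided, x$n_mask_voxels, x$n_iter))
  invisible(x)
}
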