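#' Acquisition timing for a cardiac-gated series
#'
#' Holds the per-volume inter-acquisition intervals `t_n` (ms) of a
#' heartbeat-gated acquisition, where `t_n` is the time elapsed between the
#' start of volume `n - 1` and volume `n` (`t_1` is the interval preceding the
#' first retained volume), together with their arithmetic mean `t_av`.
#'
#' @param intervals Numeric vector of positive inter-acquisition intervals, ms.
#' @return An object of class `acquisition_timing`: a list with elements
#'   `intervals` and `t_av`.
#' @export
acquisition_timing <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L || anyNA(intervals) || any(intervals <= 0))
    stopf("all inter-acquisition intervals must be positive and non-missing")
  structure(list(intervals = intervals, t_av = mean(intervals)),
            class = "acquisition_timing")
}

#' @export
print.acquisition_timing <- function(x, ...) {
  cat(sprintf("acquisition_timing: %d volumes, t_av = %.1f ms (range %.1f-%.1f)\n",
              length(x$intervals), x$t_av, min(x$intervals), max(x$intervals)))
  invisible(x)
}

#' Simulate a heartbeat (R-R) interval series
#'
#' R-R intervals are drawn i.i.d. from a normal distribution truncated below at
#' `0.5 * rr_mean` so that simulated beats stay physiological even at large
#' heart-rate variability.
#'
#' @param rr_mean Mean R-R interval, ms (e.g. 1000 for 60 bpm).
#' @param rr_sd SD of the R-R interval, ms; 0 gives a perfectly regular pulse.
#' @param n_beats Number of beats to draw.
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @return Numeric vector of `n_beats` positive intervals, ms.
#' @export
simulate_rr_series <- function(rr_mean, rr_sd, n_beats, seed = NULL) {
  if (!is.numeric(rr_mean) || length(rr_mean) != 1L || rr_mean <= 0)
    stopf("rr_mean must be a single positive number (ms)")
  if (!is.numeric(rr_sd) || rr_sd < 0) stopf("rr_sd must be >= 0")
  if (!is_count(n_beats)) stopf("n_beats must be a positive integer")
  with_seed(seed, {
    lower <- 0.5 * rr_mean
    x <- rnorm(n_beats, rr_mean, rr_sd)
    while (any(bad <- x < lower))  # rejection sampling below the truncation
      x[bad] <- rnorm(sum(bad), rr_mean, rr_sd)
    x
  })
}

#' Volume acquisition timing from a beat series
#'
#' The scanner triggers one volume every `beats_per_volume` heartbeats (two in
#' the study design this emulates), so each inter-acquisition interval is the
#' sum of a consecutive block of beat intervals.
#'
#' @param beats Numeric vector of beat (R-R) intervals, ms.
#' @param beats_per_volume Beats per acquired volume (default 2).
#' @return An [acquisition_timing()] object with
#'   `floor(length(beats) / beats_per_volume)` volumes.
#' @export
timing_from_beats <- function(beats, beats_per_volume = 2L) {
  if (!is_count(beats_per_volume)) stopf("beats_per_volume must be >= 1")
  n_vol <- length(beats) %/% beats_per_volume
  if (n_vol < 1L)
    stopf("need at least %d beats for one volume, got %d",
          beats_per_volume, length(beats))
  used <- beats[seq_len(n_vol * beats_per_volume)]
  t_n <- colSums(matrix(used, nrow = beats_per_volume))
  acquisition_timing(t_n)
}

#' Exact Ernst angle
#'
#' The flip angle maximizing steady-state signal for a spoiled acquisition:
#' `cos(alpha_E) = exp(-TR / T1)`.
#'
#' @param tr Repetition (volume acquisition) time, ms.
#' @param t1 Longitudinal relaxation time, ms (1325 ms for grey matter at 3 T).
#' @return Ernst angle in degrees.
#' @export
ernst_angle <- function(tr, t1 = 1325) {
  if (any(tr < 0) || any(t1 <= 0)) stopf("tr must be >= 0 and t1 > 0")
  acos(exp(-tr / t1)) * 180 / pi
}

# Flip-angle lookup by slice count, reproduced verbatim from the acquisition
# protocol: coarse bins around the Ernst angle rather than its exact value.
flip_angle_for_slices <- function(n_slices) {
  if (n_slices >= 8 && n_slices <= 9) 60
  else if (n_slices >= 10 && n_slices <= 13) 70
  else if (n_slices >= 14 && n_slices <= 15) 75
  else if (n_slices >= 16 && n_slices <= 20) 80
  else stopf("no flip-angle table entry for %d slices (table covers 8-20)",
             n_slices)
}

#' Derive a cardiac-gated acquisition protocol from the heart rate
#'
#' Emulates the protocol calculator used at the scanner: the subject's mean
#' R-R interval fixes the number of slices that fit inside two cardiac cycles
#' (minus a 90 ms trigger margin), the volume acquisition time follows from the
#' per-slice time, the acquisition window adds a 50 ms wait, and the flip angle
#' comes from a slice-count lookup table built around the Ernst angle for grey
#' matter.
#'
#' @param rr_mean Mean R-R interval, ms.
#' @param slice_time Acquisition time per slice, ms. The default reproduces the
#'   published worked example (60 bpm, 18 slices, 1910 ms volume time).
#' @param t1_gm Grey-matter T1, ms, used only to record the protocol's T1.
#' @return A `protocol_params` list: `n_slices`, `volume_acq_time`,
#'   `acq_window`, `flip_angle`, `t1_gm` (all times in ms, angle in degrees).
#' @export
derive_protocol <- function(rr_mean, slice_time = 1910 / 18, t1_gm = 1325) {
  if (!is.numeric(slice_time) || slice_time <= 0) stopf("slice_time must be > 0")
  if (!is.numeric(rr_mean) || rr_mean <= 0) stopf("rr_mean must be > 0")
  budget <- 2 * rr_mean - 90
  n_slices <- floor(budget / slice_time + 1e-9)
  if (n_slices < 1) stopf("rr_mean = %.0f ms leaves no room for a slice", rr_mean)
  vat <- n_slices * slice_time
  structure(list(n_slices = as.integer(n_slices),
                 volume_acq_time = vat,
                 acq_window = vat + 50,
                 flip_angle = flip_angle_for_slices(n_slices),
                 t1_gm = t1_gm),
            class = "protocol_params")
}

#' @export
print.protocol_params <- function(x, ...) {
  cat(sprintf(
    "protocol: %d slices, volume time %.0f ms, window %.0f ms, FA %g deg\n",
    x$n_slices, x$volume_acq_time, x$acq_window, x$flip_angle))
  invisible(x)
}

# Fractional box -> integer index ranges on a concrete grid.
frac_box <- function(dims, i, j, k) {
  rng <- function(f, n) max(1L, round(f[1] * n)):min(n, round(f[2] * n))
  list(i = rng(i, dims[1]), j = rng(j, dims[2]), k = rng(k, dims[3]))
}

box_mask <- function(dims, box) {
  m <- array(FALSE, dims)
  m[box$i, box$j, box$k] <- TRUE
  m
}

#' Default region layout for the synthetic slab
#'
#' Axis-aligned blobs on the acquisition slab: bilateral habenula seeds,
#' midbrain targets (SN, VTA, PAG), parahippocampus (PH), and white-matter /
#' CSF nuisance compartments. Boxes are placed by grid fraction so the layout
#' scales to any grid of at least roughly 12 x 12 x 8 voxels; disjointness is
#' verified at construction.
#'
#' @param grid_dim Integer triple of grid dimensions.
#' @return Named list of [roi_mask()] objects.
#' @export
default_roi_layout <- function(grid_dim = c(24L, 24L, 12L)) {
  boxes <- list(
    leftHb  = list(i = c(0.30, 0.38), j = c(0.48, 0.56), k = c(0.60, 0.72)),
    rightHb = list(i = c(0.62, 0.70), j = c(0.48, 0.56), k = c(0.60, 0.72)),
    VTA     = list(i = c(0.44, 0.56), j = c(0.46, 0.58), k = c(0.30, 0.45)),
    SN      = list(i = c(0.30, 0.70), j = c(0.25, 0.38), k = c(0.30, 0.45)),
    PAG     = list(i = c(0.44, 0.56), j = c(0.66, 0.76), k = c(0.42, 0.55)),
    PH      = list(i = c(0.76, 0.92), j = c(0.60, 0.74), k = c(0.40, 0.55)),
    WM      = list(i = c(0.08, 0.22), j = c(0.15, 0.85), k = c(0.25, 0.80)),
    CSF     = list(i = c(0.80, 0.95), j = c(0.12, 0.38), k = c(0.25, 0.80))
  )
  layout <- lapply(names(boxes), function(nm) {
    b <- boxes[[nm]]
    roi_mask(box_mask(grid_dim, frac_box(grid_dim, b$i, b$j, b$k)), label = nm)
  })
  names(layout) <- names(boxes)
  occupancy <- Reduce(`+`, lapply(layout, function(m) m$voxels))
  if (any(occupancy > 1L)) stopf("ROI layout boxes overlap on grid %s",
                                 paste(grid_dim, collapse = "x"))
  layout
}

#' Default seed-to-target coupling matrix
#'
#' Target correlations between each habenula seed latent and each target-ROI
#' latent, emulating the laterality structure under study: opposite-sign
#' left/right coupling to the VTA, right-lateralized SN coupling, left
#' PAG coupling, and opposite-sign parahippocampal coupling.
#'
#' @return 2 x 4 numeric matrix, rows `leftHb`/`rightHb`, columns
#'   `VTA`, `SN`, `PAG`, `PH`; entries in (-1, 1).
#' @export
default_coupling <- function() {
  m <- rbind(leftHb  = c(VTA = 0.4,  SN = 0,    PAG = 0.3, PH = -0.3),
             rightHb = c(VTA = -0.4, SN = 0.35, PAG = 0,   PH = 0.3))
  m
}

#' Ground truth for a synthetic cardiac-gated dataset
#'
#' Collects everything the generator needs and everything a downstream
#' validation needs to know: the per-voxel T1 map, equilibrium signal map,
#' region layout, planted seed-target coupling, noise level, and the pulse
#' statistics driving the gated timing.
#'
#' @param grid_dim Grid dimensions (voxels).
#' @param voxel_size Voxel edge lengths, mm.
#' @param roi_layout Named list of [roi_mask()]; defaults to
#'   [default_roi_layout()].
#' @param coupling Seed x target coupling matrix in (-1, 1); rows must be
#'   `leftHb`, `rightHb`. Defaults to [default_coupling()].
#' @param bold_frac Fractional amplitude of the latent signal in coupled
#'   voxels (0.01 = 1 percent of equilibrium signal, a typical resting BOLD
#'   fluctuation size).
#' @param noise_sd Thermal noise SD in signal units (equilibrium grey matter
#'   signal is 100, so 1 corresponds to voxelwise SNR 100).
#' @param noise_fwhm Spatial smoothness of the noise field, mm FWHM.
#' @param rr_mean,rr_sd Pulse mean and SD, ms.
#' @param t1_jitter Multiplicative per-voxel T1/M0 jitter half-width (0.05
#'   draws factors from U(0.95, 1.05)).
#' @param seed RNG seed recorded with the truth and used by the generator.
#' @return A `ground_truth` list; `t1_map` and `m0_map` are 3D arrays (ms and
#'   signal units).
#' @export
ground_truth <- function(grid_dim = c(24L, 24L, 12L),
                         voxel_size = c(1.5, 1.5, 1.9),
                         roi_layout = default_roi_layout(grid_dim),
                         coupling = default_coupling(),
                         bold_frac = 0.01,
                         noise_sd = 1,
                         noise_fwhm = 2,
                         rr_mean = 1000, rr_sd = 50,
                         t1_jitter = 0.05,
                         seed = 1L) {
  grid_dim <- as.integer(grid_dim)
  if (rr_sd < 0) stopf("rr_sd must be >= 0")
  if (any(abs(coupling) >= 1)) stopf("all couplings must satisfy |c| < 1")
  ss <- colSums(coupling^2)
  if (any(ss >= 1))
    stopf("coupling not realizable: column sums of squares must be < 1 (got %.3f)",
          max(ss))
  if (!all(rownames(coupling) == c("leftHb", "rightHb")))
    stopf("coupling rows must be leftHb, rightHb")

  with_seed(seed, {
    n_vox <- prod(grid_dim)
    jit <- function() array(runif(n_vox, 1 - t1_jitter, 1 + t1_jitter), grid_dim)
    t1 <- array(1325, grid_dim); m0 <- array(100, grid_dim)
    if (!is.null(roi_layout$WM)) {
      t1[roi_layout$WM$voxels] <- 830; m0[roi_layout$WM$voxels] <- 90
    }
    if (!is.null(roi_layout$CSF)) {
      t1[roi_layout$CSF$voxels] <- 3800; m0[roi_layout$CSF$voxels] <- 110
    }
    t1 <- t1 * jit(); m0 <- m0 * jit()
    structure(list(grid_dim = grid_dim, voxel_size = voxel_size,
                   t1_map = t1, m0_map = m0,
                   roi_layout = roi_layout, coupling = coupling,
                   bold_frac = bold_frac, noise_sd = noise_sd,
                   noise_fwhm = noise_fwhm,
                   rr_mean = rr_mean, rr_sd = rr_sd, seed = seed),
              class = "ground_truth")
  })
}

# Standardized random walk: slow drift with unit SD.
drift_series <- function(n) {
  x <- cumsum(rnorm(n))
  (x - mean(x)) / stats::sd(x)
}

#' Simulate a multi-subject cardiac-gated BOLD dataset
#'
#' For each subject: draws a truncated-normal R-R series and gates one volume
#' per `beats_per_volume` beats; builds independent left/right seed latents and
#' target-ROI latents realizing the planted coupling matrix; mixes in
#' white-matter/CSF drift and six motion nuisance series; adds spatially smooth
#' Gaussian noise; and applies the T1 recovery factor so the measured signal is
#' `S = A * (1 - exp(-t_n / T1))` with `A` the latent (T1-free) amplitude.
#'
#' @param gt A [ground_truth()] object.
#' @param protocol A [derive_protocol()] result (recorded with each subject;
#'   the steady-state flip-angle scaling is absorbed into the equilibrium map).
#' @param n_volumes Volumes per subject (>= 30).
#' @param n_subjects Number of subjects.
#' @param beats_per_volume Cardiac gating factor (default 2).
#' @return List of per-subject records, each with `series` (4D array),
#'   `amplitude` (latent 4D array before T1 modulation), `timing`
#'   ([acquisition_timing()]), `motion` (n_volumes x 6 matrix), `masks`
#'   (the ROI layout plus `brain`), `latents` (seed and target latent series),
#'   and `subject_id`.
#' @export
simulate_gated_dataset <- function(gt, protocol = derive_protocol(gt$rr_mean),
                                   n_volumes = 200L, n_subjects = 20L,
                                   beats_per_volume = 2L) {
  if (!inherits(gt, "ground_truth")) stopf("gt must be a ground_truth object")
  if (!is_count(n_volumes) || n_volumes < 30)
    stopf("n_volumes must be an integer >= 30")
  if (!is_count(n_subjects)) stopf("n_subjects must be >= 1")
  dims <- gt$grid_dim
  rois <- colnames(gt$coupling)
  missing_rois <- setdiff(c("leftHb", "rightHb", rois), names(gt$roi_layout))
  if (length(missing_rois))
    stopf("roi_layout lacks regions named in the coupling: %s",
          paste(missing_rois, collapse = ", "))

  lapply(seq_len(n_subjects), function(s) {
    with_seed(child_seed(gt$seed, s), {
      beats <- simulate_rr_series(gt$rr_mean, gt$rr_sd,
                                  n_volumes * beats_per_volume)
      timing <- timing_from_beats(beats, beats_per_volume)
      n <- length(timing$intervals)

      # latent seed signals (independent) and coupled target latents
      sL <- rnorm(n); sR <- rnorm(n)
      sL <- (sL - mean(sL)) / stats::sd(sL)
      sR <- (sR - mean(sR)) / stats::sd(sR)
      latents <- list(leftHb = sL, rightHb = sR)
      for (r in rois) {
        cL <- gt$coupling["leftHb", r]; cR <- gt$coupling["rightHb", r]
        latents[[r]] <- cL * sL + cR * sR +
          sqrt(max(0, 1 - cL^2 - cR^2)) * rnorm(n)
      }

      wm_drift <- drift_series(n); csf_drift <- drift_series(n)
      motion <- sapply(1:6, function(m) cumsum(rnorm(n, 0, 0.02)))
      colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

      n_vox <- prod(dims)
      rel <- matrix(0, n_vox, n)  # fractional fluctuation per voxel
      add_latent <- function(mask, series, frac) {
        idx <- which(mask$voxels)
        rel[idx, ] <<- rel[idx, ] + frac * rep(series, each = length(idx))
      }
      add_latent(gt$roi_layout$leftHb, sL, gt$bold_frac)
      add_latent(gt$roi_layout$rightHb, sR, gt$bold_frac)
      for (r in rois) add_latent(gt$roi_layout[[r]], latents[[r]], gt$bold_frac)

      # nuisance mixing: strong inside its compartment, weak leakage everywhere
      w_wm <- runif(n_vox, 0, 0.004); w_csf <- runif(n_vox, 0, 0.004)
      w_wm[gt$roi_layout$WM$voxels] <- runif(sum(gt$roi_layout$WM$voxels),
                                             0.01, 0.02)
      w_csf[gt$roi_layout$CSF$voxels] <- runif(sum(gt$roi_layout$CSF$voxels),
                                               0.01, 0.02)
      rel <- rel + outer(w_wm, wm_drift) + outer(w_csf, csf_drift)
      w_mot <- matrix(runif(n_vox * 6, 0, 0.01), n_vox, 6)
      rel <- rel + w_mot %*% t(motion)

      noise <- array(rnorm(n_vox * n, 0, gt$noise_sd), c(dims, n))
      if (gt$noise_fwhm > 0)
        noise <- smooth_gaussian(noise, gt$noise_fwhm, gt$voxel_size,
                                 preserve_sd = TRUE)

      amplitude <- array(as.vector(gt$m0_map) * (1 + rel), c(dims, n)) + noise
      recovery <- 1 - exp(-outer(1 / as.vector(gt$t1_map), timing$intervals))
      series <- array(as.vector(amplitude) * as.vector(recovery), c(dims, n))

      masks <- gt$roi_layout
      masks$brain <- roi_mask(array(TRUE, dims), label = "brain")
      list(subject_id = sprintf("sub-%02d", s),
           series = series, amplitude = amplitude, timing = timing,
           motion = motion, masks = masks, latents = latents,
           protocol = protocol, grid_dim = dims, voxel_size = gt$voxel_size)
    })
  })
}
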