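# Independent oracles and small fixtures shared across tests.

# Exact distribution of the longest success run in n i.i.d. Bernoulli(p)
# trials, by dynamic programming over (current run, best run so far).
# Returns P(max run >= k) for k = 0..n.
bernoulli_max_run_exceedance <- function(n, p) {
  # state: probability mass over (cur, best), 0-based runs
  prob <- matrix(0, n + 1L, n + 1L)  # [cur+1, best+1]
  prob[1L, 1L] <- 1
  for (trial in seq_len(n)) {
    nxt <- matrix(0, n + 1L, n + 1L)
    for (cur in 0:(trial - 1)) for (best in cur:(trial - 1)) {
      m <- prob[cur + 1L, best + 1L]
      if (m == 0) next
      # failure: run resets
      nxt[1L, best + 1L] <- nxt[1L, best + 1L] + m * (1 - p)
      # success: run extends
      nb <- max(best, cur + 1L)
      nxt[cur + 2L, nb + 1L] <- nxt[cur + 2L, nb + 1L] + m * p
    }
    prob <- nxt
  }
  pmax_run <- colSums(prob)  # P(best run = k), k = 0..n
  rev(cumsum(rev(pmax_run)))  # P(best >= k)
}

# Small single-voxel gated fixture: constant latent amplitude, known T1.
noiseless_voxel <- function(t1 = 1325, amp = 80,
                            intervals = rep(c(1800, 2200), 60)) {
  timing <- acquisition_timing(intervals)
  list(timing = timing, t1 = t1, amp = amp,
       signal = amp * (1 - exp(-intervals / t1)))
}

# Dense-grid CV evaluation, the brute-force oracle for estimate_t1e.
cv_grid_oracle <- function(signal, timing, grid = seq(200, 4000, by = 1)) {
  costs <- vapply(grid, function(g) cv_cost(signal, timing, g), numeric(1))
  grid[which.min(costs)]
}

# Minimal per-subject processing chain used by recovery tests (mirrors the
# pipeline stages without cluster inference or file output).
process_subject_min <- function(sub, fwhm = 3) {
  fit <- estimate_t1e(sub$series, sub$masks$brain, timing = sub$timing)
  corr <- correct_series(sub$series, fit, timing = sub$timing)$data
  wm <- erode_mask(sub$masks$WM)
  csf <- erode_mask(sub$masks$CSF)
  nu <- nuisance_set(roi_mean_series(corr, wm), roi_mean_series(corr, csf),
                     sub$motion, sub$timing$intervals)
  clean <- nuisance_regress(corr, nu)
  sm <- smooth_gaussian(clean, fwhm, sub$voxel_size)
  mask <- trim_slices(sub$masks$brain)
  zl <- correlation_map(extract_seed(clean, sub$masks$leftHb), sm, mask,
                        "leftHb", sub$subject_id)
  zr <- correlation_map(extract_seed(clean, sub$masks$rightHb), sm, mask,
                        "rightHb", sub$subject_id)
  list(zl = zl, zr = zr, sub = sub)
}

withr_local_tempdir <- function() {
  d <- tempfile("gatedfc-test-")
  dir.create(d, recursive = TRUE)
  d
}

# Small default ground truth for tests: 14x14x8 grid keeps every region
# non-empty after erosion while running fast.
test_ground_truth <- function(seed = 1L, ...) {
  ground_truth(grid_dim = c(14L, 14L, 8L), seed = seed, ...)
}
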