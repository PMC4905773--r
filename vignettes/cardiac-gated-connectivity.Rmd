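---
title: "Cardiac-gated resting-state connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-gated resting-state connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatedfc)
```

# The problem

Resting-state functional connectivity of millimetre-scale structures such as
the habenula requires high-resolution imaging of the brainstem/diencephalon,
where cardiac pulsation is the dominant physiological artifact. One remedy is
cardiac gating: each volume acquisition is triggered by the pulse (here every
second heartbeat), so motion from the cardiac cycle is frozen at a consistent
phase. The price is a variable repetition time. Longitudinal magnetization
recovers exponentially between excitations, so the measured signal of voxel
$i$ at acquisition $n$ is

$$S_{i,n} = A_{i,n}\,\bigl(1 - e^{-t_n / T1_i}\bigr),$$

where $t_n$ is the interval between acquisitions $n-1$ and $n$, $T1_i$ is the
voxel's effective longitudinal relaxation time, and $A_{i,n}$ is the
amplitude the voxel would show with full recovery. Heart-rate variability
therefore modulates every voxel's time series coherently — a potent source of
spurious correlations in a connectivity analysis. The package implements the
estimation and removal of this modulation, the seed-based connectivity
analysis built on top of it, and the inferential machinery (group
random-effects maps, laterality contrasts, a default Bayes factor, and
Monte-Carlo cluster-extent thresholds), together with a synthetic gated-BOLD
generator that makes every stage testable against known ground truth.

# Effective-T1 estimation and gating correction

`demodulate()` inverts the recovery factor at a candidate $T1$:
$A_n = S_n / (1 - e^{-t_n/T1})$. If the candidate is correct, the demodulated
amplitude of a voxel with constant underlying signal is constant; any
mismatch leaves residual modulation tracking $t_n$. `estimate_t1e()`
therefore minimizes the coefficient of variation
$\mathrm{CV}(A_n) = \mathrm{SD}(A_n)/|\overline{A_n}|$ over $T1$, per voxel.

The optimizer is a 64-point log-spaced grid on $[100, 5000]$ ms followed by
golden-section refinement inside the bracketing grid cells, stopping when the
bracket is narrower than 0.1 ms. The cost is cheap, smooth in $T1$, and can
be multimodal at low SNR; grid-plus-refine is robust and fully deterministic.
Grid ties go to the smaller $T1$ (arbitrary, documented). The search bounds
and tolerances are engineering choices: they comfortably cover tissue $T1$
values at 3 T (white matter $\approx 830$ ms, grey matter $\approx 1325$ ms,
CSF $\approx 3800$ ms).

Identifiability needs timing variation: with constant $t_n$ the recovery
factor is a single shared scale and the cost curve is flat. Voxels are
flagged unidentifiable — and pass through the correction unchanged — when the
relative range of $t_n$ is below $10^{-6}$, when the cost curve is flat
within $10^{-10}$, or when any sample is non-positive (demodulation divides
by a positive factor, so non-positive signal indicates the model does not
apply).

`correct_series()` then re-expresses every volume at the average interval
$T_{av} = \tfrac1N \sum_n t_n$:

$$Sc_{i,n} = A_{i,n}\,\bigl(1 - e^{-T_{av}/T1e_i}\bigr).$$

On exact-model data this removes all timing-induced variance; the test suite
verifies that on synthetic data the correction never increases a voxel's CV,
that noiseless voxels recover the true $T1$ to well under a millisecond, and
that noisy voxels (SNR 50, 200 volumes, 60 ms pulse SD) achieve a median
relative error under 10%.

# Nuisance cleanup and smoothing

`nuisance_regress()` removes, by voxelwise OLS, a 10-column design:
intercept, mean white-matter series, mean CSF series (both taken from the
unsmoothed corrected data over one-voxel-eroded compartment masks), six
rigid-body motion parameters, and the per-volume acquisition duration $t_n$.
The intercept is included so residuals are mean-free (otherwise later
correlations would be distorted); no additional detrending is applied. The
$t_n$ regressor removes the *linear* part of any residual timing modulation;
the nonlinear, voxel-specific part is exactly what the T1 correction
addresses, which is why the ablation test (correction disabled) shows
inflated spurious seed correlations even with the full nuisance design in
place.

`smooth_gaussian()` smooths volume by volume with a separable Gaussian,
$\sigma_{axis} = \mathrm{FWHM}/(2\sqrt{2\ln 2}\, \cdot\, \mathrm{voxel}_{axis})$,
truncated at $4\sigma$. At grid edges the per-axis kernel matrix is balanced
to doubly stochastic (iterative row/column normalization), so constant fields
*and* the volume mean are preserved exactly; interior rows are the ordinary
renormalized truncated Gaussian, and the impulse-response width matches the
nominal FWHM to within a few percent at these voxel sizes. The analysis
default is 3 mm FWHM.

Region utilities follow common practice for hand-drawn anatomy:
`rasterize_roi()` binarizes a finer-grid mask into analysis space keeping
voxels with occupancy $\ge 0.3$, and `erode_mask()` removes the one-voxel
exposed layer (6-connectivity, grid boundary counts as background).
`trim_slices()` drops the first and last slice of the slab, which can shift
into unexcited tissue between gated volumes.

# Seed connectivity and group statistics

Seed series are extracted from the cleaned *unsmoothed* data (mean over seed
voxels) while target voxels come from the cleaned *smoothed* data — the
asymmetry keeps the tiny habenular seeds free of partial-volume contamination
from neighbouring structures while giving target maps the usual noise
suppression. `correlation_map()` computes voxelwise Pearson correlations and
Fisher's $z = \operatorname{atanh}(r)$, clamping $|r|$ at $1 - 10^{-12}$;
zero-variance voxels get $z = 0$ plus a flag (excluded from group maps but
keeping grids aligned across subjects).

`group_ttest()` is the voxelwise one-sample random-effects test of $z$
against zero ($df = n - 1$); `paired_contrast()` tests the subjectwise
left-minus-right difference. For scalar region-level summaries,
`remove_outliers()` applies a single pass of the mean $\pm 2$ SD rule (both
moments from the full sample, no iteration) before a t-test, and
`jzs_bf01()` quantifies evidence *for* the null: the
Jeffreys–Zellner–Siow Bayes factor with a Cauchy prior of scale 1 on effect
size, computed by adaptive quadrature over the g-prior after the substitution
$u = g/(1+g)$. An independent log-grid Simpson rule agrees to $10^{-4}$ in
the tests.

# Monte-Carlo cluster-extent thresholds

`mc_cluster_threshold()` estimates the minimal cluster extent controlling
familywise error at $\alpha$: white Gaussian noise is generated on the mask's
bounding box padded by $3\,\mathrm{FWHM}$ (so every mask voxel sees a full
smoothing neighbourhood), smoothed to the stated FWHM, standardized by the
*analytic* per-voxel SD of the smoothed field (making the voxelwise threshold
exact under the null, with no smoothness estimation from residuals),
thresholded at the two-tailed $p$ critical value, and clustered by face
adjacency with signs kept separate (bi-sided). The returned extent is the
smallest $k$ with $\widehat{P}(\max \mathrm{extent} \ge k) \le \alpha$.
Adjacency (faces only) and sidedness are exposed as flags since conventions
differ between software versions.

At the study's operating point — voxelwise $p < 0.005$ two-tailed,
$\alpha = 0.05$, 3 mm FWHM on a $1.5 \times 1.5 \times 1.9$ mm grid — a
compact 665-voxel blob yields a 6-voxel threshold with a wide margin on both
sides, stable under a 3:1 elongation of the mask. The 248-voxel case is a
boundary case: the exceedance probability at extent 4 lies within a few
parts per thousand of $\alpha$ itself (just below it, for compact and
elongated blobs alike), so the estimator returns 4 — but masks whose shape
or simulation details shift that probability by as little as $0.002$ land at
5 instead. Runs near the minimum iteration count cannot resolve such a
boundary (at $10^4$ iterations the reported threshold flips with the seed),
so the acceptance checks and `analysis/04_cluster_thresholds.R` use $10^5$
iterations, where the Monte-Carlo standard error
($\approx 7\times10^{-4}$) separates it cleanly, and the sensitivity
analysis reports both shapes with their attained exceedance probabilities. Whole-slab thresholds for
arbitrary masks use the same machinery but are not tied to published values,
since the study's slab mask is not available.

# The synthetic generator

`simulate_gated_dataset()` emulates the study design with known ground truth:

* **Timing.** R-R intervals are i.i.d. truncated normal (default mean
  1000 ms, SD 50 ms, truncated below at half the mean); one volume per two
  beats. The i.i.d. model is the simplest that makes $T1e$ identifiable; it
  ignores autocorrelated heart-rate dynamics and respiratory sinus
  arrhythmia.
* **Protocol.** `derive_protocol()` reproduces the scanner-side calculator:
  slices fill two cardiac cycles minus a 90 ms trigger margin at
  $\approx 106.1$ ms per slice (both inferred from the published worked
  example of 18 slices / 1910 ms at 60 bpm, since no formula is given), the
  acquisition window adds 50 ms (inferred from the 1910/1960 example pair and
  cohort means), and the flip angle uses the published slice-count lookup
  verbatim (8–9 → 60°, 10–13 → 70°, 14–15 → 75°, 16–20 → 80°) rather than
  the exact Ernst angle $\cos\alpha_E = e^{-TR/T1}$, which `ernst_angle()`
  provides separately. The flip angle affects no simulated numbers beyond
  the protocol record: the steady-state amplitude is absorbed into the
  equilibrium map.
* **Signal.** Latent standard-normal seed signals (left and right drawn
  independently) and target-ROI latents realized as
  $f = c_L s_L + c_R s_R + \sqrt{1 - c_L^2 - c_R^2}\,\varepsilon$, so the
  planted coupling matrix is the true latent correlation structure. The
  default coupling emulates the laterality structure under study
  (left–VTA $+0.4$, right–VTA $-0.4$, right–SN $+0.35$, left–PAG $+0.3$,
  opposite-sign parahippocampal coupling). Voxel amplitude is
  $A_{i,n} = M0_i(1 + b\,f(n) + \mathrm{nuisance}_i(n)) + \epsilon_{i,n}$
  with $b = 1\%$ (a typical resting BOLD fluctuation), white-matter/CSF
  drifts (standardized random walks) mixed strongly inside their
  compartments and weakly everywhere, motion contributions from six smooth
  random walks kept below the study's 1.5 mm exclusion bound, and spatially
  smooth Gaussian noise (default SD 1 unit against $M0 = 100$, i.e. SNR 100;
  2 mm smoothness). The measured series is $S = A(1 - e^{-t_n/T1_i})$ with a
  per-tissue $T1$ map jittered $\pm 5\%$ per voxel.
* **Geometry.** Default grid $24 \times 24 \times 12$ at
  $1.5 \times 1.5 \times 1.9$ mm — the study's voxel size at toy extent —
  with axis-aligned boxes for the seeds, targets, and compartments, placed by
  grid fraction and verified disjoint.

What the generator does **not** emulate: k-space/MR physics beyond the
T1-recovery factor, respiratory noise, true head-motion resampling,
anatomical geometry, inter-subject registration error, or autocorrelated
physiological noise. Passing tests therefore demonstrate the correctness of
the estimators under the stated model, not performance on real data.

# Problem sizes and determinism

Module tests run on grids of $14 \times 14 \times 8$ (the smallest at which
every default region survives erosion), 60–200 volumes, and 1–30 subjects;
the cohort-level recovery checks use ten replicate 20-subject cohorts at 200
volumes. Monte-Carlo thresholds use $10^4$ iterations in module tests and
$10^5$ in the acceptance checks, as discussed above. All randomness flows
through explicit seeds (subject-level seeds derived deterministically from
the cohort seed), and regenerating a dataset or threshold with the same seed
is bit-identical; the pipeline records every output with an MD5 hash in its
provenance file.

# Known limitations

* The CV criterion assumes an amplitude that is constant apart from
  fluctuations; strong slow drifts bias $T1e$ slightly (they survive in the
  demodulated amplitude). In practice the subsequent nuisance regression
  absorbs them.
* The slice-count rule and the 50 ms acquisition-window margin are inferences
  from a single published example, not specified formulas.
* Extent thresholds assume Gaussian spatial autocorrelation at exactly the
  smoothing FWHM; no smoothness is estimated from data, and heavy-tailed
  spatial ACFs would make the thresholds anticonservative.
* The left/right seed latents are generated independently; the generator
  cannot emulate genuinely shared bilateral drive other than through the
  coupling matrix.
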