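# Readers/writers: NIfTI-1 volumes via RNifti, TSV sidecars for timing,
# motion, and manifests, JSON for ground truth and provenance.

#' Gated series container
#'
#' @param data 4D array (x, y, z, time).
#' @param timing [acquisition_timing()] with one interval per volume.
#' @param voxel_size Voxel edge lengths, mm.
#' @return A `gated_series` list.
#' @export
gated_series <- function(data, timing, voxel_size = c(1.5, 1.5, 1.9)) {
  if (length(dim(data)) != 4L) stopf("data must be a 4D array")
  if (!inherits(timing, "acquisition_timing"))
    stopf("timing must be an acquisition_timing object")
  if (dim(data)[4L] != length(timing$intervals))
    stopf("series has %d volumes but timing has %d intervals",
          dim(data)[4L], length(timing$intervals))
  structure(list(data = data, timing = timing, voxel_size = voxel_size),
            class = "gated_series")
}

#' @export
print.gated_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("gated_series: %dx%dx%d grid, %d volumes, t_av = %.1f ms\n",
              d[1], d[2], d[3], d[4], x$timing$t_av))
  invisible(x)
}

#' Write a volume or series as NIfTI-1
#'
#' @param x 3D or 4D numeric/logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge lengths, mm.
#' @return The path, invisibly.
#' @export
write_nifti_vol <- function(x, path, voxel_size = c(1.5, 1.5, 1.9)) {
  img <- RNifti::asNifti(x * 1)
  nd <- length(dim(x))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, nd - 3L))[seq_len(nd)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file; voxels above 0.5 are mask members.
#' @param label Region label for the result.
#' @return [roi_mask()].
#' @export
read_mask_nifti <- function(path, label = sub("\\.nii(\\.gz)?$", "",
                                              basename(path))) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.vector(img) > 0.5, dim(img)[1:3]), label)
}

#' Write / read an acquisition-timing sidecar
#'
#' TSV with columns `volume_index` (1-based) and `t_n_ms`.
#'
#' @param timing [acquisition_timing()].
#' @param path TSV path.
#' @return `write_timing_tsv`: the path, invisibly. `read_timing_tsv`: an
#'   [acquisition_timing()].
#' @export
write_timing_tsv <- function(timing, path) {
  utils::write.table(
    data.frame(volume_index = seq_along(timing$intervals),
               t_n_ms = timing$intervals),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timing_tsv
#' @export
read_timing_tsv <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("volume_index", "t_n_ms") %in% names(tab)))
    stopf("timing sidecar %s lacks volume_index/t_n_ms columns", path)
  acquisition_timing(tab$t_n_ms[order(tab$volume_index)])
}

#' Write / read a motion-parameter table
#'
#' TSV with six columns (three translations, three rotations), one row per
#' volume.
#'
#' @param motion n x 6 matrix.
#' @param path TSV path.
#' @return `write_motion_tsv`: the path, invisibly; `read_motion_tsv`: the
#'   matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(as.data.frame(motion), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path))
  if (ncol(m) != 6L) stopf("motion table %s has %d columns, expected 6",
                           path, ncol(m))
  m
}

#' Read a gated series from a 4D NIfTI plus its timing sidecar
#'
#' @param bold_path 4D NIfTI path.
#' @param timing_path Timing sidecar TSV (see [write_timing_tsv()]).
#' @return [gated_series()].
#' @export
read_gated_series <- function(bold_path, timing_path) {
  img <- RNifti::readNifti(bold_path)
  d <- dim(img)
  if (length(d) != 4L)
    stopf("%s is %d-dimensional, expected a 4D series", bold_path, length(d))
  timing <- read_timing_tsv(timing_path)
  if (length(timing$intervals) != d[4L])
    stopf("volume count mismatch: image has %d volumes, sidecar has %d rows",
          d[4L], length(timing$intervals))
  vs <- RNifti::pixdim(img)[1:3]
  gated_series(array(as.vector(img), d), timing, voxel_size = vs)
}

#' Write one synthetic subject to disk
#'
#' Lays out `bold.nii.gz`, `timing.tsv`, `motion.tsv`, one mask NIfTI per
#' region under `masks/`, and `ground_truth.json` (latent series and planted
#' coupling) under `dir/<subject_id>/`.
#'
#' @param subject One element of a [simulate_gated_dataset()] result.
#' @param dir Cohort directory.
#' @param coupling Coupling matrix recorded in the ground-truth JSON.
#' @return The subject directory, invisibly.
#' @export
write_subject_data <- function(subject, dir, coupling = NULL) {
  sdir <- file.path(dir, subject$subject_id)
  dir.create(file.path(sdir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_nifti_vol(subject$series, file.path(sdir, "bold.nii.gz"),
                  subject$voxel_size)
  write_timing_tsv(subject$timing, file.path(sdir, "timing.tsv"))
  write_motion_tsv(subject$motion, file.path(sdir, "motion.tsv"))
  for (nm in names(subject$masks))
    write_nifti_vol(subject$masks[[nm]]$voxels,
                    file.path(sdir, "masks", paste0(nm, ".nii.gz")),
                    subject$voxel_size)
  gt <- list(subject_id = subject$subject_id, latents = subject$latents,
             coupling = coupling, voxel_size = subject$voxel_size)
  jsonlite::write_json(gt, file.path(sdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sdir)
}

#' Read a subject manifest
#'
#' TSV with columns `subject_id`, `bold_path`, `timing_path`, `motion_path`,
#' `mask_dir`; relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV.
#' @return Data frame with absolute paths; errors if any file is missing.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "bold_path", "timing_path", "motion_path", "mask_dir")
  if (!all(need %in% names(tab)))
    stopf("manifest lacks columns: %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  root <- dirname(normalizePath(path))
  abs <- function(p) ifelse(grepl("^/", p), p, file.path(root, p))
  for (col in c("bold_path", "timing_path", "motion_path", "mask_dir"))
    tab[[col]] <- abs(tab[[col]])
  missing <- !file.exists(c(tab$bold_path, tab$timing_path, tab$motion_path))
  if (any(missing)) stopf("manifest references missing files")
  tab
}
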