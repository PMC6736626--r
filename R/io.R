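#' Write a simulated scan as NIfTI-1 plus a JSON sidecar
#'
#' The image is written as `.nii.gz` with the voxel geometry and TR in the
#' header; acquisition metadata (per-slice `SliceTiming` in seconds,
#' `RepetitionTime`, interleave step, reference slice) goes to a JSON
#' sidecar following the BIDS field-name convention.
#'
#' @param scan An [fmri4d()] scan.
#' @param path Output path ending in `.nii` or `.nii.gz`; the sidecar
#'   replaces that extension with `.json`.
#' @param extra Optional named list merged into the sidecar (e.g. seed,
#'   noise parameters).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, extra = list()) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  img <- RNifti::asNifti(scan$data)
  RNifti::pixdim(img) <- c(scan$voxel_size_mm, scan$tr_s)
  RNifti::writeNifti(img, path)
  side <- c(list(
    RepetitionTime = scan$tr_s,
    SliceTiming = scan$scheme$slice_times_s,
    InterleaveStep = scan$scheme$interleave_step,
    ReferenceSlice = scan$scheme$ref_slice,
    Provenance = scan$provenance), extra)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a NIfTI scan and its slice-timing sidecar
#'
#' @param path Path to a `.nii`/`.nii.gz` file with a matching `.json`
#'   sidecar.
#' @return An [fmri4d()] scan.
#' @export
read_scan <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing sidecar %s", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  nz <- dim(data)[3]
  if (length(side$SliceTiming) != nz)
    stopf("sidecar declares %d slice times for a %d-slice image",
          length(side$SliceTiming), nz)
  scheme <- build_scheme(side$RepetitionTime, nz,
                         side$InterleaveStep %||% 1L,
                         side$ReferenceSlice %||% NULL)
  if (max(abs(scheme$slice_times_s - side$SliceTiming)) > 1e-6)
    stopf("sidecar slice times inconsistent with TR/interleave metadata")
  pd <- RNifti::pixdim(img)
  fmri4d(data, pd[1:3], scheme,
         provenance = unlist(side$Provenance) %||% character())
}

#' Write a motion trace as TSV
#'
#' Six columns (x, y, z translations in mm; x, y, z rotations in rad), one
#' row per sample.
#'
#' @param trace A [motion_trace()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_motion_tsv <- function(trace, path) {
  df <- data.frame(trace$translations_mm, trace$rotations_rad)
  names(df) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                 "rot_x_rad", "rot_y_rad", "rot_z_rad")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion TSV written by [write_motion_tsv()]
#' @param path TSV path.
#' @param tr_s Sampling interval used to reconstruct the time axis.
#' @return A [motion_trace()].
#' @export
read_motion_tsv <- function(path, tr_s = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  motion_trace((seq_len(nrow(df)) - 1) * tr_s,
               as.matrix(df[, 1:3]), as.matrix(df[, 4:6]))
}

#' Write a stimulus train as a BIDS-style events TSV
#' @param stim A [generate_stimulus()] train.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(stim, path) {
  df <- data.frame(onset = stim$onsets_s, duration = stim$durations_s)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path Events TSV with `onset` and `duration` columns.
#' @param total_s Scan duration in seconds.
#' @return A [generate_stimulus()] train.
#' @export
read_events_tsv <- function(path, total_s) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(onsets_s = df$onset, durations_s = df$duration,
                 total_duration_s = total_s),
            class = "stimulus_train")
}
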