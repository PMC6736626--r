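#' 4-D fMRI scan container
#'
#' Bundles a 4-D intensity array (x, y, z, t) with its voxel geometry, TR,
#' acquisition scheme, and a free-form provenance record of applied steps.
#'
#' @param data 4-D numeric array.
#' @param voxel_size_mm Length-3 voxel size.
#' @param scheme An [build_scheme()] acquisition scheme; `dim(data)[3]`
#'   must equal `scheme$n_slices`.
#' @param provenance Character vector of applied processing steps.
#' @return An object of class `fmri4d`.
#' @export
fmri4d <- function(data, voxel_size_mm, scheme, provenance = character()) {
  if (length(dim(data)) != 4L) stopf("data must be a 4-D array")
  if (!inherits(scheme, "acquisition_scheme"))
    stopf("scheme must be an acquisition_scheme")
  if (dim(data)[3] != scheme$n_slices)
    stopf("data has %d slices but the scheme declares %d",
          dim(data)[3], scheme$n_slices)
  if (!all(is.finite(data))) stopf("data must be finite")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = scheme$tr_s, scheme = scheme,
                 provenance = as.character(provenance)),
            class = "fmri4d")
}

#' @export
print.fmri4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri4d> %dx%dx%d voxels x %d volumes, TR %.3g s, interleave %d\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$scheme$interleave_step))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

n_vols <- function(scan) dim(scan$data)[4]

with_data <- function(scan, data, step = NULL) {
  scan$data <- data
  if (!is.null(step)) scan$provenance <- c(scan$provenance, step)
  scan
}

## Apply a function to the (n_time x n_vox) series matrix of each slice.
## f(mat, k) must return a matrix of the same shape.
map_slices <- function(scan, f) {
  d <- dim(scan$data)
  out <- scan$data
  for (k in seq_len(d[3])) {
    m <- matrix(aperm(scan$data[, , k, , drop = FALSE], c(4, 1, 2, 3)),
                nrow = d[4])
    m2 <- f(m, k)
    out[, , k, ] <- aperm(array(m2, c(d[4], d[1], d[2])), c(2, 3, 1))
  }
  out
}
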