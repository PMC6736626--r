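#' Select the top-k voxels of a slice by t statistic
#'
#' Restricts the statistic map to `roi_mask` intersected with slice
#' `slice_index`, then picks the `k` voxels with the highest t values,
#' breaking ties by ascending linear index.
#'
#' @param tmap 3-D array of t statistics.
#' @param roi_mask Logical array of the same shape.
#' @param slice_index Slice (third-axis index) to draw from.
#' @param k Number of voxels (default 20).
#' @return An object of class `voxel_set`: list with `coords` (k x 3
#'   matrix of (i, j, k) indices), `index` (linear indices), `source_slice`,
#'   `k_top`, `selection_stat`.
#' @export
select_top_voxels <- function(tmap, roi_mask, slice_index, k = 20L) {
  if (!all(dim(tmap) == dim(roi_mask))) stopf("tmap/mask shape mismatch")
  k <- check_count(k, "k")
  slice_index <- check_count(slice_index, "slice_index")
  elig <- roi_mask
  elig[, , -slice_index] <- FALSE
  idx <- which(elig & !is.na(tmap))
  if (length(idx) < k)
    stopf("only %d eligible voxels on slice %d (need %d)",
          length(idx), slice_index, k)
  ord <- idx[order(-tmap[idx], idx)]
  top <- ord[seq_len(k)]
  coords <- arrayInd(top, dim(tmap))
  structure(list(coords = coords, index = top, source_slice = slice_index,
                 k_top = k, selection_stat = tmap[top]),
            class = "voxel_set")
}

#' Dice overlap of two voxel sets
#'
#' `2 |A intersect B| / (|A| + |B|)`.
#'
#' @param a,b [select_top_voxels()] voxel sets (or integer index vectors).
#' @return Scalar in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  ia <- if (inherits(a, "voxel_set")) a$index else as.integer(a)
  ib <- if (inherits(b, "voxel_set")) b$index else as.integer(b)
  if (length(ia) == 0 && length(ib) == 0)
    stopf("dice overlap of two empty sets is undefined")
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

#' Sum of squared error between unit-normalized response curves
#'
#' Both curves are scaled to unit Euclidean norm before the SSE is taken,
#' making the measure invariant to (positive) amplitude rescaling of
#' either argument; it is bounded by 4 (anti-parallel unit vectors).
#'
#' @param estimated,truth Numeric vectors on the same lag grid.
#' @return Scalar SSE.
#' @export
hrf_sse <- function(estimated, truth) {
  if (length(estimated) != length(truth))
    stopf("curves must share one lag grid")
  ne <- sqrt(sum(estimated^2)); nt <- sqrt(sum(truth^2))
  if (ne == 0 || nt == 0) stopf("zero-norm curve")
  sum((estimated / ne - truth / nt)^2)
}

#' Gaussian spatial smoothing of a 4-D scan
#'
#' Convolves each 3-D volume with a separable Gaussian of the requested
#' full width at half maximum (`sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, converted to voxel units), with nearest-replication boundaries.
#' `fwhm_mm = 0` is the identity.
#'
#' @param scan An [fmri4d()] scan.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @return The smoothed `fmri4d` scan.
#' @export
gaussian_smooth <- function(scan, fwhm_mm) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  check_num(fwhm_mm, "fwhm_mm", nonneg = TRUE)
  if (fwhm_mm == 0) return(scan)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / scan$voxel_size_mm
  d <- dim(scan$data)
  out <- scan$data
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- gauss_band_matrix(d[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:4, ax))
    m <- aperm(out, perm)
    dim(m) <- c(d[ax], prod(d[-ax]))
    m <- K %*% m
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  with_data(scan, out, sprintf("smooth(fwhm=%.3gmm)", fwhm_mm))
}

#' Split-half reliability of the beta map
#'
#' Splits the series into its first and second temporal halves, rebuilds
#' the task regressor for each half, fits both GLMs, and returns the
#' Pearson correlation of the two beta maps within the mask.
#'
#' @param scan An [fmri4d()] scan (odd final volume dropped).
#' @param stim,hrf Stimulus train and HRF used to rebuild the regressors.
#' @param mask Logical array with at least 2 voxels.
#' @return Correlation scalar.
#' @export
split_half_reliability <- function(scan, stim, hrf, mask) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  if (sum(mask) < 2L) stopf("mask must contain at least 2 voxels")
  V <- n_vols(scan) %/% 2L * 2L
  half <- V %/% 2L
  tr <- scan$tr_s
  reg_full <- build_task_regressor(stim, hrf, tr, V)
  betas <- lapply(1:2, function(h) {
    vols <- seq_len(half) + (h - 1L) * half
    reg <- reg_full[vols]
    if (sd(reg) == 0) stopf("half %d has zero task variance", h)
    d <- dim(scan$data)
    Y <- t(matrix(scan$data[, , , vols], nrow = prod(d[1:3])))
    fit <- fit_glm(Y, design_matrix(reg), mask = as.vector(mask))
    fit$beta
  })
  stats::cor(betas[[1]], betas[[2]])
}

#' Paired one-tailed t test
#'
#' Paired t test on `a - b` with the one-sided alternative
#' `mean(a) > mean(b)`; `dof = n - 1`.
#'
#' @param z_a,z_b Equal-length paired vectors.
#' @return List with `t`, `p`, `dof`.
#' @export
paired_one_tailed_t <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) stopf("paired vectors differ in length")
  n <- length(z_a)
  if (n < 2L) stopf("need at least 2 pairs")
  d <- z_a - z_b
  if (sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    if (abs(mean(d)) <= 1e-12) return(list(t = 0, p = 0.5, dof = n - 1L))
    return(list(t = sign(mean(d)) * Inf, p = as.numeric(mean(d) < 0),
                dof = n - 1L))
  }
  ht <- t.test(z_a, z_b, paired = TRUE, alternative = "greater")
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       dof = unname(ht$parameter))
}
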