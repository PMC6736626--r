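#' Build a synthetic brain-like phantom with labelled ROIs
#'
#' Constructs an ellipsoidal "brain" on a voxel grid with a smooth
#' tissue-like baseline intensity (bright core, darker shell) and a set of
#' named regions of interest. One ROI, `"tall_cortex"`, is a thin
#' (about two voxels in-plane) cortical band that spans at least half of
#' all slices, standing in for a superior-frontal-type region that crosses
#' many acquisition delays. Three further compact ROIs (`"occipital"`,
#' `"parietal"`, `"deep"`) sit elsewhere in the volume. Background voxels
#' carry label 0 and zero intensity.
#'
#' @param shape Integer length-3 grid size `(nx, ny, nz)`; `nz >= 10`.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @param seed Optional seed controlling the smooth intensity perturbation.
#' @return An object of class `phantom` with fields `label_grid` (integer
#'   array), `mean_intensity` (array), `roi_masks` (named list of logical
#'   arrays), `roi_labels` (named integer vector), `voxel_size_mm`, `shape`.
#' @export
build_phantom <- function(shape = c(32L, 32L, 20L),
                          voxel_size_mm = c(2, 2, 3), seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L) || shape[3] < 10L)
    stopf("shape must be three integers with nz >= 10")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be three positive numbers")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ## normalized coordinates in [-1, 1] per axis
  cx <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  cy <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  cz <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2)
  X <- array(rep(cx, times = ny * nz), dim = shape)
  Y <- array(rep(rep(cy, each = nx), times = nz), dim = shape)
  Z <- array(rep(cz, each = nx * ny), dim = shape)
  ## anisotropic ellipsoid (narrower left-right than anterior-posterior,
  ## like a real head) so in-plane rotation is identifiable
  r2 <- (X / 0.80)^2 + (Y / 0.95)^2 + (Z / 0.95)^2
  brain <- r2 <= 1
  ## baseline: bright white-matter-like core fading to a darker shell,
  ## with two dark ventricle-like lobes off-centre
  base <- array(0, dim = shape)
  base[brain] <- 800 + 400 * (1 - r2[brain])
  vent <- ((abs(X) - 0.22)^2 / 0.012 + (Y - 0.05)^2 / 0.06 + Z^2 / 0.10) < 1
  base[brain & vent] <- base[brain & vent] - 350
  perturb <- with_seed(seed, {
    p <- array(rnorm(prod(shape), sd = 1), dim = shape)
    smooth3d(p, sigma_vox = c(2, 2, 1.5))
  })
  base[brain] <- base[brain] * (1 + 0.05 * perturb[brain] / max(1e-9, sd(perturb[brain])))
  ## partial-volume soft edge, as in real EPI: slight blur of the baseline
  base <- smooth3d(base, sigma_vox = c(0.7, 0.7, 0.5))

  lab <- array(0L, dim = shape)
  ## tall cortical band: thin (about two voxels) shell segment on the
  ## anterior (+y) side, spanning the central >= nz/2 slices; its outer
  ## face sits at the brain edge, as cortex does
  shell <- brain & r2 > 0.80 & Y > 0.35 & abs(X) < 0.55
  zspan <- cz >= cz[max(1L, floor(nz * 0.15))] & cz <= cz[ceiling(nz * 0.9)]
  tall <- shell & array(rep(zspan, each = nx * ny), dim = shape)
  ## compact blobs
  occ <- brain & ((X - 0.0)^2 + (Y + 0.6)^2 + (Z - 0.0)^2) < 0.09
  par <- brain & ((X + 0.5)^2 + (Y - 0.1)^2 + (Z - 0.35)^2) < 0.07
  deep <- brain & (X^2 + Y^2 + (Z + 0.1)^2) < 0.06
  lab[tall] <- 1L; lab[occ] <- 2L; lab[par] <- 3L; lab[deep] <- 4L
  masks <- list(tall_cortex = lab == 1L, occipital = lab == 2L,
                parietal = lab == 3L, deep = lab == 4L)
  nslice_tall <- sum(apply(masks$tall_cortex, 3, any))
  if (nslice_tall < nz / 2)
    stopf("internal error: tall ROI spans only %d of %d slices", nslice_tall, nz)
  structure(list(label_grid = lab, mean_intensity = base,
                 roi_masks = masks,
                 roi_labels = c(tall_cortex = 1L, occipital = 2L,
                                parietal = 3L, deep = 4L),
                 brain_mask = brain,
                 voxel_size_mm = as.numeric(voxel_size_mm), shape = shape),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%dx%d voxels (%.3gx%.3gx%.3g mm), %d ROIs\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm[1],
              x$voxel_size_mm[2], x$voxel_size_mm[3], length(x$roi_masks)))
  invisible(x)
}

## Separable Gaussian smoothing of a 3-D or 4-D array along the first
## three axes, in voxel units (edge handling: nearest replication).
smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  nd <- length(d)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    K <- gauss_band_matrix(d[ax], s)
    perm <- c(ax, setdiff(seq_len(nd), ax))
    m <- aperm(arr, perm)
    dim(m) <- c(d[ax], prod(d[-ax]))
    m <- K %*% m
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

smooth4d <- smooth3d

## Dense n x n Gaussian kernel matrix with nearest-boundary replication
## (clipped tap indices accumulate onto the edge rows).
gauss_band_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq(-half, half)) {
    idx <- pmin(pmax(seq_len(n) + j, 1L), n)
    K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + w[j + half + 1L]
  }
  K
}
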