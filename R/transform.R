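#' Rigid-body transforms
#'
#' A rigid transform is parameterized by three translations (mm) and three
#' rotations (rad) about the volume centre, composed intrinsically in the
#' order x, then y, then z: `R = Rz %*% Ry %*% Rx`. Applied to a point `p`
#' in mm coordinates the forward map is `T(p) = R (p - c) + c + t` where
#' `c` is the volume centre.
#'
#' @param translations_mm Numeric length-3.
#' @param rotations_rad Numeric length-3.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translations_mm = c(0, 0, 0),
                            rotations_rad = c(0, 0, 0)) {
  if (length(translations_mm) != 3L || length(rotations_rad) != 3L)
    stopf("need 3 translations and 3 rotations")
  structure(list(translations_mm = as.numeric(translations_mm),
                 rotations_rad = as.numeric(rotations_rad)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3g, %.3g, %.3g) mm, r = (%.3g, %.3g, %.3g) rad\n",
              x$translations_mm[1], x$translations_mm[2], x$translations_mm[3],
              x$rotations_rad[1], x$rotations_rad[2], x$rotations_rad[3]))
  invisible(x)
}

rot_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

## Euler angles (x, y, z order) from a rotation matrix R = Rz Ry Rx.
euler_from_rot <- function(R) {
  ry <- -asin(max(-1, min(1, R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz)
}

## Composition A(B(p)) of two centre-anchored rigid transforms.
compose_transform <- function(A, B) {
  RA <- rot_matrix(A$rotations_rad)
  RB <- rot_matrix(B$rotations_rad)
  rigid_transform(as.vector(RA %*% B$translations_mm) + A$translations_mm,
                  euler_from_rot(RA %*% RB))
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The `rigid_transform` whose composition with `transform` is the
#'   identity.
#' @export
invert_transform <- function(transform) {
  R <- rot_matrix(transform$rotations_rad)
  ## T^{-1}(p) = R' (p - c) + c + t' with R' = R^T, t' = -R^T t
  rigid_transform(-as.vector(t(R) %*% transform$translations_mm),
                  euler_from_rot(t(R)))
}

## 3 x 4 pull matrix in 0-based voxel coordinates: for an image whose
## content has undergone `transform`, the resampled value at output voxel v
## is taken from input voxel A[,1:3] %*% v + A[,4].
pull_matrix <- function(transform, dim3, voxmm) {
  R <- rot_matrix(transform$rotations_rad)
  t <- transform$translations_mm
  c_mm <- (dim3 - 1) / 2 * voxmm
  S <- diag(voxmm)
  Sinv <- diag(1 / voxmm)
  ## x_in = T^{-1}(x_out) = R^T (x_out - c - t) + c   (mm coords)
  A3 <- Sinv %*% t(R) %*% S
  b <- Sinv %*% (t(R) %*% (-c_mm - t) + c_mm)
  cbind(A3, b)
}

## 3 x 4 matrix of the forward map itself in 0-based voxel coordinates:
## x_mapped = R (x - c) + c + t. Sampling a moving volume at these
## coordinates and comparing with the reference realizes the registration
## cost without an explicit matrix inversion per evaluation.
push_matrix <- function(transform, dim3, voxmm) {
  R <- rot_matrix(transform$rotations_rad)
  t <- transform$translations_mm
  c_mm <- (dim3 - 1) / 2 * voxmm
  S <- diag(voxmm)
  Sinv <- diag(1 / voxmm)
  A3 <- Sinv %*% R %*% S
  b <- Sinv %*% (-R %*% c_mm + c_mm + t)
  cbind(A3, b)
}

#' Resample a 3-D volume under a rigid transform
#'
#' Applies `transform` to the image content by inverse-mapped resampling:
#' the output value at voxel `x` is the input interpolated at
#' `T^{-1}(x)`. Out-of-field voxels are filled with `fill`.
#'
#' @param vol 3-D numeric array.
#' @param transform A [rigid_transform()].
#' @param voxel_size_mm Voxel size, length 3.
#' @param interp_order 1 (trilinear) or 3 (cubic convolution).
#' @param fill Fill value for voxels mapped outside the input field.
#' @return The resampled 3-D array.
#' @export
resample_rigid <- function(vol, transform, voxel_size_mm = c(1, 1, 1),
                           interp_order = 3L, fill = 0) {
  if (length(dim(vol)) != 3L) stopf("vol must be a 3-D array")
  if (!interp_order %in% c(1L, 3L)) stopf("interp_order must be 1 or 3")
  A <- pull_matrix(transform, dim(vol), voxel_size_mm)
  out <- cpp_pull_resample(vol, A, as.integer(interp_order), fill)
  array(out, dim = dim(vol))
}
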