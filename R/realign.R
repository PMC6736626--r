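#' Estimate the rigid transform between two volumes
#'
#' Finds the 6-parameter rigid motion that maps the reference volume onto
#' `vol`, by minimizing the mean squared intensity difference between
#' `vol` pulled back through the candidate transform and `ref_vol`.
#' Optimization is a derivative-free Nelder-Mead simplex run
#' coarse-to-fine on a two-level pyramid (2x block-mean downsampling, then
#' full resolution), optionally warm-started from `init`.
#'
#' @param vol Moving 3-D volume.
#' @param ref_vol Reference 3-D volume of the same shape.
#' @param voxel_size_mm Voxel size, length 3.
#' @param init Optional [rigid_transform()] initial guess.
#' @param tol Relative convergence tolerance of the simplex (default 1e-8).
#' @param maxit Iteration cap per pyramid level.
#' @param pyramid Use the coarse level (default TRUE).
#' @param smooth_sigma_vox Gaussian pre-smoothing (voxels) applied to both
#'   volumes before the cost is evaluated; suppresses the
#'   interpolation-induced pull of rotation estimates toward zero
#'   (default 1).
#' @param interp_order,stride,n_restarts Cost interpolation order (1 or
#'   3), voxel stride of the cost grid, and Nelder-Mead restarts.
#' @param refine After convergence, resample the moving volume by the
#'   inverse estimate and re-estimate the residual, composing the two
#'   (default TRUE; skipped for sub-half-millimetre displacements).
#' @return A [rigid_transform()] with attribute `cost` (final mean squared
#'   difference). The returned transform is the estimated motion of `vol`
#'   relative to `ref_vol`; applying its inverse via [resample_rigid()]
#'   realigns `vol` onto `ref_vol`.
#' @export
estimate_rigid <- function(vol, ref_vol, voxel_size_mm = c(1, 1, 1),
                           init = NULL, tol = 1e-10, maxit = 800L,
                           pyramid = TRUE, smooth_sigma_vox = 1,
                           interp_order = 3L, stride = 1L,
                           n_restarts = 5L, refine = TRUE) {
  if (length(dim(vol)) != 3L || !all(dim(vol) == dim(ref_vol)))
    stopf("vol and ref_vol must be 3-D arrays of the same shape")
  vol0 <- vol; ref0 <- ref_vol
  if (smooth_sigma_vox > 0) {
    vol <- smooth3d(vol, rep(smooth_sigma_vox, 3))
    ref_vol <- smooth3d(ref_vol, rep(smooth_sigma_vox, 3))
  }
  p0 <- if (is.null(init)) rep(0, 6)
  else c(init$translations_mm, init$rotations_rad)
  parscale <- c(1, 1, 1, 0.02, 0.02, 0.02)
  ## cost restricted to the reference brain support; sampling `vol` along
  ## the candidate motion T(p) and comparing to the reference is minimized
  ## when T(p) equals the motion that produced vol
  mask <- as.integer(ref_vol > 0.01 * max(ref_vol))
  ## output voxels within 3 voxels of the array boundary are excluded from
  ## the cost: at the optimum those are the only samples whose source can
  ## touch fill-contaminated voxels of the moving volume
  margin <- pmin(rep(3, 3), pmax((dim(vol) - 1) %/% 2 - 1, 0))
  make_cost <- function(v, r, msk, vox, ord, strd, marg) {
    vc <- if (ord == 3L) cpp_prefilter3(v) else v
    dim(vc) <- dim(v)
    function(p) {
      A <- push_matrix(rigid_transform(p[1:3], p[4:6]), dim(v), vox)
      cpp_pull_ssd(vc, r, A, ord, msk, strd, marg)
    }
  }
  ctrl <- function(rt) list(maxit = maxit, reltol = rt, parscale = parscale)
  if (pyramid && all(dim(vol) >= 8L)) {
    rc <- downsample2(ref_vol)
    cost_c <- make_cost(downsample2(vol), rc,
                        as.integer(rc > 0.01 * max(rc)),
                        voxel_size_mm * 2, 1L, 1L,
                        pmin(rep(2, 3), pmax(dim(rc) %/% 4, 0)))
    oc <- optim(p0, cost_c, method = "Nelder-Mead", control = ctrl(tol * 100))
    p0 <- oc$par
  }
  cost_f <- make_cost(vol, ref_vol, mask, voxel_size_mm,
                      as.integer(interp_order), as.integer(stride), margin)
  of <- NULL
  for (i in seq_len(max(1L, n_restarts))) {
    o2 <- optim(p0, cost_f, method = "Nelder-Mead", control = ctrl(tol))
    improved <- if (is.null(of)) Inf else of$value - o2$value
    of <- o2
    p0 <- of$par
    if (improved <= abs(tol) * max(1, of$value)) break
  }
  out <- rigid_transform(of$par[1:3], of$par[4:6])
  if (refine && max(abs(of$par * c(1, 1, 1, 50, 50, 50))) > 0.5) {
    ## undo the estimate and re-estimate the residual in the small-motion
    ## regime, where the interpolation-induced bias is negligible
    aligned <- resample_rigid(vol0, invert_transform(out), voxel_size_mm, 3L)
    resid <- estimate_rigid(aligned, ref0, voxel_size_mm, pyramid = FALSE,
                            smooth_sigma_vox = smooth_sigma_vox,
                            interp_order = interp_order, stride = stride,
                            n_restarts = n_restarts, tol = tol,
                            maxit = maxit, refine = FALSE)
    out2 <- compose_transform(out, resid)
    attr(out2, "cost") <- attr(resid, "cost")
    attr(out2, "convergence") <- attr(resid, "convergence")
    return(out2)
  }
  attr(out, "cost") <- of$value
  attr(out, "convergence") <- of$convergence
  out
}

#' Apply previously estimated motion to a scan
#'
#' Resamples every volume of `scan` by the inverse of the per-volume
#' rigid parameters in `motion`, realigning the scan without re-running
#' the estimation (e.g. reusing transforms estimated on a filtered copy
#' of the same scan).
#'
#' @param scan An [fmri4d()] scan.
#' @param motion Per-volume [motion_trace()] of estimates, as returned by
#'   [realign_series()].
#' @param ref_index Volume left untouched (default: middle volume).
#' @param interp_order Resampling order (default 3).
#' @return The realigned `fmri4d` scan.
#' @export
apply_motion <- function(scan, motion, ref_index = NULL, interp_order = 3L) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  V <- n_vols(scan)
  if (length(motion$times_s) != V)
    stopf("motion has %d samples for %d volumes", length(motion$times_s), V)
  if (is.null(ref_index)) ref_index <- (V + 1L) %/% 2L
  out <- scan$data
  for (v in seq_len(V)) {
    if (v == ref_index) next
    tf <- invert_transform(rigid_transform(motion$translations_mm[v, ],
                                           motion$rotations_rad[v, ]))
    out[, , , v] <- resample_rigid(scan$data[, , , v], tf,
                                   scan$voxel_size_mm, interp_order)
  }
  list(scan = with_data(scan, out, sprintf("realign(ref=%d)", ref_index)),
       motion = motion)
}

## 2x block-mean downsampling along every axis (trailing odd voxel dropped).
downsample2 <- function(vol) {
  d <- dim(vol) %/% 2L
  v <- vol[seq_len(2 * d[1]), seq_len(2 * d[2]), seq_len(2 * d[3])]
  e <- (v[seq(1, 2 * d[1], 2), , ] + v[seq(2, 2 * d[1], 2), , ]) / 2
  e <- (e[, seq(1, 2 * d[2], 2), ] + e[, seq(2, 2 * d[2], 2), ]) / 2
  (e[, , seq(1, 2 * d[3], 2)] + e[, , seq(2, 2 * d[3], 2)]) / 2
}

#' Rigid-body realignment of a 4-D scan
#'
#' Registers every volume to the reference volume (the middle one by
#' default), resamples each volume into the reference frame, and returns
#' both the realigned scan and the per-volume motion estimates. Estimation
#' is warm-started from the neighbouring volume's estimate, working
#' outward from the reference.
#'
#' @param scan An [fmri4d()] scan with at least 2 volumes.
#' @param ref_index Reference volume index (default: middle volume).
#' @param interp_order Interpolation order for the final resampling
#'   (default 3).
#' @param estimate_only If `TRUE`, return the motion estimates without
#'   resampling the data (used for motion parameter residualization
#'   without realignment).
#' @param cost_order,stride,n_restarts Registration cost settings passed
#'   to [estimate_rigid()]; the defaults (trilinear cost on a stride-2
#'   voxel grid, warm-started from the neighbouring volume) trade a little
#'   precision for the speed a 4-D series needs.
#' @return A list with `scan` (realigned; the input scan if
#'   `estimate_only`) and `motion` (a per-volume [motion_trace()] of the
#'   estimates).
#' @export
realign_series <- function(scan, ref_index = NULL, interp_order = 3L,
                           estimate_only = FALSE, cost_order = 3L,
                           stride = 3L, n_restarts = 1L) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  V <- n_vols(scan)
  if (V < 2L) stopf("need at least 2 volumes")
  if (is.null(ref_index)) ref_index <- (V + 1L) %/% 2L
  ref_index <- check_count(ref_index, "ref_index")
  if (ref_index > V) stopf("ref_index out of range")
  ## pre-smooth all volumes once (the cost's 1-voxel Gaussian), rather
  ## than per registration
  sm <- smooth4d(scan$data, rep(1, 3))
  ref <- sm[, , , ref_index]
  pars <- matrix(0, V, 6)
  ## outward sweep with warm starts
  order_idx <- c(seq(ref_index + 1L, V, length.out = max(0L, V - ref_index)),
                 seq(ref_index - 1L, 1L, length.out = max(0L, ref_index - 1L)))
  order_idx <- as.integer(order_idx)
  for (v in order_idx) {
    prev <- if (v > ref_index) v - 1L else v + 1L
    init <- rigid_transform(pars[prev, 1:3], pars[prev, 4:6])
    est <- tryCatch(
      estimate_rigid(sm[, , , v], ref, scan$voxel_size_mm,
                     init = init, pyramid = TRUE, smooth_sigma_vox = 0,
                     interp_order = cost_order, stride = stride,
                     n_restarts = n_restarts, tol = 1e-6, refine = FALSE),
      error = function(e) stopf("realignment failed at volume %d: %s",
                                v, conditionMessage(e)))
    pars[v, ] <- c(est$translations_mm, est$rotations_rad)
  }
  trace <- motion_trace((seq_len(V) - 1) * scan$tr_s, pars[, 1:3, drop = FALSE],
                        pars[, 4:6, drop = FALSE])
  if (estimate_only)
    return(list(scan = scan, motion = trace))
  out <- scan$data
  for (v in seq_len(V)) {
    if (v == ref_index) next
    tf <- invert_transform(rigid_transform(pars[v, 1:3], pars[v, 4:6]))
    out[, , , v] <- resample_rigid(scan$data[, , , v], tf,
                                   scan$voxel_size_mm, interp_order)
  }
  list(scan = with_data(scan, out, sprintf("realign(ref=%d)", ref_index)),
       motion = trace)
}
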