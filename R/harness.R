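#' Pipeline specification
#'
#' Encodes one preprocessing pipeline: the slice timing correction method,
#' where motion correction sits relative to it, and the optional motion
#' parameter residualization, prewhitening, and smoothing stages.
#' `mc = "before_stc"` applies motion correction first (the "STC after
#' MC" pipeline), `"after_stc"` applies it to the corrected data, and
#' `"none"` applies no realignment. With `mc = "none"` and `mpr = TRUE`,
#' motion parameters are still estimated (after STC) but no realignment
#' is applied. The shifted-regressor method applies no temporal shift to
#' the data; it low-pass filters (before any MC) and carries the
#' per-slice shift in the regressor.
#'
#' @param stc_method One of `"filtershift"`, `"sinc"`, `"fourier"`,
#'   `"none"`, `"shifted_regressor"`.
#' @param mc One of `"before_stc"`, `"after_stc"`, `"none"`.
#' @param mpr Include the 12 motion nuisance regressors.
#' @param prewhiten Apply ARMA(1,1) prewhitening before the final fit.
#' @param smoothing_fwhm_mm Gaussian FWHM in mm (0 = no smoothing).
#' @param ref_slice Optional reference slice override.
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(stc_method = c("filtershift", "sinc", "fourier",
                                         "none", "shifted_regressor"),
                          mc = c("before_stc", "after_stc", "none"),
                          mpr = FALSE, prewhiten = FALSE,
                          smoothing_fwhm_mm = 0, ref_slice = NULL) {
  stc_method <- match.arg(stc_method)
  mc <- match.arg(mc)
  check_flag(mpr, "mpr")
  check_flag(prewhiten, "prewhiten")
  check_num(smoothing_fwhm_mm, "smoothing_fwhm_mm", nonneg = TRUE)
  structure(list(stc_method = stc_method, mc = mc, mpr = mpr,
                 prewhiten = prewhiten,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 ref_slice = ref_slice),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline_spec> stc=%s, mc=%s, mpr=%s, pw=%s, fwhm=%.3g mm\n",
              x$stc_method, x$mc, x$mpr, x$prewhiten, x$smoothing_fwhm_mm))
  invisible(x)
}

## Highest-delay slice that still holds at least k ROI voxels.
pick_high_delay_slice <- function(roi_mask, scheme, k = 20L) {
  counts <- apply(roi_mask, 3, sum)
  elig <- which(counts >= k)
  if (!length(elig)) stopf("no slice holds %d ROI voxels", k)
  elig[which.max(scheme$slice_times_s[elig])]
}

apply_stc <- function(scan, method, fspec) {
  switch(method,
         filtershift = filtershift(scan, fspec),
         sinc = hanning_sinc_stc(scan),
         fourier = fourier_phase_stc(scan),
         none = scan,
         shifted_regressor =
           with_data(scan, map_slices(scan, function(m, k)
             kaiser_lowpass(m, 1 / scan$tr_s, spec_with_L(fspec, scan))),
             "sr_lowpass"))
}

spec_with_L <- function(fspec, scan) {
  fspec$upsample_factor <- fspec$upsample_factor %||% scan$scheme$n_slices
  fspec
}

#' Run one preprocessing pipeline and evaluate it
#'
#' Applies the steps encoded in `spec` to `scan`, fits the voxelwise GLM
#' (per-slice shifted regressors for the shifted-regressor method, the
#' plain task regressor otherwise), and evaluates against the reference
#' voxel set: mean Fisher z over the reference voxels, dice overlap of the
#' pipeline's own top-k voxels with the reference set, and per-voxel
#' unit-normalized SSE of the FIR-deconvolved HRF against the true HRF.
#'
#' @param scan An [fmri4d()] scan.
#' @param spec A [pipeline_spec()].
#' @param stim Stimulus train driving the analysed ROI.
#' @param hrf The HRF model used to build regressors (and as HRF truth).
#' @param roi_mask Logical array confining voxel selection.
#' @param ref_set Reference [select_top_voxels()] set from the
#'   shifted-regressor reference run (see [sr_reference()]); `NULL` fits
#'   and evaluates on the pipeline's own top-k set.
#' @param fspec [filter_spec()] shared by FilterShift and the SR low-pass.
#' @param mc_cache Optional precomputed [realign_series()] result for the
#'   raw scan, reused when `mc = "before_stc"`.
#' @param k Top-voxel count (default 20).
#' @param fir_window_s FIR deconvolution window (default 24 s).
#' @param full_maps Fit the GLM on every slice (default: only the slice
#'   the voxel protocol evaluates, which is all the metrics need).
#' @return List with `mean_z`, `z_voxels`, `dice`, `sse` (per-voxel),
#'   `mean_sse`, `maps` (the [fit_glm()] maps), `own_set`, `motion`
#'   (estimates when computed), and `spec`.
#' @export
run_pipeline <- function(scan, spec, stim, hrf, roi_mask, ref_set = NULL,
                         fspec = filter_spec(), mc_cache = NULL, k = 20L,
                         fir_window_s = 24, full_maps = FALSE) {
  if (!inherits(spec, "pipeline_spec")) stopf("spec must be a pipeline_spec")
  if (!is.null(spec$ref_slice)) scan$scheme$ref_slice <- spec$ref_slice
  is_sr <- spec$stc_method == "shifted_regressor"
  motion <- NULL
  x <- scan

  if (is_sr) {
    ## LPF before MC, never a temporal shift
    x <- apply_stc(x, "shifted_regressor", fspec)
    if (spec$mc != "none") {
      mc <- realign_series(x)
      x <- mc$scan; motion <- mc$motion
    }
  } else if (spec$mc == "before_stc") {
    mc <- mc_cache %||% realign_series(x)
    x <- mc$scan; motion <- mc$motion
    x <- apply_stc(x, spec$stc_method, fspec)
  } else if (spec$mc == "after_stc") {
    x <- apply_stc(x, spec$stc_method, fspec)
    mc <- realign_series(x)
    x <- mc$scan; motion <- mc$motion
  } else {
    x <- apply_stc(x, spec$stc_method, fspec)
    if (spec$mpr) {
      mc <- realign_series(x, estimate_only = TRUE)
      motion <- mc$motion
    }
  }
  if (spec$smoothing_fwhm_mm > 0)
    x <- gaussian_smooth(x, spec$smoothing_fwhm_mm)

  nuis <- if (spec$mpr && !is.null(motion)) motion_nuisance(motion) else NULL
  slice_idx <- if (!is.null(ref_set)) ref_set$source_slice
  else pick_high_delay_slice(roi_mask, x$scheme, k)
  maps <- glm_maps_slicewise(x, stim, hrf, shifted_regressors = is_sr,
                             nuisance = nuis, prewhiten = spec$prewhiten,
                             slices = if (full_maps) NULL else slice_idx)
  own_set <- select_top_voxels(maps$t, roi_mask, slice_idx, k)
  eval_set <- ref_set %||% own_set

  z_vox <- maps$z[eval_set$index]
  dice <- dice_overlap(own_set, eval_set)

  ## FIR HRF at the evaluated voxels, against the TR-sampled true HRF
  coords <- eval_set$coords
  series <- sapply(seq_len(nrow(coords)), function(i)
    x$data[coords[i, 1], coords[i, 2], coords[i, 3], ])
  fir <- fir_deconvolve(series, stim, x$tr_s, fir_window_s)
  truth <- approx(hrf$times_s, hrf$kernel, xout = fir$lags_s, rule = 2)$y
  sse <- apply(as.matrix(fir$hrf), 2, hrf_sse, truth = truth)

  list(mean_z = mean(z_vox), z_voxels = z_vox, dice = dice,
       sse = sse, mean_sse = mean(sse), maps = maps, own_set = own_set,
       motion = motion, spec = spec)
}

#' Slicewise GLM statistic maps
#'
#' Fits the voxelwise GLM slice by slice, optionally with the per-slice
#' shifted regressor (the shifted-regressor method's design), nuisance
#' columns, and ARMA(1,1) prewhitening (whitening parameters pooled per
#' slice).
#'
#' @param scan An [fmri4d()] scan.
#' @param stim,hrf Stimulus train and HRF model for the task regressor.
#' @param shifted_regressors Shift the regressor by each slice's
#'   acquisition delay.
#' @param nuisance Optional nuisance matrix (volume rate).
#' @param prewhiten Apply ARMA(1,1) prewhitening per slice.
#' @param slices Slice indices to fit (default: all); unfitted slices stay
#'   `NA` in the returned maps.
#' @return List of 3-D arrays `z` and `t`.
#' @export
glm_maps_slicewise <- function(scan, stim, hrf, shifted_regressors = FALSE,
                               nuisance = NULL, prewhiten = FALSE,
                               slices = NULL) {
  V <- n_vols(scan)
  d <- dim(scan$data)
  delays <- slice_delays(scan$scheme)
  zmap <- tmap <- array(NA_real_, d[1:3])
  reg0 <- build_task_regressor(stim, hrf, scan$tr_s, V)
  if (is.null(slices)) slices <- seq_len(d[3])
  for (kk in slices) {
    reg <- if (shifted_regressors && delays[kk] != 0)
      build_task_regressor(stim, hrf, scan$tr_s, V, shift_s = delays[kk])
    else reg0
    dm <- design_matrix(reg, nuisance)
    Y <- t(matrix(scan$data[, , kk, ], nrow = prod(d[1:2])))
    if (prewhiten) {
      pw <- prewhiten_arma11(Y, unclass(dm))
      Y <- pw$Y
      dm <- structure(pw$X, task_col = attr(dm, "task_col"),
                      class = class(dm))
    }
    f <- fit_glm(Y, dm)
    zmap[, , kk] <- f$z
    tmap[, , kk] <- f$t
  }
  list(z = zmap, t = tmap)
}

#' Shifted-regressor reference run
#'
#' Runs the unsmoothed shifted-regressor pipeline (Kaiser low-pass, then
#' motion correction when requested, per-slice shifted regressors) and
#' selects the top-k voxels on the high-delay slice. This set anchors all
#' other pipelines' evaluation.
#'
#' @inheritParams run_pipeline
#' @param mc Apply motion correction inside the reference run.
#' @param slice_index Optional explicit slice; default: the highest-delay
#'   slice holding at least `k` ROI voxels.
#' @return List with `set` (the [select_top_voxels()] reference set),
#'   `result` (the full [run_pipeline()] output), `slice_index`.
#' @export
sr_reference <- function(scan, stim, hrf, roi_mask, k = 20L,
                         fspec = filter_spec(), mc = TRUE,
                         slice_index = NULL) {
  spec <- pipeline_spec("shifted_regressor",
                        mc = if (mc) "before_stc" else "none")
  res <- run_pipeline(scan, spec, stim, hrf, roi_mask, ref_set = NULL,
                      fspec = fspec, k = k)
  set <- if (is.null(slice_index)) res$own_set
  else select_top_voxels(res$maps$t, roi_mask, slice_index, k)
  list(set = set, result = res, slice_index = set$source_slice)
}

#' Simulate one study scan
#'
#' Convenience wrapper tying the simulator pieces together: phantom,
#' per-ROI stimulus trains and BOLD series, a motion trace in the
#' requested bin, and the rendered scan.
#'
#' @param shape Grid size, e.g. `c(32, 32, 37)`.
#' @param tr_s Repetition time (default 2 s).
#' @param interleave Interleave step (default 6).
#' @param motion_level `"none"`, `"low"`, `"medium"`, or `"high"`.
#' @param duration_s Scan length (default 600 s).
#' @param seed Integer seed; all randomness derives from it.
#' @param noise A [noise_spec()].
#' @param voxel_size_mm Voxel size (default `c(2, 2, 3)`).
#' @param n_events Events per ROI stimulus train (default 20).
#' @return List with `scan`, `phantom`, `stim` (the analysed ROI's train),
#'   `stims` (all trains), `hrf`, `trace`, `scheme`.
#' @export
simulate_scan <- function(shape = c(32L, 32L, 20L), tr_s = 2,
                          interleave = 6L,
                          motion_level = c("low", "medium", "high", "none"),
                          duration_s = 600, seed = 1L,
                          noise = noise_spec(),
                          voxel_size_mm = c(2, 2, 3), n_events = 20L) {
  motion_level <- match.arg(motion_level)
  scheme <- build_scheme(tr_s, shape[3], interleave)
  phantom <- build_phantom(shape, voxel_size_mm, seed = seed)
  hrf <- canonical_hrf(dt_s = 0.05)
  rate <- max(20, 2 * shape[3] / tr_s)
  rois <- names(phantom$roi_masks)
  stims <- lapply(seq_along(rois), function(i)
    generate_stimulus(n_events, duration_s, seed = seed * 131L + i))
  names(stims) <- rois
  roi_bold <- lapply(stims, function(s) simulate_bold(s, hrf, rate))
  n_v <- round(duration_s / tr_s)
  trace <- generate_motion_trace(motion_level, n_v, tr_s, seed = seed + 7L)
  scan <- render_scan(phantom, roi_bold, trace, scheme, noise,
                      seed = seed + 13L)
  list(scan = scan, phantom = phantom, stim = stims$tall_cortex,
       stims = stims, hrf = hrf, trace = trace, scheme = scheme)
}

#' Run a full experiment grid
#'
#' Enumerates motion levels x interleaves x realizations, simulates each
#' scan, runs the requested STC method / MC placement pipelines, and
#' collates a tidy table of mean Fisher z, dice overlap against the
#' shifted-regressor reference, and mean HRF SSE per cell, with the
#' paired one-tailed test against the `"after_stc"` ("Before MC") row of
#' each method/motion/interleave block.
#'
#' @param motion_levels,interleaves Character/integer vectors of grid axes.
#' @param n_realizations Scans per cell.
#' @param shape,tr_s,duration_s Scan geometry.
#' @param methods STC methods to compare.
#' @param mc_options MC placements to compare.
#' @param seed Base seed; realization `i` of each cell derives from it.
#' @param noise A [noise_spec()].
#' @param n_events Events per stimulus train (default 20).
#' @param mpr Apply motion parameter residualization in every pipeline.
#' @param k Top-voxel count.
#' @return List with `table` (data.frame, one row per cell) and
#'   `manifest` (data.frame of simulated scans).
#' @export
run_experiment_grid <- function(motion_levels = c("low", "medium", "high"),
                                interleaves = c(1L, 2L, 6L),
                                n_realizations = 5L,
                                shape = c(32L, 32L, 20L), tr_s = 2,
                                duration_s = 300,
                                methods = c("filtershift", "sinc", "fourier",
                                            "none"),
                                mc_options = c("before_stc", "after_stc",
                                               "none"),
                                seed = 1L, noise = noise_spec(),
                                mpr = FALSE, k = 20L, n_events = 20L) {
  rows <- list()
  manifest <- list()
  cell_z <- list()
  for (ml in motion_levels) for (il in interleaves) {
    per_real <- list()
    for (i in seq_len(n_realizations)) {
      sseed <- seed + 1000L * i +
        17L * match(ml, c("none", "low", "medium", "high")) + il
      sim <- simulate_scan(shape, tr_s, il, ml, duration_s, seed = sseed,
                           noise = noise, n_events = n_events)
      manifest[[length(manifest) + 1L]] <-
        data.frame(motion = ml, interleave = il, realization = i,
                   seed = sseed, mfwd = mean_fwd(sim$trace))
      roi <- sim$phantom$roi_masks$tall_cortex
      ref <- sr_reference(sim$scan, sim$stim, sim$hrf, roi, k = k,
                          mc = ml != "none")
      mc_cache <- if ("before_stc" %in% mc_options)
        realign_series(sim$scan) else NULL
      res_real <- list()
      for (m in methods) for (mc in mc_options) {
        if (m == "none" && mc == "after_stc") next  # identical to before_stc
        sp <- pipeline_spec(m, mc, mpr = mpr)
        res <- run_pipeline(sim$scan, sp, sim$stim, sim$hrf, roi,
                            ref_set = ref$set, mc_cache = mc_cache, k = k)
        res_real[[paste(m, mc, sep = "|")]] <-
          list(z = res$z_voxels, dice = res$dice, sse = res$sse)
      }
      per_real[[i]] <- res_real
    }
    for (key in names(per_real[[1]])) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      z_all <- unlist(lapply(per_real, function(r) r[[key]]$z))
      base_key <- paste(parts[1], "after_stc", sep = "|")
      p_val <- if (base_key %in% names(per_real[[1]]) && key != base_key) {
        z_base <- unlist(lapply(per_real, function(r) r[[base_key]]$z))
        paired_one_tailed_t(z_all, z_base)$p
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        motion = ml, interleave = il, method = parts[1], mc = parts[2],
        mean_z = mean(z_all), sd_z = sd(z_all),
        mean_dice = mean(sapply(per_real, function(r) r[[key]]$dice)),
        mean_sse = mean(unlist(lapply(per_real, function(r) r[[key]]$sse))),
        p_vs_before_mc = p_val, n_voxels = length(z_all))
      cell_z[[paste(ml, il, key)]] <- z_all
    }
  }
  list(table = do.call(rbind, rows), manifest = do.call(rbind, manifest),
       z_values = cell_z)
}
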