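#' Noise specification for the simulator
#'
#' Physiological noise is modelled as single sinusoids at the cardiac and
#' respiratory frequencies (1.23 Hz and 0.25 Hz by default), each with an
#' amplitude expressed as a fraction of the local voxel mean. Thermal noise
#' is white Gaussian noise whose power is `thermal_energy_frac` times the
#' BOLD signal power (5% by default). The BOLD signal itself is scaled so
#' its standard deviation is `signal_pct` percent of the voxel mean (4% by
#' default, comparable to a robust visual-cortex response).
#'
#' @param cardiac_hz,resp_hz Physiological frequencies in Hz.
#' @param cardiac_amp_frac,resp_amp_frac Sinusoid amplitudes as fractions
#'   of the voxel mean intensity.
#' @param thermal_energy_frac White-noise power as a fraction of BOLD
#'   signal power.
#' @param signal_pct BOLD standard deviation as a percent of voxel mean.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_hz = 1.23, resp_hz = 0.25,
                       cardiac_amp_frac = 0.01, resp_amp_frac = 0.01,
                       thermal_energy_frac = 0.05, signal_pct = 4) {
  check_num(cardiac_hz, "cardiac_hz", positive = TRUE)
  check_num(resp_hz, "resp_hz", positive = TRUE)
  check_num(cardiac_amp_frac, "cardiac_amp_frac", nonneg = TRUE)
  check_num(resp_amp_frac, "resp_amp_frac", nonneg = TRUE)
  check_num(thermal_energy_frac, "thermal_energy_frac", nonneg = TRUE)
  check_num(signal_pct, "signal_pct", nonneg = TRUE)
  structure(list(cardiac_hz = cardiac_hz, resp_hz = resp_hz,
                 cardiac_amp_frac = cardiac_amp_frac,
                 resp_amp_frac = resp_amp_frac,
                 thermal_energy_frac = thermal_energy_frac,
                 signal_pct = signal_pct),
            class = "noise_spec")
}

#' Render a simulated 4-D fMRI scan
#'
#' Couples head motion with slice acquisition timing at the per-slice
#' level. For each volume `v` and slice `k`, acquired at time
#' `t = (v-1) TR + slice_times[k]`: the instantaneous brain volume is the
#' phantom baseline plus, for every ROI with an assigned BOLD series, that
#' series evaluated at `t` (centred, unit variance, scaled per voxel to
#' `signal_pct`% of the voxel mean); the volume is rigidly transformed by
#' the spline-upsampled motion at `t`; and plane `k` of the transformed
#' volume is recorded. Physiological sinusoids (sampled at each slice's
#' own acquisition times, so they alias exactly as acquisition would) and
#' white thermal noise are then added.
#'
#' @param phantom A [build_phantom()] phantom.
#' @param roi_bold Named list mapping ROI names to high-rate BOLD series
#'   from [simulate_bold()]. ROIs not listed carry no signal.
#' @param trace Per-volume [motion_trace()] with one sample per volume.
#' @param scheme An [build_scheme()] acquisition scheme.
#' @param noise A [noise_spec()].
#' @param seed Optional seed for the thermal noise.
#' @param interp_order Interpolation order for the rigid resampling
#'   (3 = cubic spline-like convolution, the default; 1 = trilinear).
#' @return An `fmri4d` scan with attribute fields `ground_truth` (a list
#'   with the scaled per-ROI series, the per-slice motion, and the clean
#'   per-slice BOLD samples) stored in `scan$ground_truth`.
#' @export
render_scan <- function(phantom, roi_bold, trace, scheme,
                        noise = noise_spec(), seed = NULL,
                        interp_order = 3L) {
  if (!inherits(phantom, "phantom")) stopf("phantom must be a phantom")
  if (!inherits(scheme, "acquisition_scheme")) stopf("scheme required")
  if (length(roi_bold) == 0 || is.null(names(roi_bold)))
    stopf("roi_bold must be a named list of BOLD series")
  bad <- setdiff(names(roi_bold), names(phantom$roi_masks))
  if (length(bad)) stopf("unknown ROI(s): %s", paste(bad, collapse = ", "))
  d3 <- phantom$shape
  if (d3[3] != scheme$n_slices)
    stopf("phantom has %d slices but scheme declares %d", d3[3], scheme$n_slices)
  rate <- roi_bold[[1]]$rate_hz
  if (rate < scheme$n_slices / scheme$tr_s)
    stopf("BOLD rate %.3g Hz below per-slice sampling rate %.3g Hz",
          rate, scheme$n_slices / scheme$tr_s)
  total_s <- length(roi_bold[[1]]$series) / rate
  V <- round(total_s / scheme$tr_s)
  if (length(trace$times_s) != V)
    stopf("trace has %d samples but the scan has %d volumes",
          length(trace$times_s), V)

  ## per-voxel BOLD amplitude maps, one column per signalled ROI
  nroi <- length(roi_bold)
  amps <- matrix(0, prod(d3), nroi)
  for (r in seq_len(nroi)) {
    m <- phantom$roi_masks[[names(roi_bold)[r]]]
    amps[as.vector(m), r] <-
      noise$signal_pct / 100 * phantom$mean_intensity[m]
  }

  ## slice sample times in temporal order within each volume
  st_sorted <- sort(scheme$slice_times_s)
  k_of_pos <- scheme$acquisition_order            # slice index per position
  sample_t <- as.vector(outer(st_sorted, (seq_len(V) - 1) * scheme$tr_s, `+`))
  slice_k0 <- rep(k_of_pos - 1L, times = V)       # 0-based slice per sample
  ns <- length(sample_t)

  ## centred, unit-variance BOLD value per sample per ROI
  bold_mat <- matrix(0, ns, nroi)
  truth_series <- vector("list", nroi)
  names(truth_series) <- names(roi_bold)
  for (r in seq_len(nroi)) {
    s <- roi_bold[[r]]$series
    s <- (s - mean(s)) / max(sd(s), 1e-12)
    truth_series[[r]] <- list(rate_hz = rate,
                              times_s = roi_bold[[r]]$times_s, series = s)
    bold_mat[, r] <- approx(roi_bold[[r]]$times_s, s, xout = sample_t,
                            rule = 2)$y
  }

  moving <- any(trace$translations_mm != 0) || any(trace$rotations_rad != 0)
  if (moving) {
    slice_trace <- upsample_trace(trace, scheme)
    Amats <- t(vapply(seq_len(ns), function(s) {
      tf <- rigid_transform(slice_trace$translations_mm[s, ],
                            slice_trace$rotations_rad[s, ])
      as.vector(pull_matrix(tf, d3, phantom$voxel_size_mm))
    }, numeric(12)))
  } else {
    slice_trace <- NULL
    A0 <- as.vector(pull_matrix(rigid_transform(), d3, phantom$voxel_size_mm))
    Amats <- matrix(rep(A0, each = ns), nrow = ns)
  }

  base_in <- phantom$mean_intensity
  amps_in <- amps
  if (interp_order == 3L) {
    ## order-3 sampling interpolates cubic B-spline coefficients
    base_in <- cpp_prefilter3(base_in)
    dim(base_in) <- d3
    for (r in seq_len(nroi)) {
      a3 <- array(amps[, r], dim = d3)
      amps_in[, r] <- as.vector(cpp_prefilter3(a3))
    }
  }
  roi_z <- t(vapply(names(roi_bold), function(nm) {
    zs <- which(apply(phantom$roi_masks[[nm]], 3, any))
    c(min(zs), max(zs)) - 1L
  }, integer(2)))
  planes <- cpp_render_planes(base_in, amps_in, bold_mat,
                              slice_k0, Amats, d3,
                              as.integer(interp_order), 0, roi_z)
  data <- array(0, dim = c(d3, V))
  vol_of <- rep(seq_len(V), each = scheme$n_slices)
  for (s in seq_len(ns))
    data[, , slice_k0[s] + 1L, vol_of[s]] <- planes[, s]

  ## physiological sinusoids, sampled per slice at its own acquisition times
  if (noise$cardiac_amp_frac > 0 || noise$resp_amp_frac > 0) {
    for (k in seq_len(scheme$n_slices)) {
      tk <- (seq_len(V) - 1) * scheme$tr_s + scheme$slice_times_s[k]
      phys <- noise$cardiac_amp_frac * sin(2 * pi * noise$cardiac_hz * tk) +
        noise$resp_amp_frac * sin(2 * pi * noise$resp_hz * tk)
      plane_mean <- phantom$mean_intensity[, , k]
      data[, , k, ] <- data[, , k, ] +
        outer(plane_mean, phys)
    }
  }

  ## thermal noise: power = thermal_energy_frac x BOLD signal power
  if (noise$thermal_energy_frac > 0) {
    sdmap <- sqrt(noise$thermal_energy_frac) * noise$signal_pct / 100 *
      phantom$mean_intensity
    data <- data + with_seed(seed, {
      array(rnorm(length(data)), dim = dim(data)) *
        as.vector(sdmap)
    })
  }

  scan <- fmri4d(data, phantom$voxel_size_mm, scheme,
                 provenance = sprintf("render(interleave=%d, seed=%s)",
                                      scheme$interleave_step,
                                      deparse(seed)))
  scan$ground_truth <- list(roi_series = truth_series,
                            motion = trace, slice_motion = slice_trace,
                            bold_samples = bold_mat, sample_times = sample_t,
                            slice_of_sample = slice_k0 + 1L)
  scan
}
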