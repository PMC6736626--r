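#' FilterShift slice timing correction
#'
#' Corrects each slice's voxel time series by the polyphase realization of
#' zero-stuff upsampling, Kaiser-windowed sinc low-pass filtering, and
#' resampling at the grid shifted backward by the slice's acquisition
#' delay. With the default upsample factor equal to the slice count, every
#' slice delay lands exactly on the upsampled grid. The reference slice is
#' altered only by the low-pass filter itself.
#'
#' @param scan An [fmri4d()] scan carrying an acquisition scheme.
#' @param spec A [filter_spec()]; a `NULL` `upsample_factor` (the default)
#'   uses the scan's slice count.
#' @return The corrected `fmri4d` scan.
#' @export
filtershift <- function(scan, spec = filter_spec()) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  fs <- 1 / scan$tr_s
  L <- spec$upsample_factor %||% scan$scheme$n_slices
  spec$upsample_factor <- L
  h <- design_kaiser_taps(fs * L, spec)
  delays <- slice_delays(scan$scheme)
  shifts <- delays / scan$tr_s * L           # in upsample ticks
  if (max(abs(shifts - round(shifts))) > 1e-6)
    shifts <- round(shifts)                  # snap to the upsampled grid
  data <- map_slices(scan, function(m, k) {
    ## correlation kernel c[o] = L h[oL + s_k]: mass at offset -delay
    g <- polyphase_branch(h, L, -round(shifts[k]))
    apply_fir(m, g, spec$padding)
  })
  with_data(scan, data, sprintf("filtershift(cutoff=%.3g)", spec$cutoff_hz))
}

#' Hanning-windowed sinc slice timing correction
#'
#' Low-order interpolation kernel: each voxel series on slice `k` is
#' shifted backward by its acquisition delay using a Hanning-windowed sinc
#' truncated to `half_width_taps` samples either side, with edge samples
#' replicated. Zero shift is an exact identity.
#'
#' @param scan An [fmri4d()] scan.
#' @param half_width_taps Kernel half width in samples (default 3).
#' @return The corrected `fmri4d` scan.
#' @export
hanning_sinc_stc <- function(scan, half_width_taps = 3L) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  hw <- check_count(half_width_taps, "half_width_taps")
  if (n_vols(scan) < 2L * hw + 2L)
    stopf("fewer time points than the interpolation kernel support")
  delays <- slice_delays(scan$scheme) / scan$tr_s  # in samples
  data <- map_slices(scan, function(m, k) {
    shift_series_hsinc(m, delays[k], hw)
  })
  with_data(scan, data, sprintf("hanning_sinc(hw=%d)", hw))
}

## Fractional delay of a (time x voxels) matrix: y[n] = x(n - delta),
## Hanning-windowed sinc of half width hw, boundary replication.
shift_series_hsinc <- function(mat, delta, hw) {
  n <- nrow(mat)
  if (delta == 0) return(mat)
  out <- matrix(0, n, ncol(mat))
  u <- seq_len(n) - delta              # source positions
  j0 <- floor(u)
  w_total <- numeric(n)
  for (o in (-hw):(hw + 1L)) {
    j <- j0 + o
    d <- u - j
    w <- sinc(d) * 0.5 * (1 + cos(pi * d / (hw + 1)))
    w[abs(d) > hw + 1] <- 0
    jc <- pmin(pmax(j, 1L), n)
    out <- out + w * mat[jc, , drop = FALSE]
    w_total <- w_total + w
  }
  out / w_total
}

#' Fourier phase-shift slice timing correction
#'
#' Shifts each voxel series by multiplying its discrete Fourier transform
#' with a linear phase `exp(-i 2 pi f delta)` and inverse transforming;
#' the Nyquist bin is kept real. Exact for sinusoids below Nyquist; the
#' series is treated as periodic (no detrending), so a linear trend leaks
#' as with any circular method.
#'
#' @param scan An [fmri4d()] scan.
#' @return The corrected `fmri4d` scan.
#' @export
fourier_phase_stc <- function(scan) {
  if (!inherits(scan, "fmri4d")) stopf("scan must be an fmri4d")
  if (!all(is.finite(scan$data))) stopf("scan contains non-finite values")
  delays <- slice_delays(scan$scheme) / scan$tr_s  # in samples
  n <- n_vols(scan)
  freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
  data <- map_slices(scan, function(m, k) {
    if (delays[k] == 0) return(m)
    ph <- exp(-2i * pi * freqs * delays[k])
    if (n %% 2L == 0L) ph[n / 2 + 1L] <- cos(pi * delays[k])  # Nyquist real
    Re(stats::mvfft(stats::mvfft(m) * ph, inverse = TRUE)) / n
  })
  with_data(scan, data, "fourier_phase")
}
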