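#' Kaiser low-pass filter specification
#'
#' Design parameters for the Kaiser-windowed sinc low-pass filter shared
#' by the FilterShift slice timing correction and the shifted-regressor
#' gold standard. The filter is designed at the upsampled rate
#' `fs * upsample_factor`; the number of taps and the Kaiser beta follow
#' the standard Kaiser design formulas for the requested stopband
#' attenuation and transition width unless `n_taps` is given explicitly.
#'
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.21, the highest
#'   frequency with appreciable power in the canonical HRF).
#' @param upsample_factor Integer zero-stuffing factor (>= 1). `NULL`
#'   (default) means "use the scan's slice count", which places every
#'   slice shift exactly on the upsampled grid.
#' @param stopband_atten_db Stopband attenuation in dB (default 60).
#' @param transition_hz Transition bandwidth in Hz (default 0.08).
#' @param n_taps Optional odd filter length override (at the upsampled
#'   rate).
#' @param padding Edge handling: `"circular"` (default), `"reflect"`, or
#'   `"zero"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 0.21, upsample_factor = NULL,
                        stopband_atten_db = 60, transition_hz = 0.08,
                        n_taps = NULL,
                        padding = c("circular", "reflect", "zero")) {
  check_num(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (!is.null(upsample_factor))
    upsample_factor <- check_count(upsample_factor, "upsample_factor")
  check_num(stopband_atten_db, "stopband_atten_db", positive = TRUE)
  check_num(transition_hz, "transition_hz", positive = TRUE)
  if (!is.null(n_taps)) {
    n_taps <- check_count(n_taps, "n_taps", min = 3L)
    if (n_taps %% 2L == 0L) stopf("n_taps must be odd")
  }
  padding <- match.arg(padding)
  structure(list(cutoff_hz = cutoff_hz, upsample_factor = upsample_factor,
                 stopband_atten_db = stopband_atten_db,
                 transition_hz = transition_hz, n_taps = n_taps,
                 padding = padding),
            class = "filter_spec")
}

## Kaiser design: beta and tap count from attenuation/transition width.
kaiser_beta <- function(A) {
  if (A > 50) 0.1102 * (A - 8.7)
  else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  else 0
}

## Prototype Kaiser-windowed sinc taps at rate fs_up, unit DC gain.
design_kaiser_taps <- function(fs_up, spec) {
  nyq <- fs_up / 2
  if (spec$cutoff_hz >= nyq)
    stopf("cutoff %.3g Hz is not below the (upsampled) Nyquist %.3g Hz",
          spec$cutoff_hz, nyq)
  A <- spec$stopband_atten_db
  beta <- kaiser_beta(A)
  if (is.null(spec$n_taps)) {
    dw <- 2 * pi * spec$transition_hz / fs_up
    N <- ceiling((A - 7.95) / (2.285 * dw)) + 1L
    if (N %% 2L == 0L) N <- N + 1L
  } else N <- spec$n_taps
  M <- (N - 1L) / 2L
  n <- seq(-M, M)
  fc <- spec$cutoff_hz / fs_up          # normalized cutoff (cycles/sample)
  h <- 2 * fc * sinc(2 * fc * n) * as.numeric(signal::kaiser(N, beta))
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## Pad a series matrix (time x voxels) at both ends by `m` samples.
pad_series <- function(mat, m, padding) {
  n <- nrow(mat)
  if (m >= n && padding != "circular")
    stopf("series of length %d too short for a %d-tap kernel", n, 2 * m + 1)
  idx_pre <- switch(padding,
                    circular = ((n - m):(n - 1)) %% n + 1L,
                    reflect = pmin(n, m:1 + 1L),
                    zero = NULL)
  idx_post <- switch(padding,
                     circular = (0:(m - 1)) %% n + 1L,
                     reflect = pmax(1L, n - 1L - 0:(m - 1)),
                     zero = NULL)
  if (padding == "zero") {
    z <- matrix(0, m, ncol(mat))
    rbind(z, mat, z)
  } else {
    rbind(mat[idx_pre, , drop = FALSE], mat, mat[idx_post, , drop = FALSE])
  }
}

## Apply a symmetric-support kernel g (offsets -M..M) along time to a
## (time x voxels) matrix with the requested padding; zero-phase output.
apply_fir <- function(mat, g, padding) {
  M <- (length(g) - 1L) / 2L
  n <- nrow(mat)
  if (padding == "circular" && n <= M)
    stopf("series of length %d too short for kernel half-width %d", n, M)
  p <- pad_series(mat, M, padding)
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(g)) {
    if (g[j] == 0) next
    out <- out + g[j] * p[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out
}

## Polyphase branch of the upsampled prototype for an integer sub-sample
## shift s (in upsample ticks): g[i] = L * h[i*L - s], normalized to unit
## sum so constants are preserved exactly.
polyphase_branch <- function(h, L, s) {
  N <- length(h)
  M <- (N - 1L) / 2L
  imax <- ceiling((M + abs(s)) / L)
  i <- seq(-imax, imax)
  pos <- i * L - s + M + 1L
  g <- ifelse(pos >= 1L & pos <= N, h[pmin(pmax(pos, 1L), N)], 0)
  g * L / sum(g * L)
}

#' Zero-phase Kaiser low-pass filtering
#'
#' Filters each column of a series (or a single vector) with the
#' Kaiser-windowed sinc low-pass used by FilterShift, realized as the
#' zero-shift polyphase branch of the upsampled design, so that filtering
#' alone and FilterShift with zero delay coincide exactly. DC gain is
#' exactly 1.
#'
#' @param series Numeric vector or (time x voxels) matrix.
#' @param fs_hz Sampling rate of the series in Hz.
#' @param spec A [filter_spec()]. A `NULL` `upsample_factor` defaults to 1
#'   here.
#' @return Filtered series of identical shape.
#' @export
kaiser_lowpass <- function(series, fs_hz, spec = filter_spec()) {
  check_num(fs_hz, "fs_hz", positive = TRUE)
  vec <- is.null(dim(series))
  mat <- if (vec) matrix(series, ncol = 1) else series
  L <- spec$upsample_factor %||% 1L
  h <- design_kaiser_taps(fs_hz * L, spec)
  g <- polyphase_branch(h, L, 0L)
  out <- apply_fir(mat, g, spec$padding)
  if (vec) drop(out) else out
}
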