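#' Generate a jittered event-related stimulus train
#'
#' Draws `n_events` non-overlapping boxcar events with onsets jittered
#' uniformly over the feasible range and durations drawn uniformly from
#' `duration_range_s`. Events are separated by at least `min_gap_s`.
#'
#' @param n_events Number of boxcar events.
#' @param total_s Scan duration in seconds.
#' @param duration_range_s Length-2 numeric, uniform range of event
#'   durations in seconds.
#' @param min_gap_s Minimum inter-event gap in seconds.
#' @param seed Optional integer seed; identical seeds give identical trains.
#' @return An object of class `stimulus_train` with fields `onsets_s`,
#'   `durations_s`, `total_duration_s`.
#' @export
generate_stimulus <- function(n_events = 20L, total_s = 600,
                              duration_range_s = c(2, 8), min_gap_s = 2,
                              seed = NULL) {
  n_events <- check_count(n_events, "n_events")
  check_num(total_s, "total_s", positive = TRUE)
  if (length(duration_range_s) != 2L || any(duration_range_s < 0) ||
      duration_range_s[2] < duration_range_s[1])
    stopf("duration_range_s must be an increasing non-negative pair")
  check_num(min_gap_s, "min_gap_s", nonneg = TRUE)
  if (n_events * (duration_range_s[2] + min_gap_s) > total_s)
    stopf("cannot pack %d events of up to %.3g s (+%.3g s gap) into %.3g s",
          n_events, duration_range_s[2], min_gap_s, total_s)
  with_seed(seed, {
    durations <- runif(n_events, duration_range_s[1], duration_range_s[2])
    ## Jitter onsets by distributing the slack left over after all
    ## durations and minimum gaps among the n_events + 1 spacings.
    slack <- total_s - sum(durations) - (n_events - 1) * min_gap_s
    sp <- runif(n_events + 1L)
    sp <- sp / sum(sp) * slack
    onsets <- cumsum(c(sp[1], durations[-n_events] + min_gap_s +
                         sp[seq_len(n_events - 1L) + 1L]))
    if (n_events == 1L) onsets <- sp[1]
    structure(list(onsets_s = onsets, durations_s = durations,
                   total_duration_s = total_s),
              class = "stimulus_train")
  })
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d events over %.4g s\n",
              length(x$onsets_s), x$total_duration_s))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Samples the standard difference-of-gammas HRF: a gamma-density main
#' response minus a scaled gamma-density undershoot,
#' `h(t) = dgamma(t, a1, 1/d1) - ratio * dgamma(t, a2, 1/d2)` with shape
#' parameters chosen so the peaks fall at `peak_delay_s` and
#' `undershoot_delay_s`. The kernel is normalized to unit peak height.
#'
#' @param dt_s Sampling interval of the kernel in seconds.
#' @param peak_delay_s Time-to-peak of the main response (default 6 s).
#' @param undershoot_delay_s Time-to-trough of the undershoot (default 16 s).
#' @param dispersion_s,u_dispersion_s Dispersions of the two gammas.
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param length_s Kernel duration (default 32 s).
#' @return An object of class `hrf_model` with fields `dt_s`, `times_s`,
#'   `kernel`, and the shape parameters.
#' @export
canonical_hrf <- function(dt_s = 0.1, peak_delay_s = 6,
                          undershoot_delay_s = 16, dispersion_s = 1,
                          u_dispersion_s = 1, undershoot_ratio = 1 / 6,
                          length_s = 32) {
  check_num(dt_s, "dt_s", positive = TRUE)
  check_num(dispersion_s, "dispersion_s", positive = TRUE)
  check_num(u_dispersion_s, "u_dispersion_s", positive = TRUE)
  check_num(peak_delay_s, "peak_delay_s", positive = TRUE)
  t <- seq(0, length_s, by = dt_s)
  ## standard double-gamma parameterization: shape = delay / dispersion,
  ## scale = dispersion (the density mode sits just below the delay)
  k1 <- peak_delay_s / dispersion_s
  k2 <- undershoot_delay_s / u_dispersion_s
  h <- stats::dgamma(t, shape = k1, scale = dispersion_s) -
    undershoot_ratio * stats::dgamma(t, shape = k2, scale = u_dispersion_s)
  h <- h / max(h)
  structure(list(dt_s = dt_s, times_s = t, kernel = h,
                 peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 dispersion_s = dispersion_s, u_dispersion_s = u_dispersion_s,
                 undershoot_ratio = undershoot_ratio, length_s = length_s),
            class = "hrf_model")
}

#' @export
print.hrf_model <- function(x, ...) {
  cat(sprintf("<hrf_model> double gamma, peak %.3g s, %.3g s @ dt %.3g s\n",
              x$peak_delay_s, x$length_s, x$dt_s))
  invisible(x)
}

## Continuous boxcar indicator sampled at arbitrary times.
sample_boxcar <- function(stim, times_s) {
  out <- numeric(length(times_s))
  for (i in seq_along(stim$onsets_s)) {
    out <- out + as.numeric(times_s >= stim$onsets_s[i] &
                              times_s < stim$onsets_s[i] + stim$durations_s[i])
  }
  pmin(out, 1)
}

#' Simulate a high-rate BOLD time course
#'
#' Convolves the boxcar stimulus train with the HRF kernel on a dense time
#' grid at `rate_hz`. The result is the noise-free hemodynamic time course
#' from which per-slice samples are later drawn.
#'
#' @param stim A [generate_stimulus()] train.
#' @param hrf A [canonical_hrf()] model.
#' @param rate_hz Sampling rate of the output series; must be at least the
#'   per-slice sampling rate `n_slices / tr_s` of the target scheme.
#' @param min_rate_hz Optional lower bound checked against `rate_hz`.
#' @return A list with `rate_hz`, `times_s`, and `series` (length
#'   `total_s * rate_hz`).
#' @export
simulate_bold <- function(stim, hrf, rate_hz, min_rate_hz = NULL) {
  check_num(rate_hz, "rate_hz", positive = TRUE)
  if (!is.null(min_rate_hz) && rate_hz < min_rate_hz)
    stopf("rate_hz (%.3g) below the per-slice sampling rate (%.3g)",
          rate_hz, min_rate_hz)
  dt <- 1 / rate_hz
  n <- round(stim$total_duration_s * rate_hz)
  times <- (seq_len(n) - 1) * dt
  box <- sample_boxcar(stim, times)
  ## resample the HRF kernel onto the dense grid
  kt <- seq(0, hrf$length_s, by = dt)
  k <- approx(hrf$times_s, hrf$kernel, xout = kt, rule = 2)$y
  y <- convolve_full(box, k) * dt
  list(rate_hz = rate_hz, times_s = times, series = y[seq_len(n)])
}

## Linear "full" convolution truncated to length(x) + length(k) - 1.
convolve_full <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nf <- stats::nextn(n, 2)
  xr <- c(x, numeric(nf - length(x)))
  kr <- c(k, numeric(nf - length(k)))
  re <- Re(fft(fft(xr) * fft(kr), inverse = TRUE)) / nf
  re[seq_len(n)]
}

## Sample a high-rate series at arbitrary times (linear interpolation).
sample_series <- function(bold, at_s) {
  approx(bold$times_s, bold$series, xout = at_s, rule = 2)$y
}
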