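#' Construct a motion trace
#'
#' A motion trace holds 6-parameter rigid head motion (3 translations in
#' mm, 3 rotations in rad) sampled either once per volume or once per
#' slice acquisition.
#'
#' @param times_s Sample times in seconds.
#' @param translations_mm n x 3 matrix of translations.
#' @param rotations_rad n x 3 matrix of rotations.
#' @param rate `"volume"` or `"slice"`.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(times_s, translations_mm, rotations_rad,
                         rate = c("volume", "slice")) {
  rate <- match.arg(rate)
  translations_mm <- as.matrix(translations_mm)
  rotations_rad <- as.matrix(rotations_rad)
  n <- length(times_s)
  if (nrow(translations_mm) != n || nrow(rotations_rad) != n ||
      ncol(translations_mm) != 3L || ncol(rotations_rad) != 3L)
    stopf("translations and rotations must be n x 3 with n = length(times_s)")
  structure(list(times_s = as.numeric(times_s),
                 translations_mm = translations_mm,
                 rotations_rad = rotations_rad, rate = rate),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d samples at %s rate, max |t| %.3g mm, max |r| %.3g rad\n",
              length(x$times_s), x$rate, max(abs(x$translations_mm)),
              max(abs(x$rotations_rad))))
  invisible(x)
}

#' Mean framewise displacement of a per-volume motion trace
#'
#' Framewise displacement at frame `i` is the sum of absolute backward
#' differences of the three translations plus `head_radius_mm` times the
#' sum of absolute backward differences of the three rotations; the mean
#' over frames 2..n is returned.
#'
#' @param trace A per-volume [motion_trace()].
#' @param head_radius_mm Head radius converting rotations to arc length
#'   (default 50 mm).
#' @return Mean framewise displacement in mm.
#' @export
mean_fwd <- function(trace, head_radius_mm = 50) {
  if (!inherits(trace, "motion_trace")) stopf("trace must be a motion_trace")
  if (trace$rate != "volume") stopf("mean_fwd expects a per-volume trace")
  n <- length(trace$times_s)
  if (n < 2L) stopf("mean_fwd needs at least 2 samples")
  dt <- abs(diff(trace$translations_mm))
  dr <- abs(diff(trace$rotations_rad))
  mean(rowSums(dt) + head_radius_mm * rowSums(dr))
}

#' Generate a smooth random motion trace in a target mFWD bin
#'
#' Draws a smooth per-volume trace as a sum of low-frequency (< 0.2 Hz)
#' random sinusoids plus a slow random walk for each of the six rigid
#' parameters, then rescales it so the mean framewise displacement hits the
#' centre of the requested bin exactly (mFWD is positively homogeneous in
#' the trace amplitude, so a single rescale is exact). Bins follow the
#' low / medium / high convention: mFWD < 0.1 mm, 0.25-0.4 mm, and
#' 0.6-0.7 mm.
#'
#' @param level `"low"`, `"medium"`, `"high"`, or `"none"` (all-zero trace).
#' @param n_vols Number of volumes.
#' @param tr_s Repetition time in seconds.
#' @param seed Optional integer seed.
#' @param target_mfwd_mm Optional explicit target overriding `level`.
#' @param head_radius_mm Head radius used in the framewise displacement.
#' @return A per-volume [motion_trace()].
#' @export
generate_motion_trace <- function(level = c("low", "medium", "high", "none"),
                                  n_vols, tr_s, seed = NULL,
                                  target_mfwd_mm = NULL,
                                  head_radius_mm = 50) {
  level <- match.arg(level)
  n_vols <- check_count(n_vols, "n_vols", min = 2L)
  check_num(tr_s, "tr_s", positive = TRUE)
  times <- (seq_len(n_vols) - 1) * tr_s
  if (is.null(target_mfwd_mm))
    target_mfwd_mm <- switch(level, none = 0, low = 0.05,
                             medium = 0.325, high = 0.65)
  check_num(target_mfwd_mm, "target_mfwd_mm", nonneg = TRUE)
  if (target_mfwd_mm == 0)
    return(motion_trace(times, matrix(0, n_vols, 3), matrix(0, n_vols, 3)))
  with_seed(seed, {
    mk <- function() {
      ## slow drift (sinusoids below 0.2 Hz plus a random walk) and
      ## frame-to-frame jitter, mixed so each contributes about half the
      ## framewise displacement; because FD measures per-frame change, the
      ## accumulated drift range ends up several times the mFWD, as real
      ## head-motion traces show
      n_sin <- 6L
      f <- runif(n_sin, 0.005, 0.2)        # Hz, below the BOLD band edge
      a <- runif(n_sin) / sqrt(n_sin)
      ph <- runif(n_sin, 0, 2 * pi)
      s <- colSums(a * sin(outer(2 * pi * f, times) + ph)) +
        cumsum(rnorm(n_vols, sd = 0.15))
      s <- s / max(mean(abs(diff(s))), 1e-12)
      j <- rnorm(n_vols)
      j <- j / max(mean(abs(diff(j))), 1e-12)
      (s + j) / 2
    }
    tr <- sapply(1:3, function(i) mk())
    ## rotations drawn at a scale whose FD contribution (x head radius)
    ## is comparable to 1 mm of translation
    ro <- sapply(1:3, function(i) mk()) / head_radius_mm
    trace <- motion_trace(times, tr, ro)
    got <- mean_fwd(trace, head_radius_mm)
    sc <- target_mfwd_mm / got
    motion_trace(times, tr * sc, ro * sc)
  })
}

#' Upsample a per-volume trace to per-slice rate by spline interpolation
#'
#' Produces one rigid-parameter sample per slice acquisition: `n_slices`
#' samples per TR, at the slice acquisition times of `scheme`, using cubic
#' spline interpolation of each of the six parameter series.
#'
#' @param trace Per-volume [motion_trace()].
#' @param scheme An [build_scheme()] acquisition scheme.
#' @return A per-slice `motion_trace` of length `n_vols * n_slices`, in
#'   temporal (acquisition) order.
#' @export
upsample_trace <- function(trace, scheme) {
  if (trace$rate != "volume") stopf("expected a per-volume trace")
  n_vols <- length(trace$times_s)
  ## acquisition times of every slice sample, in temporal order
  tt <- as.vector(outer(sort(scheme$slice_times_s), trace$times_s, `+`))
  up <- function(y) spline(trace$times_s, y, xout = tt, method = "natural")$y
  motion_trace(tt,
               sapply(1:3, function(i) up(trace$translations_mm[, i])),
               sapply(1:3, function(i) up(trace$rotations_rad[, i])),
               rate = "slice")
}
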