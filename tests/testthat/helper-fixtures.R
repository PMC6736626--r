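## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

## mid-sized phantom used by the registration tests
reg_phantom <- function() fixture("reg_phantom", function()
  build_phantom(c(32L, 32L, 24L), c(2, 2, 3), seed = 1))

## small noiseless, motion-free scan
clean_sim <- function() fixture("clean_sim", function()
  simulate_scan(c(24L, 24L, 16L), tr_s = 2, interleave = 2,
                motion_level = "none", duration_s = 160, seed = 5,
                n_events = 8,
                noise = noise_spec(cardiac_amp_frac = 0, resp_amp_frac = 0,
                                   thermal_energy_frac = 0)))

## a multi-slice scan whose every slice holds the same band-limited signal
## sampled at that slice's own acquisition offset
bandlimited_scan <- function(freqs = c(0.05, 0.11, 0.17), n_slices = 12L,
                             tr_s = 2, n_vols = 150L, interleave = 2L) {
  sch <- build_scheme(tr_s, n_slices, interleave)
  sig <- function(t) {
    out <- 0
    for (i in seq_along(freqs))
      out <- out + sin(2 * pi * freqs[i] * t + i)
    out
  }
  dat <- array(0, c(2, 2, n_slices, n_vols))
  for (k in seq_len(n_slices)) {
    tt <- (seq_len(n_vols) - 1) * tr_s + sch$slice_times_s[k]
    dat[, , k, ] <- rep(sig(tt), each = 4)
  }
  list(scan = fmri4d(dat, c(2, 2, 3), sch), sig = sig, scheme = sch)
}

expect_transform_close <- function(est, t_mm, r_rad, tol_mm, tol_rad) {
  expect_lt(max(abs(est$translations_mm - t_mm)), tol_mm)
  expect_lt(max(abs(est$rotations_rad - r_rad)), tol_rad)
}
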