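#' Build a slice acquisition scheme
#'
#' Describes when each slice of an EPI volume is acquired within the TR.
#' Slices are acquired in interleaved groups: with an interleave step of
#' `s`, the scanner first acquires slices 1, 1+s, 1+2s, ..., then 2, 2+s,
#' ..., up to group start `s` (all indices 1-based, ascending within each
#' group). Step 1 is a sequential acquisition, step 2 the common even/odd
#' interleave, and step 6 the 6:1 ascending interleave used by Philips
#' scanners. Slice `k` acquired at position `p` (0-based) in that order has
#' acquisition delay `tr_s * p / n_slices` seconds from the start of the TR.
#'
#' Under this convention a 41-slice, step-6 scheme at TR 2 s acquires slice
#' 17 at 2*30/41 = 1.46 s, and a 37-slice, step-6 scheme acquires slice 18
#' at 2*33/37 = 1.78 s.
#'
#' @param tr_s Repetition time in seconds (> 0).
#' @param n_slices Number of slices (>= 1).
#' @param interleave_step Positive integer step; 1 = sequential.
#' @param ref_slice Slice index (1-based) whose acquisition time defines
#'   zero delay. Defaults to the first slice acquired.
#' @return An object of class `acquisition_scheme` with fields `tr_s`,
#'   `n_slices`, `interleave_step`, `acquisition_order` (permutation of
#'   `1:n_slices` in temporal order), `slice_times_s` (per-slice delay,
#'   indexed by slice), and `ref_slice`.
#' @examples
#' sch <- build_scheme(2, 37, interleave_step = 6)
#' sch$slice_times_s[18]  # 1.78 s
#' @export
build_scheme <- function(tr_s, n_slices, interleave_step = 1L, ref_slice = NULL) {
  check_num(tr_s, "tr_s", positive = TRUE)
  n_slices <- check_count(n_slices, "n_slices")
  interleave_step <- check_count(interleave_step, "interleave_step")
  if (interleave_step > n_slices)
    stopf("interleave_step (%d) cannot exceed n_slices (%d)",
          interleave_step, n_slices)
  order <- unlist(lapply(seq_len(interleave_step), function(s)
    seq.int(s, n_slices, by = interleave_step)))
  pos <- match(seq_len(n_slices), order) - 1L  # 0-based temporal position
  times <- tr_s * pos / n_slices
  if (is.null(ref_slice)) ref_slice <- order[1L]
  ref_slice <- check_count(ref_slice, "ref_slice")
  if (ref_slice > n_slices) stopf("ref_slice out of range")
  structure(
    list(tr_s = tr_s, n_slices = n_slices,
         interleave_step = interleave_step,
         acquisition_order = as.integer(order),
         slice_times_s = times, ref_slice = ref_slice),
    class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("<acquisition_scheme> TR %.3g s, %d slices, interleave %d, ref slice %d\n",
              x$tr_s, x$n_slices, x$interleave_step, x$ref_slice))
  invisible(x)
}

## Per-slice shift (s) relative to the reference slice.
slice_delays <- function(scheme) {
  scheme$slice_times_s - scheme$slice_times_s[scheme$ref_slice]
}
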