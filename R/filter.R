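# Zero-phase band-pass filtering of voxel time series.

# Forward-backward Butterworth band-pass of a single demeaned series.
bp_single <- function(x, tr, f_lo, f_hi, order = 4L) {
  nyq <- 1 / (2 * tr)
  flt <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  x <- x - mean(x)
  y <- signal::filtfilt(flt, x)
  y - mean(y)
}

#' Band-pass filter all voxel time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass, the standard BOLD
#' band being 0.009-0.08 Hz. Row means are removed before and after
#' filtering, so constant series become all-zero.
#'
#' @param series An [fmri_series()].
#' @param f_lo,f_hi Band edges in Hz; must satisfy
#'   `0 < f_lo < f_hi < 1/(2*tr)`.
#' @param order Butterworth order per band edge (default 4); the
#'   forward-backward pass squares the magnitude response and cancels phase.
#' @return An `fmri_series` of the same shape.
#' @export
bandpass_filter <- function(series, f_lo = 0.009, f_hi = 0.08, order = 4L) {
  if (!inherits(series, "fmri_series")) abort("`series` must be an fmri_series")
  nyq <- 1 / (2 * series$tr)
  check_scalar_number(f_lo, "f_lo")
  check_scalar_number(f_hi, "f_hi")
  if (!(0 < f_lo && f_lo < f_hi && f_hi < nyq)) {
    abort(sprintf("band (%g, %g) Hz must lie strictly inside (0, Nyquist = %g) Hz",
                  f_lo, f_hi, nyq))
  }
  vals <- t(apply(series$values, 1L, bp_single,
                  tr = series$tr, f_lo = f_lo, f_hi = f_hi, order = order))
  fmri_series(vals, series$geometry, series$tr)
}
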