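#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward (zero phase
#' lag), the standard smoothing step for kinematic position data. To suppress
#' start-up transients the series is extended at both ends by odd (point-
#' symmetric) reflection before filtering and the padding is discarded
#' afterwards; a straight-line signal therefore passes through unchanged.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param cutoff_hz Low-pass cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Filter order per pass (default 2).
#' @return Filtered object of the same shape as `x`.
#' @export
lowpass_butter <- function(x, cutoff_hz, fs, order = 2L) {
  if (cutoff_hz <= 0 || fs <= 0) {
    fk_stop("cutoff_hz and fs must be positive", "feedkin_validation_error")
  }
  if (cutoff_hz >= fs / 2) return(x)  # at/above Nyquist: nothing to remove
  if (is.matrix(x)) {
    return(apply(x, 2L, lowpass_butter, cutoff_hz = cutoff_hz, fs = fs,
                 order = order))
  }
  n <- length(x)
  if (n < 8L) return(x)  # too short for a meaningful IIR pass
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "low")
  pad <- min(n - 1L, max(24L, 3L * ceiling(fs / cutoff_hz)))
  head_ref <- 2 * x[1L] - x[seq(pad + 1L, 2L, by = -1L)]
  tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad, by = -1L)]
  ext <- c(head_ref, x, tail_ref)
  y <- rev(signal::filter(bf, rev(signal::filter(bf, ext))))
  y[seq(pad + 1L, pad + n)]
}
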