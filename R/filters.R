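#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic representation of a real signal (the signal
#' plus i times its Hilbert transform), computed by zeroing negative
#' frequencies of the DFT. `Mod()` of the result is the amplitude envelope,
#' `Arg()` the instantaneous phase.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (anyNA(x)) stop("analytic_signal: input contains NA")
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = 0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# forward-backward filtering with odd (point-reflected) end padding, so
# edge transients settle in the pads rather than inside the signal
zp_filter <- function(x, bf, pad) {
  n <- length(x)
  np <- max(1L, min(n - 2L, as.integer(pad)))
  xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1L):(np + n)]
}

#' Zero-phase Butterworth filters
#'
#' Forward-backward ("two-pass") Butterworth filtering, order 4 per pass by
#' default, so the effective magnitude response is 8th order and the phase
#' response is zero. Used for all band-limited views of the EEG: the SO band
#' (0.5-2 Hz), the spindle bands (10-13, 13-16 Hz) and the 0.5 Hz high-pass
#' applied before ERP and RSA analyses.
#'
#' @param x numeric vector (one channel).
#' @param band numeric length-2, passband edges in Hz (low < high).
#' @param fs sampling rate in Hz.
#' @param order filter order per pass.
#' @return filtered numeric vector, same length as `x`.
#' @export
filter_bandpass <- function(x, band, fs, order = 4L) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("filter_bandpass: band must be increasing and positive")
  if (band[2] >= fs / 2) stop("filter_bandpass: upper edge at or above Nyquist")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  zp_filter(x, bf, 3 * fs / band[1])
}

#' @rdname filter_bandpass
#' @param cutoff cutoff frequency in Hz.
#' @export
filter_highpass <- function(x, cutoff, fs, order = 4L) {
  if (cutoff <= 0) stop("filter_highpass: cutoff must be positive")
  if (cutoff >= fs / 2) stop("filter_highpass: cutoff at or above Nyquist")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  zp_filter(x, bf, 3 * fs / cutoff)
}

#' @rdname filter_bandpass
#' @export
filter_lowpass <- function(x, cutoff, fs, order = 4L) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("filter_lowpass: cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zp_filter(x, bf, 6 * fs / cutoff)
}

#' Spindle-band amplitude envelope
#'
#' Band-pass filters one channel and returns the magnitude of the analytic
#' signal.
#'
#' @inheritParams filter_bandpass
#' @return numeric vector of envelope values (same length, non-negative).
#' @export
band_envelope <- function(x, band, fs, order = 4L) {
  Mod(analytic_signal(filter_bandpass(x, band, fs, order)))
}
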