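#' Cue-locked event-related potential
#'
#' Arithmetic mean over retained (unflagged) trials, optionally restricted
#' to a condition subset and optionally collapsed across channels.
#'
#' @param epochs a `nap_epochs`.
#' @param condition optional character vector of conditions to include.
#' @param collapse_channels if TRUE, average over channels as well.
#' @return matrix channels x time (with a `times` attribute), or a numeric
#'   vector if collapsed.
#' @export
compute_erp <- function(epochs, condition = NULL, collapse_channels = FALSE) {
  keep <- retained_idx(epochs)
  if (!is.null(condition))
    keep <- keep[epochs$metadata$condition[keep] %in% condition]
  if (length(keep) == 0) stop("compute_erp: empty trial selection")
  erp <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(erp) <- epochs$channel_labels
  if (collapse_channels) {
    out <- colMeans(erp)
    attr(out, "times") <- epochs$times
    return(out)
  }
  attr(erp, "times") <- epochs$times
  erp
}

#' Length of the Hanning analysis window at one frequency
#'
#' Five cycles per frequency by default, e.g. 333 ms at 15 Hz.
#'
#' @param freq frequency in Hz.
#' @param n_cycles cycles per window.
#' @return window length in milliseconds (nearest ms).
#' @export
tfr_window_ms <- function(freq, n_cycles = 5) round(n_cycles / freq * 1000)

# cross-correlation of x with a (possibly complex) centred kernel via FFT;
# returns values for all centres, NA where the window is clipped
kernel_scan <- function(x, k) {
  n <- length(x); L <- length(k); h <- (L - 1L) %/% 2L
  m <- n + L - 1L
  full <- stats::fft(stats::fft(c(x, rep(0, L - 1L))) *
                     stats::fft(c(rev(k), rep(0, n - 1L))), inverse = TRUE) / m
  out <- rep(NA_complex_, n)
  valid <- (h + 1L):(n - h)
  out[valid] <- full[valid + h]
  out
}

#' Time-frequency representation by Hanning-tapered complex demodulation
#'
#' For each frequency f the signal is scanned with a Hanning-tapered
#' complex exponential whose length is `n_cycles / f` seconds (odd sample
#' count, centred on the evaluated time point); power is the squared
#' amplitude estimate, scaled so a pure sinusoid of amplitude A yields
#' A^2/2 at its own frequency. Time points whose window exceeds the epoch
#' are missing values, never zero-padded. Power is averaged over retained
#' trials unless `keep_trials` is set.
#'
#' @param epochs a `nap_epochs`.
#' @param freqs frequencies in Hz (default 4-30 in 0.5 Hz steps).
#' @param n_cycles taper length in cycles per frequency.
#' @param step_ms spacing of evaluated time points in ms.
#' @param condition optional condition filter.
#' @param keep_trials return per-trial power (memory-hungry) instead of the
#'   trial average.
#' @return object of class `nap_tfr`: list with `power` (channels x
#'   frequencies x times, or trials x channels x frequencies x times),
#'   `freqs`, `times`, `units`, `n_trials`.
#' @export
compute_tfr <- function(epochs, freqs = seq(4, 30, by = 0.5), n_cycles = 5,
                        step_ms = 5, condition = NULL, keep_trials = FALSE) {
  fs <- epochs$fs
  if (any(freqs >= fs / 2)) stop("compute_tfr: frequency at or above Nyquist")
  if (any(freqs <= 0)) stop("compute_tfr: frequencies must be positive")
  n_t <- dim(epochs$data)[3]
  keep <- retained_idx(epochs)
  if (!is.null(condition))
    keep <- keep[epochs$metadata$condition[keep] %in% condition]
  if (length(keep) == 0) stop("compute_tfr: empty trial selection")
  step <- max(1L, round(fs * step_ms / 1000))
  t_idx <- seq(1L, n_t, by = step)
  times <- epochs$times[t_idx]
  nch <- dim(epochs$data)[2]
  kernels <- lapply(freqs, function(f) {
    L <- round(n_cycles / f * fs)
    L <- L + (1L - L %% 2L)               # force odd for a symmetric centre
    if (L > n_t) stop("compute_tfr: epoch too short for ", f, " Hz window")
    j <- seq_len(L) - (L + 1L) / 2L
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
    list(k = w * exp(-2i * pi * f * j / fs), norm = sum(w))
  })
  one_trial <- function(tr) {
    p <- array(NA_real_, dim = c(nch, length(freqs), length(t_idx)))
    for (ch in seq_len(nch)) {
      x <- epochs$data[tr, ch, ]
      for (fi in seq_along(freqs)) {
        kk <- kernels[[fi]]
        amp <- 2 * Mod(kernel_scan(x, kk$k)) / kk$norm
        p[ch, fi, ] <- (amp[t_idx])^2 / 2
      }
    }
    p
  }
  if (keep_trials) {
    pw <- array(NA_real_,
                dim = c(length(keep), nch, length(freqs), length(t_idx)))
    for (i in seq_along(keep)) pw[i, , , ] <- one_trial(keep[i])
  } else {
    pw <- array(0, dim = c(nch, length(freqs), length(t_idx)))
    for (tr in keep) pw <- pw + one_trial(tr)
    pw <- pw / length(keep)
  }
  structure(list(power = pw, freqs = freqs, times = times,
                 units = "uV^2", n_trials = length(keep),
                 channel_labels = epochs$channel_labels),
            class = "nap_tfr")
}

#' Percent power change relative to a pre-cue baseline
#'
#' Converts a trial-averaged TFR to 100 * (P - Pbase) / Pbase per channel
#' and frequency, with the baseline power averaged over the window (and
#' across trials beforehand, since the input is the trial average). Cells
#' with zero baseline power propagate as missing values.
#'
#' @param tfr a `nap_tfr` in raw power units (trial-averaged).
#' @param baseline length-2 closed window in seconds (default -0.3 to -0.1).
#' @return a `nap_tfr` in percent-change units.
#' @export
percent_change <- function(tfr, baseline = c(-0.3, -0.1)) {
  if (length(dim(tfr$power)) != 3L)
    stop("percent_change: expected a trial-averaged TFR (use keep_trials = FALSE)")
  b_idx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(b_idx) == 0) stop("percent_change: baseline outside TFR times")
  if (anyNA(tfr$power[, , b_idx]))
    stop("percent_change: baseline times unavailable at some frequencies")
  pb <- apply(tfr$power[, , b_idx, drop = FALSE], c(1, 2), mean)
  pb[pb == 0] <- NA_real_
  tfr$power <- 100 * sweep(sweep(tfr$power, c(1, 2), pb, "-"), c(1, 2), pb, "/")
  tfr$units <- "percent"
  tfr
}
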