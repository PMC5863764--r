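#' Read a recording and its sidecars
#'
#' Loads an EDF signal file together with a cue-events TSV and a hypnogram
#' TSV and checks their mutual consistency: the hypnogram must cover the
#' whole recording, all event onsets must lie inside it, and when
#' `expected_labels` is given the EDF channel set must match it exactly.
#'
#' @param edf path to the EDF file.
#' @param events path to the events TSV (`onset_s`, `condition`,
#'   `category`, `adjective_id`, `round`).
#' @param hypnogram path to the hypnogram TSV (`epoch_start_s`, `stage`).
#' @param expected_labels optional channel labels to enforce.
#' @return a `nap_recording`.
#' @export
read_recording <- function(edf, events, hypnogram, expected_labels = NULL) {
  e <- read_edf(edf)
  if (!is.null(expected_labels)) {
    bad <- setdiff(union(expected_labels, e$labels),
                   intersect(expected_labels, e$labels))
    if (!identical(e$labels, expected_labels))
      stop("read_recording: channel label mismatch: ",
           paste(bad, collapse = ", "))
  }
  ev <- utils::read.delim(events, sep = "\t", stringsAsFactors = FALSE)
  hy <- utils::read.delim(hypnogram, sep = "\t", stringsAsFactors = FALSE)
  dur <- ncol(e$signal) / e$fs
  if (nrow(hy) == 0 || max(hy$epoch_start_s) + 30 < dur)
    stop("read_recording: hypnogram does not cover the recording")
  if (nrow(ev) > 0 && (any(ev$onset_s < 0) || any(ev$onset_s > dur)))
    stop("read_recording: event onset beyond recording bounds")
  structure(list(
    signal = e$signal, fs = e$fs, channel_labels = e$labels,
    hypnogram = hy, events = ev, subject = NA_integer_
  ), class = "nap_recording")
}

# internal epoch-set constructor; data is trials x channels x time
new_epochs <- function(data, fs, channel_labels, tmin, metadata, ...) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == length(channel_labels),
            nrow(metadata) == dim(data)[1])
  structure(list(
    data = data, fs = fs, channel_labels = channel_labels,
    times = tmin + (seq_len(dim(data)[3]) - 1) / fs,
    metadata = metadata, ...
  ), class = "nap_epochs")
}

#' @export
print.nap_epochs <- function(x, ...) {
  cat(sprintf("<nap_epochs> %d trials x %d channels x %d samples @ %d Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat(sprintf("  time %.3f..%.3f s; %d trial(s) flagged as artifact\n",
              min(x$times), max(x$times), sum(x$metadata$artifact_flag)))
  invisible(x)
}

retained_idx <- function(epochs) which(!epochs$metadata$artifact_flag)

#' Extract cue-locked epochs
#'
#' Segments the continuous recording into trials spanning the half-open
#' interval [`tmin`, `tmax`) seconds around each cue onset (the sample at
#' t = 0 is the cue onset). Cues too close to either recording edge are
#' dropped with a warning.
#'
#' @param rec a `nap_recording`.
#' @param tmin,tmax epoch limits in seconds relative to cue onset.
#' @return a `nap_epochs` with per-trial metadata (`condition`,
#'   `category`, `adjective_id`, `round`, `artifact_flag`).
#' @export
extract_epochs <- function(rec, tmin = -1, tmax = 3) {
  fs <- rec$fs
  n <- ncol(rec$signal)
  ev <- rec$events
  if (nrow(ev) == 0) stop("extract_epochs: recording has no cue events")
  on_i <- round(ev$onset_s * fs) + 1L
  n_t <- round((tmax - tmin) * fs)
  first <- on_i + round(tmin * fs)
  ok <- first >= 1L & (first + n_t - 1L) <= n
  if (any(!ok))
    warning(sprintf("extract_epochs: dropping %d cue(s) too close to the recording edge",
                    sum(!ok)))
  if (!any(ok)) stop("extract_epochs: no cue survives the epoch bounds")
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nrow(rec$signal), n_t))
  for (k in seq_along(keep)) {
    i0 <- first[keep[k]]
    dat[k, , ] <- rec$signal[, i0:(i0 + n_t - 1L)]
  }
  meta <- ev[keep, , drop = FALSE]
  rownames(meta) <- NULL
  meta$artifact_flag <- FALSE
  new_epochs(dat, fs, rec$channel_labels, tmin, meta, subject = rec$subject)
}

#' Automatic artifact rejection (step one)
#'
#' Flags trials whose signal amplitude or gradient is extreme relative to
#' the distribution over trials: for each trial the amplitude statistic is
#' the maximum absolute value over channels and samples, and the gradient
#' statistic is the maximum absolute difference between adjacent samples.
#' A trial is flagged when either statistic falls outside
#' median +/- `k` * IQR of that statistic across trials. Flags are sticky:
#' trials already flagged stay flagged and still contribute to the
#' statistics' distribution.
#'
#' @param epochs a `nap_epochs` with >= 4 trials.
#' @param k IQR multiplier (default 3.5).
#' @return the epoch set with updated `artifact_flag`s.
#' @export
reject_artifacts_auto <- function(epochs, k = 3.5) {
  n_tr <- dim(epochs$data)[1]
  if (n_tr < 4L) stop("reject_artifacts_auto: need at least 4 trials")
  amp <- apply(epochs$data, 1, function(m) max(abs(m)))
  grd <- apply(epochs$data, 1, function(m) max(abs(m[, -1, drop = FALSE] -
                                                    m[, -ncol(m), drop = FALSE])))
  out <- function(x) {
    lo <- stats::median(x) - k * stats::IQR(x)
    hi <- stats::median(x) + k * stats::IQR(x)
    x < lo | x > hi
  }
  flag <- out(amp) | out(grd)
  epochs$metadata$artifact_flag <- epochs$metadata$artifact_flag | flag
  if (all(epochs$metadata$artifact_flag))
    stop("reject_artifacts_auto: all trials flagged; review thresholds")
  epochs
}

#' Robust outlier screen (step two)
#'
#' Automated stand-in for interactive summary-statistics screening: per
#' trial, signal variance and excess kurtosis are computed over all
#' channels and samples, converted to robust z-scores
#' ((x - median) / (1.4826 * MAD)) across unflagged trials, and trials
#' exceeding `z_cut` on either metric are flagged. A metric whose MAD is
#' zero is skipped with a warning.
#'
#' @param epochs a `nap_epochs` with >= 4 unflagged trials.
#' @param z_cut robust z threshold (default 5; `Inf` disables the screen).
#' @return the epoch set with updated `artifact_flag`s.
#' @export
screen_outliers <- function(epochs, z_cut = 5) {
  keep <- retained_idx(epochs)
  if (length(keep) < 4L) stop("screen_outliers: need at least 4 unflagged trials")
  metrics <- list(
    variance = apply(epochs$data, 1, function(m) stats::var(as.numeric(m))),
    kurtosis = apply(epochs$data, 1, function(m) {
      x <- as.numeric(m); x <- x - mean(x)
      mean(x^4) / mean(x^2)^2 - 3
    })
  )
  flag <- rep(FALSE, dim(epochs$data)[1])
  for (nm in names(metrics)) {
    x <- metrics[[nm]]
    md <- stats::median(x[keep]); s <- stats::mad(x[keep])
    if (is.na(s) || s == 0) {
      warning(sprintf("screen_outliers: MAD of %s is zero; metric skipped", nm))
      next
    }
    z <- abs(x - md) / s
    flag <- flag | (!is.na(z) & z > z_cut)
  }
  epochs$metadata$artifact_flag <- epochs$metadata$artifact_flag | flag
  epochs
}

#' High-pass filter and baseline-correct epochs
#'
#' Applies a zero-phase Butterworth high-pass per trial and channel, then
#' subtracts the mean of the baseline window so that the post-correction
#' baseline mean is exactly zero.
#'
#' @param epochs a `nap_epochs`.
#' @param hp high-pass cutoff in Hz (must be below Nyquist).
#' @param baseline length-2 window in seconds (closed interval) inside the
#'   epoch span.
#' @return the filtered, baseline-corrected epoch set.
#' @export
highpass_baseline <- function(epochs, hp = 0.5, baseline = c(-0.2, 0)) {
  if (hp >= epochs$fs / 2) stop("highpass_baseline: cutoff at or above Nyquist")
  if (baseline[1] < min(epochs$times) || baseline[2] > max(epochs$times))
    stop("highpass_baseline: baseline outside epoch span")
  b_idx <- which(epochs$times >= baseline[1] & epochs$times <= baseline[2])
  d <- epochs$data
  for (tr in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      x <- filter_highpass(d[tr, ch, ], hp, epochs$fs)
      d[tr, ch, ] <- x - mean(x[b_idx])
    }
  }
  epochs$data <- d
  epochs
}

#' Per-condition rejection log
#'
#' Counts retained and flagged trials per condition, the check that
#' artifact rejection did not differentially remove one cue type.
#'
#' @param epochs a `nap_epochs`.
#' @return data.frame with `condition`, `retained`, `flagged`.
#' @export
rejection_log <- function(epochs) {
  m <- epochs$metadata
  agg <- stats::aggregate(m$artifact_flag,
                          by = list(condition = m$condition),
                          FUN = function(f) c(retained = sum(!f), flagged = sum(f)))
  data.frame(condition = agg$condition,
             retained = agg$x[, "retained"], flagged = agg$x[, "flagged"])
}
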