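# Eligible-sample mask for event detection: N2/N3 stages, minus artifact
# samples padded by +/- pad_s.
eligible_mask <- function(rec, stages = c("N2", "N3"), artifact_mask = NULL,
                          pad_s = 1) {
  n <- ncol(rec$signal)
  m <- stage_mask(rec$hypnogram, stages, n, rec$fs)
  if (!is.null(artifact_mask)) {
    stopifnot(length(artifact_mask) == n)
    pad <- round(pad_s * rec$fs)
    bad <- which(artifact_mask)
    if (length(bad) > 0) {
      lo <- pmax(bad - pad, 1L); hi <- pmin(bad + pad, n)
      padded <- logical(n)
      for (i in seq_along(bad)) padded[lo[i]:hi[i]] <- TRUE
      m <- m & !padded
    }
  }
  m
}

# contiguous TRUE runs as (start, end) sample indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect discrete sleep spindles
#'
#' Per channel: band-pass filter (two-pass Butterworth, order 4 per pass),
#' amplitude envelope via the analytic signal, threshold = mean + `thresh_sd`
#' times the SD of the envelope over all eligible samples (N2/N3, artifact
#' samples padded +/- 1 s excluded) on that channel. Events are
#' supra-threshold runs of eligible samples lasting `min_dur` to `max_dur`
#' seconds; runs separated by less than `merge_gap` seconds are merged
#' before the duration gate.
#'
#' @param rec a `nap_recording`.
#' @param band passband in Hz; fast spindles 13-16 (default), slow 10-13.
#' @param stages sleep stages eligible for detection.
#' @param artifact_mask optional logical vector, one per sample, TRUE where
#'   the signal is artifactual.
#' @param thresh_sd SD multiplier of the envelope threshold.
#' @param min_dur,max_dur event duration bounds in seconds.
#' @param merge_gap maximum sub-threshold gap merged into one event, s.
#' @param channels optional subset of channel labels.
#' @return data.frame of detected events: `kind`, `channel`, `start_s`,
#'   `end_s`, `peak_s` (envelope maximum), `amplitude` (envelope max, uV).
#' @export
detect_spindles <- function(rec, band = c(13, 16), stages = c("N2", "N3"),
                            artifact_mask = NULL, thresh_sd = 1.25,
                            min_dur = 0.5, max_dur = 3, merge_gap = 0.1,
                            channels = NULL) {
  if (band[1] >= band[2]) stop("detect_spindles: inverted band")
  fs <- rec$fs
  elig <- eligible_mask(rec, stages, artifact_mask)
  if (!any(elig)) stop("detect_spindles: no eligible N2/N3 data")
  kind <- if (band[1] >= 13) "spindle_fast" else "spindle_slow"
  if (is.null(channels)) channels <- rec$channel_labels
  out <- list()
  for (ch in channels) {
    x0 <- rec$signal[ch, ] - mean(rec$signal[ch, ])   # exact DC invariance
    env <- band_envelope(x0, band, fs)
    thr <- mean(env[elig]) + thresh_sd * stats::sd(env[elig])
    supra <- env > thr & elig
    runs <- true_runs(supra)
    if (nrow(runs) > 1) {                         # merge short gaps
      gap <- (runs[-1, "start"] - runs[-nrow(runs), "end"] - 1L) / fs
      grp <- cumsum(c(0, gap >= merge_gap))
      runs <- do.call(rbind, lapply(split(seq_len(nrow(runs)), grp), function(i)
        cbind(start = runs[i[1], "start"], end = runs[i[length(i)], "end"])))
    }
    for (r in seq_len(nrow(runs))) {
      dur <- (runs[r, "end"] - runs[r, "start"] + 1L) / fs
      if (dur < min_dur || dur > max_dur) next
      idx <- runs[r, "start"]:runs[r, "end"]
      pk <- idx[which.max(env[idx])]
      out[[length(out) + 1L]] <- data.frame(
        kind = kind, channel = ch,
        start_s = (runs[r, "start"] - 1L) / fs,
        end_s = (runs[r, "end"] - 1L) / fs,
        peak_s = (pk - 1L) / fs, amplitude = env[pk])
    }
  }
  if (length(out) == 0)
    return(data.frame(kind = character(0), channel = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), amplitude = numeric(0)))
  do.call(rbind, out)
}

#' Detect slow oscillations
#'
#' Per channel: 0.5-2 Hz two-pass Butterworth filter, zero-crossing
#' detection, candidate events = successive positive-to-negative crossing
#' pairs 0.8-2 s apart whose samples are all eligible. For each candidate
#' the trough amplitude (most negative value) and trough-to-peak amplitude
#' are computed; candidates exceeding mean + `thresh_sd` * SD of **both**
#' metrics (over all candidates on that channel) are kept.
#'
#' @inheritParams detect_spindles
#' @param band SO filter band in Hz.
#' @param dur_range candidate duration bounds in seconds.
#' @return data.frame of events: `kind`, `channel`, `start_s`, `end_s`,
#'   `peak_s` (= trough time), `trough_uv`, `trough_peak_uv`.
#' @export
detect_sos <- function(rec, band = c(0.5, 2), stages = c("N2", "N3"),
                       artifact_mask = NULL, thresh_sd = 1.25,
                       dur_range = c(0.8, 2), channels = NULL) {
  fs <- rec$fs
  elig <- eligible_mask(rec, stages, artifact_mask)
  if (!any(elig)) stop("detect_sos: no eligible N2/N3 data")
  if (is.null(channels)) channels <- rec$channel_labels
  out <- list()
  for (ch in channels) {
    x <- filter_bandpass(rec$signal[ch, ] - mean(rec$signal[ch, ]), band, fs)
    pn <- which(x[-length(x)] > 0 & x[-1] <= 0)    # positive-to-negative
    if (length(pn) < 2) next
    cand <- list()
    for (i in seq_len(length(pn) - 1L)) {
      span <- (pn[i + 1L] - pn[i]) / fs
      if (span < dur_range[1] || span > dur_range[2]) next
      idx <- pn[i]:pn[i + 1L]
      if (!all(elig[idx])) next
      tr_i <- idx[which.min(x[idx])]
      trough <- x[tr_i]
      peak <- max(x[tr_i:pn[i + 1L]])              # up-state after the trough
      cand[[length(cand) + 1L]] <- data.frame(
        start = pn[i], end = pn[i + 1L], trough_i = tr_i,
        trough = trough, t2p = peak - trough)
    }
    if (length(cand) == 0) next
    cd <- do.call(rbind, cand)
    thr_tr <- mean(-cd$trough) + thresh_sd * stats::sd(-cd$trough)
    thr_tp <- mean(cd$t2p) + thresh_sd * stats::sd(cd$t2p)
    if (is.na(thr_tr) || is.na(thr_tp)) next
    # degenerate candidate pool (e.g. a constant-amplitude oscillation):
    # when all candidates agree to within a fraction of a percent, none
    # stands out from the rest and the adaptive threshold is meaningless
    if (stats::sd(-cd$trough) < 0.005 * mean(-cd$trough) ||
        stats::sd(cd$t2p) < 0.005 * mean(cd$t2p)) next
    keep <- which(-cd$trough > thr_tr & cd$t2p > thr_tp)
    for (i in keep) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "so", channel = ch,
        start_s = (cd$start[i] - 1L) / fs, end_s = (cd$end[i] - 1L) / fs,
        peak_s = (cd$trough_i[i] - 1L) / fs,
        trough_uv = cd$trough[i], trough_peak_uv = cd$t2p[i])
    }
  }
  if (length(out) == 0)
    return(data.frame(kind = character(0), channel = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), trough_uv = numeric(0),
                      trough_peak_uv = numeric(0)))
  do.call(rbind, out)
}

#' Count detected events in a post-cue window
#'
#' Per trial, counts events whose `peak_s` falls inside the closed window
#' [onset + window1, onset + window2] on the given channels
#' (left-hemisphere sites by default), then aggregates mean counts per
#' condition and the old-minus-control difference.
#'
#' @param events data.frame from [detect_spindles()] or [detect_sos()].
#' @param epochs a `nap_epochs` from the same recording (provides cue
#'   onsets and conditions; flagged trials are excluded).
#' @param window post-cue window in seconds, closed on both ends.
#' @param channels channel subset to count on.
#' @return list with `per_trial` (data.frame), `per_condition` (mean
#'   counts), and `old_minus_control` (difference of means, old = pooled
#'   old-object and old-scene).
#' @export
count_events_window <- function(events, epochs, window = c(1.5, 2.5),
                                channels = c("F3", "C3", "P3", "O1")) {
  if (window[1] < min(epochs$times) || window[2] > max(epochs$times))
    stop("count_events_window: window outside epoch span")
  keep <- retained_idx(epochs)
  onset <- epochs$metadata$onset_s[keep]
  cond <- epochs$metadata$condition[keep]
  ev <- events[events$channel %in% channels, , drop = FALSE]
  cnt <- vapply(onset, function(on)
    sum(ev$peak_s >= on + window[1] & ev$peak_s <= on + window[2]), 0L)
  per_trial <- data.frame(trial = keep, condition = cond, count = cnt)
  per_condition <- tapply(cnt, cond, mean)
  old <- mean(cnt[cond %in% c("old-object", "old-scene")])
  ctl <- mean(cnt[cond == "control"])
  list(per_trial = per_trial, per_condition = per_condition,
       old_minus_control = old - ctl)
}

#' Grand average of raw signal around event peaks
#'
#' Averages raw-signal segments of +/- `half_width` seconds around each
#' event's `peak_s` on the event's own channel. Events whose segment is
#' clipped by the recording edge are dropped.
#'
#' @param rec a `nap_recording`.
#' @param events detected events.
#' @param half_width segment half width in seconds.
#' @return list with `average` (numeric vector), `times`, `n_events`.
#' @export
grand_average_event <- function(rec, events, half_width = 1.5) {
  fs <- rec$fs
  h <- round(half_width * fs)
  n <- ncol(rec$signal)
  acc <- NULL; used <- 0L
  for (i in seq_len(nrow(events))) {
    c_i <- round(events$peak_s[i] * fs) + 1L
    if (c_i - h < 1L || c_i + h > n) next
    seg <- rec$signal[events$channel[i], (c_i - h):(c_i + h)]
    acc <- if (is.null(acc)) seg else acc + seg
    used <- used + 1L
  }
  if (used == 0L) stop("grand_average_event: no event with a full segment")
  list(average = acc / used, times = (-h:h) / fs, n_events = used)
}

#' Match detected events against ground-truth injections
#'
#' An injected event counts as recovered when a detected event on the same
#' channel has its peak within `tol_s` of the injected center. Sensitivity
#' is recovered / injected; precision is matched / detected.
#'
#' @param detected data.frame of detected events.
#' @param truth_centers data.frame with `channel` and `center_s`.
#' @param tol_s matching tolerance in seconds.
#' @return list with `sensitivity`, `precision`, `n_truth`, `n_detected`.
#' @export
match_events <- function(detected, truth_centers, tol_s = 0.5) {
  n_truth <- nrow(truth_centers); n_det <- nrow(detected)
  hit_truth <- logical(n_truth); hit_det <- logical(n_det)
  for (i in seq_len(n_truth)) {
    same <- which(detected$channel == truth_centers$channel[i] &
                  abs(detected$peak_s - truth_centers$center_s[i]) <= tol_s)
    if (length(same) > 0) { hit_truth[i] <- TRUE; hit_det[same] <- TRUE }
  }
  list(sensitivity = if (n_truth) mean(hit_truth) else NA_real_,
       precision = if (n_det) mean(hit_det) else NA_real_,
       n_truth = n_truth, n_detected = n_det)
}
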