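#' Preferred SO phase of spindle-amplitude modulation for one segment
#'
#' Implements the per-event coupling estimate on a raw-signal segment
#' centred on a spindle envelope maximum (601 samples at 200 Hz, i.e.
#' +/- 1.5 s). Two band-limited views are derived: the SO band (0.5-2 Hz),
#' whose instantaneous phase comes from the analytic signal, and the fast
#' spindle band (13-16 Hz), whose amplitude envelope is demeaned and passed
#' through the analytic signal to obtain the envelope phase. The per-sample
#' circular distance (SO phase minus envelope phase) is then averaged with
#' the circular mean, weighted by the instantaneous spindle envelope so
#' that samples without spindle energy (whose envelope phase is undefined
#' in practice) do not dilute the estimate.
#'
#' Phase convention: cosine phase of the SO, 0 = up-state peak,
#' +/-180 degrees = down-state trough. A spindle envelope peaking a quarter
#' cycle after the up-state peak yields +90 degrees.
#'
#' @param segment numeric vector, raw signal (one channel).
#' @param fs sampling rate in Hz.
#' @param so_band,spindle_band filter bands in Hz.
#' @return list with `phase` (radians in (-pi, pi]), `r` (resultant length
#'   of the weighted distances), `n` (samples).
#' @export
preferred_phase <- function(segment, fs, so_band = c(0.5, 2),
                            spindle_band = c(13, 16)) {
  so_ph <- Arg(analytic_signal(filter_bandpass(segment, so_band, fs)))
  env <- band_envelope(segment, spindle_band, fs)
  env_ph <- Arg(analytic_signal(env - mean(env)))
  d <- circ_dist(so_ph, env_ph)
  cm <- circ_mean(d, w = env)
  list(phase = cm$mean, r = cm$r, n = length(segment))
}

#' Per-event preferred phase from a recording
#'
#' Extracts the +/- `half_width` s raw segment around an event's peak on
#' its own channel and runs [preferred_phase()]. Events whose segment is
#' clipped by the recording edge are skipped with a warning.
#'
#' @param rec a `nap_recording`.
#' @param events data.frame of spindle events (`channel`, `peak_s`).
#' @param half_width segment half width in seconds (1.5 gives 601 samples
#'   at 200 Hz, accommodating the maximum 3 s spindle duration).
#' @return data.frame: `channel`, `peak_s`, `phase_rad`, `phase_deg`, `r`.
#' @export
event_preferred_phase <- function(rec, events, half_width = 1.5) {
  fs <- rec$fs
  h <- round(half_width * fs)
  n <- ncol(rec$signal)
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(events))) {
    c_i <- round(events$peak_s[i] * fs) + 1L
    if (c_i - h < 1L || c_i + h > n) { skipped <- skipped + 1L; next }
    seg <- rec$signal[events$channel[i], (c_i - h):(c_i + h)]
    pp <- preferred_phase(seg, fs)
    out[[length(out) + 1L]] <- data.frame(
      channel = events$channel[i], peak_s = events$peak_s[i],
      phase_rad = pp$phase, phase_deg = deg(pp$phase), r = pp$r)
  }
  if (skipped > 0)
    warning(sprintf("event_preferred_phase: %d event(s) skipped (clipped segment)",
                    skipped))
  if (length(out) == 0)
    return(data.frame(channel = character(0), peak_s = numeric(0),
                      phase_rad = numeric(0), phase_deg = numeric(0),
                      r = numeric(0)))
  do.call(rbind, out)
}

#' Subject-level mean preferred phase
#'
#' Circular mean over a subject's per-event preferred phases; `r` is the
#' mean resultant length. Antipodal cancellation (r ~ 0) is flagged
#' degenerate, in which case the mean direction is not interpretable.
#'
#' @param phases per-event phases in radians (length >= 1).
#' @return list with `mean` (radians), `r`, `n`, `degenerate`.
#' @export
subject_mean_phase <- function(phases) {
  if (length(phases) == 0) stop("subject_mean_phase: no phases")
  circ_mean(phases)
}

#' Select post-cue spindles and run the full coupling analysis
#'
#' Keeps spindle events whose envelope maximum falls from `window[1]` to
#' `window[2]` s after old-cue onsets on the given channels, estimates each
#' event's preferred phase, averages per subject, and (for a cohort of
#' recordings) tests the subject means against uniformity (Rayleigh) and
#' against the SO up-state (V test versus 0).
#'
#' @param rec a `nap_recording`.
#' @param spindles detected spindle events for that recording.
#' @param window post-cue selection window in seconds (closed).
#' @param channels channel subset (left hemisphere by default).
#' @param conditions cue conditions whose post-cue spindles qualify.
#' @return list with `events` (per-event phases) and `subject`
#'   (mean phase, r, n, degenerate flag).
#' @export
couple_postcue_spindles <- function(rec, spindles, window = c(1.5, 2.5),
                                    channels = c("F3", "C3", "P3", "O1"),
                                    conditions = c("old-object", "old-scene")) {
  ev <- rec$events
  on <- ev$onset_s[ev$condition %in% conditions]
  sp <- spindles[spindles$channel %in% channels, , drop = FALSE]
  in_win <- vapply(sp$peak_s, function(p)
    any(p >= on + window[1] & p <= on + window[2]), logical(1))
  sp <- sp[in_win, , drop = FALSE]
  if (nrow(sp) == 0)
    return(list(events = NULL, subject = NULL))
  ph <- event_preferred_phase(rec, sp)
  list(events = ph, subject = subject_mean_phase(ph$phase_rad))
}

#' Cohort-level coupling statistics
#'
#' @param subject_phases per-subject mean phases in radians (degenerate
#'   subjects already excluded).
#' @param ref reference direction in radians for the V test (0 = up-state).
#' @return list with `mean_deg`, `r`, `rayleigh` (z, p), `v` (v, p), `n`.
#' @export
coupling_group_stats <- function(subject_phases, ref = 0) {
  cm <- circ_mean(subject_phases)
  ray <- rayleigh_test(subject_phases)
  vt <- v_test(subject_phases, ref)
  list(mean_deg = deg(cm$mean), r = cm$r, rayleigh = ray, v = vt,
       n = length(subject_phases))
}
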