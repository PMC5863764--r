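#' Simulation configuration for synthetic polysomnography
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults emulate the study conditions of a nap TMR experiment: 8 scalp
#' channels sampled at 200 Hz, NREM background EEG with a 1/f spectrum,
#' discrete slow oscillations and fast-spindle bursts coupled to SO phase,
#' auditory cues delivered every 4 s (+/- 200 ms jitter) during N2/N3 with a
#' condition-dependent spindle surge 1.5-2.5 s post-cue, category-specific
#' low-frequency patterns 1.7-2.3 s post-cue, and a configurable behavioral
#' cueing benefit tied to each subject's pattern distinctiveness.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_channels number of EEG channels (default 8).
#' @param channel_labels channel names, 10-20 montage order.
#' @param fs sampling rate, Hz.
#' @param duration recording length per subject, seconds.
#' @param background_exponent 1/f spectral exponent of the background EEG.
#' @param background_amplitude background RMS amplitude, microvolts.
#' @param so_rate slow-oscillation rate, events/min.
#' @param so_amplitude SO peak-to-peak scale, microvolts.
#' @param so_duration SO duration (one down+up half-wave pair), seconds, in
#'   [0.8, 2].
#' @param spindle_rate spontaneous spindle rate per channel, events/min.
#' @param spindle_freq spindle carrier frequency, Hz, in [13, 16].
#' @param spindle_amplitude spindle burst amplitude, microvolts.
#' @param spindle_duration spindle burst duration, seconds, in [0.5, 3].
#' @param coupling_phase injected SO phase of spindle centers, degrees in
#'   (-180, 180] (0 = up-state peak, 180 = trough).
#' @param coupling_concentration von Mises kappa of the phase jitter (>= 0).
#' @param cue_isi inter-cue interval, seconds.
#' @param cue_isi_jitter uniform ISI jitter half-width, seconds.
#' @param evoked_so_latency length-2 range (s) of evoked k-complex onset
#'   after a cue.
#' @param evoked_spindle_prob probability a control cue evokes a spindle.
#' @param evoked_spindle_gain_old multiplier on that probability for old
#'   (memory) cues.
#' @param evoked_window post-cue window (s) holding evoked spindle centers.
#' @param category_pattern_snr amplitude of the category-specific pattern
#'   relative to background RMS (0 disables).
#' @param pattern_window post-cue window (s) carrying category patterns.
#' @param behavior_effect cohort-mean cued minus non-cued T3 retention
#'   difference.
#' @param n_pairs_per_category adjective-image pairs learned per category.
#' @param seed master RNG seed; all subject streams derive from it.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_subjects = 10L,
                       n_channels = 8L,
                       channel_labels = c("F3", "F4", "C3", "C4",
                                          "P3", "P4", "O1", "O2"),
                       fs = 200L,
                       duration = 600,
                       background_exponent = 1,
                       background_amplitude = 15,
                       so_rate = 5,
                       so_amplitude = 75,
                       so_duration = 1.4,
                       spindle_rate = 3,
                       spindle_freq = 14,
                       spindle_amplitude = 25,
                       spindle_duration = 1,
                       coupling_phase = 0,
                       coupling_concentration = 4,
                       cue_isi = 4,
                       cue_isi_jitter = 0.2,
                       evoked_so_latency = c(0.4, 0.9),
                       evoked_spindle_prob = 0.35,
                       evoked_spindle_gain_old = 1.5,
                       evoked_window = c(1.5, 2.5),
                       category_pattern_snr = 1,
                       pattern_window = c(1.7, 2.3),
                       behavior_effect = 0.2,
                       n_pairs_per_category = 50L,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    channel_labels = channel_labels, fs = as.integer(fs), duration = duration,
    background_exponent = background_exponent,
    background_amplitude = background_amplitude,
    so_rate = so_rate, so_amplitude = so_amplitude, so_duration = so_duration,
    spindle_rate = spindle_rate, spindle_freq = spindle_freq,
    spindle_amplitude = spindle_amplitude,
    spindle_duration = spindle_duration,
    coupling_phase = coupling_phase,
    coupling_concentration = coupling_concentration,
    cue_isi = cue_isi, cue_isi_jitter = cue_isi_jitter,
    evoked_so_latency = evoked_so_latency,
    evoked_spindle_prob = evoked_spindle_prob,
    evoked_spindle_gain_old = evoked_spindle_gain_old,
    evoked_window = evoked_window,
    category_pattern_snr = category_pattern_snr,
    pattern_window = pattern_window,
    behavior_effect = behavior_effect,
    n_pairs_per_category = as.integer(n_pairs_per_category),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1L, cfg$n_channels >= 1L,
    length(cfg$channel_labels) == cfg$n_channels,
    cfg$fs > 0L, cfg$duration > 0,
    cfg$background_amplitude >= 0, cfg$background_exponent >= 0,
    cfg$so_rate >= 0, cfg$so_amplitude >= 0,
    cfg$so_duration >= 0.8, cfg$so_duration <= 2,
    cfg$spindle_rate >= 0, cfg$spindle_amplitude >= 0,
    cfg$spindle_duration >= 0.5, cfg$spindle_duration <= 3,
    cfg$coupling_concentration >= 0,
    cfg$cue_isi > 0, cfg$cue_isi_jitter >= 0,
    cfg$evoked_spindle_prob >= 0, cfg$evoked_spindle_prob <= 1,
    cfg$evoked_spindle_gain_old >= 0,
    cfg$category_pattern_snr >= 0,
    length(cfg$pattern_window) == 2L,
    cfg$pattern_window[1] < cfg$pattern_window[2],
    cfg$n_pairs_per_category >= 1L
  )
  if (cfg$coupling_phase <= -180 || cfg$coupling_phase > 180)
    stop("sim_config: coupling_phase must lie in (-180, 180]")
  if (cfg$spindle_freq < 13 || cfg$spindle_freq > 16)
    stop("sim_config: spindle_freq must lie in [13, 16] (fast spindles)")
  if (cfg$fs <= 2 * cfg$spindle_freq)
    stop("sim_config: sampling_rate must exceed twice the spindle frequency")
  invisible(cfg)
}

# Save/restore the caller's RNG state around functions that seed
# internally, so seeded pipeline stages do not perturb user-level
# randomness.
preserve_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Deterministic per-subject, per-component seed stream: every generator
# component reseeds from (master seed, subject, component index) so any
# stage can be regenerated independently. Kept below 2^31.
subject_seed <- function(cfg, subject, component = 0L) {
  as.integer((cfg$seed * 7919L + subject * 104729L + component * 613L) %%
               2147483L + subject)
}
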