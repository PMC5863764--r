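#' Simulate behavioral recall and discrimination outcomes
#'
#' Draws per-item Bernoulli recall outcomes at the three test phases
#' (T1 before the nap, T2 after it, T3 the next day) for one subject.
#' Cued/non-cued assignment is balanced within category among T1-correct
#' items; conditional T3 retention for cued items is raised by the
#' subject's true cueing benefit from the ground truth, so the cohort mean
#' of the cued minus non-cued T2->T3 retention difference recovers
#' `cfg$behavior_effect`. Discrimination responses are cue-independent,
#' emulating participants' inability to identify which adjectives were
#' replayed.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [generate_recording()] (provides the
#'   subject's true benefit); may also be a list with `subject` and
#'   `true_benefit`.
#' @param p_t1 probability an item's category is recalled at T1.
#' @param p_t2 conditional retention probability T1->T2.
#' @param p_t3 conditional retention probability T2->T3, non-cued.
#' @param p_cat_correct probability an image is correctly classified in the
#'   object/scene categorisation task (misclassified items are excluded
#'   from recall scoring downstream).
#' @param p_discrim_yes probability of an "identified as replayed" response.
#' @return data.frame of class `nap_behavior`, one row per item.
#' @export
generate_behavior <- function(cfg, truth,
                              p_t1 = 0.55, p_t2 = 0.8, p_t3 = 0.65,
                              p_cat_correct = 0.965, p_discrim_yes = 0.3) {
  if (is.null(truth$true_benefit))
    stop("generate_behavior: truth lacks a per-subject true benefit")
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  subject <- truth$subject
  set.seed(subject_seed(cfg, subject, 7L))
  n_per <- cfg$n_pairs_per_category
  items <- data.frame(
    subject = subject,
    item_id = sprintf("s%02d_item%03d", subject, seq_len(2L * n_per)),
    category = rep(c("object", "scene"), each = n_per)
  )
  items$categorisation_correct <- stats::runif(nrow(items)) < p_cat_correct
  items$t1 <- stats::runif(nrow(items)) < p_t1

  # inclusion criterion: at least 14 correctly recalled per category; top
  # up deterministically if the draw fell short (rare at the defaults)
  for (cat in c("object", "scene")) {
    ok <- items$category == cat & items$t1 & items$categorisation_correct
    short <- 14L - sum(ok)
    if (short > 0) {
      fix <- which(items$category == cat & !ok)[seq_len(short)]
      items$t1[fix] <- TRUE
      items$categorisation_correct[fix] <- TRUE
    }
  }

  # cued assignment: half of T1-correct items per category
  items$cued <- NA
  for (cat in c("object", "scene")) {
    idx <- which(items$category == cat & items$t1)
    cued_idx <- sample(idx, floor(length(idx) / 2))
    items$cued[idx] <- FALSE
    items$cued[cued_idx] <- TRUE
  }

  p3_cued <- p_t3 + truth$true_benefit
  if (p3_cued > 1 || p3_cued < 0) {
    warning("generate_behavior: cued T3 retention probability clipped to [0, 1]")
    p3_cued <- min(max(p3_cued, 0), 1)
  }
  items$t2 <- items$t1 & (stats::runif(nrow(items)) < p_t2)
  p3 <- ifelse(isTRUE_vec(items$cued), p3_cued, p_t3)
  items$t3 <- items$t2 & (stats::runif(nrow(items)) < p3)
  items$discrim_yes <- ifelse(is.na(items$cued), NA,
                              stats::runif(nrow(items)) < p_discrim_yes)
  class(items) <- c("nap_behavior", "data.frame")
  items
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write a synthetic recording to disk as analysis-ready files
#'
#' Produces the on-disk interchange formats the pipeline reads back: an EDF
#' signal file, a cue-events TSV (`onset_s`, `condition`, `category`,
#' `adjective_id`, `round`), a hypnogram TSV (`epoch_start_s`, `stage`) and
#' a ground-truth JSON.
#'
#' @param recording a `nap_recording`.
#' @param truth matching `nap_ground_truth` (optional; skipped when NULL).
#' @param dir output directory (created if missing).
#' @param stem file-name stem, default `subject<k>`.
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(recording, truth = NULL, dir, stem = NULL) {
  if (is.null(stem)) stem <- sprintf("subject%02d", recording$subject)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edf <- file.path(dir, paste0(stem, ".edf"))
  write_edf(recording$signal, recording$fs, recording$channel_labels, edf)
  ev <- file.path(dir, paste0(stem, "_events.tsv"))
  utils::write.table(recording$events, ev, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  hy <- file.path(dir, paste0(stem, "_hypnogram.tsv"))
  utils::write.table(recording$hypnogram, hy, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(edf = edf, events = ev, hypnogram = hy)
  if (!is.null(truth)) {
    tj <- file.path(dir, paste0(stem, "_truth.json"))
    jsonlite::write_json(unclass(truth), tj, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths <- c(paths, truth = tj)
  }
  paths
}

#' Simulate cue-locked epochs directly
#'
#' Reduced-scale generator used for calibration studies (for example
#' family-wise error of the cluster test over many replicate null
#' datasets): draws an epoch set straight at the trial level -- 1/f
#' background noise plus the category-specific patterns in the configured
#' post-cue window -- without synthesizing and segmenting a continuous
#' recording.
#'
#' @param cfg a [sim_config()].
#' @param n_trials trials per category (total is twice this).
#' @param subject subject index for the RNG stream.
#' @param tmin,tmax epoch limits in seconds relative to cue onset.
#' @return a `nap_epochs` object with `old-object`/`old-scene` metadata.
#' @export
simulate_epochs <- function(cfg, n_trials = 10L, subject = 1L,
                            tmin = -1, tmax = 3) {
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  set.seed(subject_seed(cfg, subject, 8L))
  fs <- cfg$fs
  n_t <- round((tmax - tmin) * fs)
  n_trial_tot <- 2L * n_trials
  dat <- array(0, dim = c(n_trial_tot, cfg$n_channels, n_t))
  u_s <- stats::runif(1, 0.6, 1.4)
  pat <- category_patterns(cfg, u_s)   # zero-amplitude when snr = 0
  cats <- rep(c("object", "scene"), times = n_trials)
  w0 <- round((cfg$pattern_window[1] - tmin) * fs) + 1L
  ev_T <- 1.4
  ev_m <- round(ev_T * fs)
  ev_wave <- -0.5 * cfg$so_amplitude * sin(2 * pi * (seq_len(ev_m) - 1) / ev_m)
  tail_w <- common_tail_wave(cfg)
  for (tr in seq_len(n_trial_tot)) {
    for (ch in seq_len(cfg$n_channels))
      dat[tr, ch, ] <- one_over_f_noise(n_t, cfg$background_exponent,
                                        cfg$background_amplitude)
    # condition-independent evoked activity with latency jitter: an early
    # k-complex plus a sustained late slow component, giving all trials the
    # shared response cues evoke in a real recording
    lat <- stats::runif(1, cfg$evoked_so_latency[1], cfg$evoked_so_latency[2])
    e0 <- round((lat - tmin) * fs) + 1L
    if (e0 >= 1L && e0 + ev_m - 1L <= n_t) {
      for (ch in seq_len(cfg$n_channels))
        dat[tr, ch, e0:(e0 + ev_m - 1L)] <-
          dat[tr, ch, e0:(e0 + ev_m - 1L)] + ev_wave
    }
    t0 <- round((tail_w$offset + stats::runif(1, -0.05, 0.05) - tmin) * fs) + 1L
    t1 <- t0 + length(tail_w$wave) - 1L
    if (t0 >= 1L && t1 <= n_t) {
      for (ch in seq_len(cfg$n_channels))
        dat[tr, ch, t0:t1] <- dat[tr, ch, t0:t1] + tail_w$wave
    }
    idx <- w0:(w0 + ncol(pat[[cats[tr]]]) - 1L)
    dat[tr, , idx] <- dat[tr, , idx] + pat[[cats[tr]]]
  }
  meta <- data.frame(
    condition = paste0("old-", cats), category = cats,
    adjective_id = sprintf("adj%03d", seq_len(n_trial_tot)),
    round = 1L, artifact_flag = FALSE
  )
  new_epochs(dat, fs, cfg$channel_labels, tmin, meta,
             subject = subject, true_distinctiveness = cfg$category_pattern_snr * u_s)
}
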