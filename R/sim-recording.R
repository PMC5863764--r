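#' Synthetic polysomnography with ground truth
#'
#' Generates one subject's continuous multi-channel sleep EEG emulating a
#' cued-nap TMR session: 1/f background activity, discrete slow
#' oscillations (down-state half-wave followed by an up-state half-wave),
#' Gaussian-windowed fast-spindle bursts whose centers sit at a configured
#' SO phase with von Mises jitter, auditory cue markers restricted to N2/N3,
#' a stereotyped evoked k-complex 0.4-0.9 s after every cue, a
#' condition-dependent evoked spindle (more likely after old memory cues
#' than after control adjectives), and category-specific low-frequency
#' spatiotemporal patterns in a post-cue window for old cues. Every
#' injection is recorded in the returned ground truth.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index (1-based); determines the RNG streams.
#' @return list with elements `recording` (class `nap_recording`: `signal`
#'   channels x samples in microvolts, `fs`, `channel_labels`, `hypnogram`,
#'   `events`) and `truth` (class `nap_ground_truth`: injected SOs,
#'   spindles, trial table, per-subject true distinctiveness and benefit).
#' @export
generate_recording <- function(cfg, subject = 1L) {
  validate_sim_config(cfg)
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  nch <- cfg$n_channels
  hyp <- sim_hypnogram(cfg$duration)
  elig <- stage_mask(hyp, c("N2", "N3"), n, fs)
  if (sum(elig) / fs < 10 &&
      (cfg$so_rate > 0 || cfg$spindle_rate > 0 || cfg$cue_isi < cfg$duration))
    stop("generate_recording: duration too short to place requested events")

  # background: spectrally shaped Gaussian noise, independent per channel
  set.seed(subject_seed(cfg, subject, 1L))
  sig <- matrix(0, nrow = nch, ncol = n,
                dimnames = list(cfg$channel_labels, NULL))
  for (ch in seq_len(nch)) {
    sig[ch, ] <- one_over_f_noise(n, cfg$background_exponent,
                                  cfg$background_amplitude)
  }

  # spontaneous SOs: shared across channels (global NREM events)
  set.seed(subject_seed(cfg, subject, 2L))
  so_T <- cfg$so_duration
  n_so <- stats::rpois(1, cfg$so_rate * sum(elig) / fs / 60)
  so_starts <- numeric(0)
  if (n_so > 0 && cfg$so_amplitude > 0) {
    cand <- which(elig[seq_len(n - round(so_T * fs))])
    cand <- cand[cand > fs]  # keep clear of the recording edge
    if (length(cand) > 0) {
      so_starts <- sort(sample(cand, min(n_so, length(cand)))) / fs
      # enforce non-overlap
      keep <- c(TRUE, diff(so_starts) > so_T)
      so_starts <- so_starts[keep]
      for (s in so_starts) sig <- add_so(sig, s, so_T, cfg$so_amplitude, fs)
    }
  }
  so_truth <- data.frame(
    start_s = so_starts, trough_s = so_starts + so_T / 4,
    peak_s = so_starts + 3 * so_T / 4, duration_s = rep(so_T, length(so_starts)),
    evoked = rep(FALSE, length(so_starts))
  )

  # spontaneous spindles, coupled to the nearest injected SO when one exists
  set.seed(subject_seed(cfg, subject, 3L))
  mu <- rad(cfg$coupling_phase)
  spin <- list()
  sp_T <- cfg$spindle_duration
  ph2t <- so_phase_to_time(so_T, fs)
  n_sp_ch <- stats::rpois(nch, cfg$spindle_rate * sum(elig) / fs / 60)
  placed <- vector("list", nch)          # per-channel centers, for refractoriness
  for (ch in seq_len(nch)) {
    if (n_sp_ch[ch] == 0 || cfg$spindle_amplitude == 0) next
    for (k in seq_len(n_sp_ch[ch])) {
      if (nrow(so_truth) > 0) {
        so_i <- sample.int(nrow(so_truth), 1)
        ph <- rvonmises(1, mu, cfg$coupling_concentration)
        ctr <- so_truth$start_s[so_i] + ph2t(ph)
      } else {
        cand <- which(elig)
        ctr <- sample(cand, 1) / fs
        ph <- NA_real_
      }
      if (ctr < sp_T / 2 + 0.1 || ctr > cfg$duration - sp_T / 2 - 0.1) next
      if (any(abs(placed[[ch]] - ctr) < sp_T + 0.5)) next  # refractory gap
      placed[[ch]] <- c(placed[[ch]], ctr)
      sig[ch, ] <- add_spindle(sig[ch, ], ctr, sp_T, cfg$spindle_amplitude,
                               cfg$spindle_freq, fs)
      spin[[length(spin) + 1L]] <- data.frame(
        channel = cfg$channel_labels[ch], center_s = ctr, phase_rad = ph,
        evoked = FALSE, condition = NA_character_, cue_index = NA_integer_
      )
    }
  }

  # cue schedule inside N2/N3 stretches
  set.seed(subject_seed(cfg, subject, 4L))
  events <- sim_cue_schedule(cfg, hyp)

  # evoked responses: k-complex for every cue; spindle with
  # condition-dependent probability, coupled to the evoked SO up-state
  set.seed(subject_seed(cfg, subject, 5L))
  if (nrow(events) > 0) {
    ev_T <- 1.4
    ph2t_ev <- if (ev_T == so_T) ph2t else so_phase_to_time(ev_T, fs)
    tail_w <- common_tail_wave(cfg)
    for (i in seq_len(nrow(events))) {
      on <- events$onset_s[i]
      t0 <- round((on + tail_w$offset + stats::runif(1, -0.05, 0.05)) * fs) + 1L
      t1 <- t0 + length(tail_w$wave) - 1L
      if (t0 >= 1L && t1 <= n) {
        for (ch in seq_len(nch))
          sig[ch, t0:t1] <- sig[ch, t0:t1] + tail_w$wave
      }
      lat <- stats::runif(1, cfg$evoked_so_latency[1], cfg$evoked_so_latency[2])
      if ((on + lat + ev_T) * fs < n && cfg$so_amplitude > 0) {
        sig <- add_so(sig, on + lat, ev_T, cfg$so_amplitude, fs)
        so_truth <- rbind(so_truth, data.frame(
          start_s = on + lat, trough_s = on + lat + ev_T / 4,
          peak_s = on + lat + 3 * ev_T / 4, duration_s = ev_T, evoked = TRUE))
      }
      p_ev <- cfg$evoked_spindle_prob *
        ifelse(events$condition[i] %in% c("old-object", "old-scene"),
               cfg$evoked_spindle_gain_old, 1)
      if (stats::runif(1) < min(p_ev, 1) && cfg$spindle_amplitude > 0) {
        ph <- rvonmises(1, mu, cfg$coupling_concentration)
        ctr <- on + lat + ph2t_ev(ph)
        if (ctr > sp_T / 2 + 0.1 && ctr < cfg$duration - sp_T / 2 - 0.1) {
          # left-hemisphere surge, mirroring the left-lateralized effect
          for (ch in which(cfg$channel_labels %in% c("F3", "C3", "P3", "O1"))) {
            if (any(abs(placed[[ch]] - ctr) < sp_T + 0.5)) next
            placed[[ch]] <- c(placed[[ch]], ctr)
            sig[ch, ] <- add_spindle(sig[ch, ], ctr, sp_T,
                                     cfg$spindle_amplitude, cfg$spindle_freq, fs)
            spin[[length(spin) + 1L]] <- data.frame(
              channel = cfg$channel_labels[ch], center_s = ctr, phase_rad = ph,
              evoked = TRUE, condition = events$condition[i], cue_index = i)
          }
        }
      }
    }
  }

  # category-specific slow spatiotemporal patterns on old trials
  set.seed(subject_seed(cfg, subject, 6L))
  u_s <- stats::runif(1, 0.6, 1.4)       # subject-level pattern strength
  if (cfg$category_pattern_snr > 0 && nrow(events) > 0) {
    pat <- category_patterns(cfg, u_s)
    for (i in seq_len(nrow(events))) {
      cat_i <- events$category[i]
      if (is.na(cat_i)) next
      i0 <- round((events$onset_s[i] + cfg$pattern_window[1]) * fs) + 1L
      idx <- i0:(i0 + ncol(pat[[cat_i]]) - 1L)
      if (max(idx) <= n) sig[, idx] <- sig[, idx] + pat[[cat_i]]
    }
  }

  spindle_truth <- if (length(spin)) do.call(rbind, spin) else
    data.frame(channel = character(0), center_s = numeric(0),
               phase_rad = numeric(0), evoked = logical(0),
               condition = character(0), cue_index = integer(0))

  rec <- structure(list(
    signal = sig, fs = fs, channel_labels = cfg$channel_labels,
    hypnogram = hyp, events = events, subject = subject
  ), class = "nap_recording")
  truth <- structure(list(
    subject = subject, so = so_truth, spindles = spindle_truth,
    trials = events,
    true_distinctiveness = cfg$category_pattern_snr * u_s,
    true_benefit = cfg$behavior_effect * u_s,
    pattern_strength = u_s
  ), class = "nap_ground_truth")
  list(recording = rec, truth = truth)
}

# Gaussian noise with amplitude spectrum proportional to f^(-exponent/2),
# scaled to a target RMS. exponent = 0 gives white noise.
one_over_f_noise <- function(n, exponent, rms) {
  if (rms == 0) return(numeric(n))
  white <- stats::rnorm(n)
  if (exponent == 0) return(white * rms)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                       # avoid DC blow-up
  f <- pmin(f, n - f + 1)                         # symmetric frequency index
  shaped <- Re(stats::fft(X * f^(-exponent / 2), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  shaped / stats::sd(shaped) * rms
}

# Map a desired SO phase (cosine convention: 0 = up-state peak) to a time
# offset from the template start, using the analytic phase of the 0.5-2 Hz
# filtered template itself. A solitary SO cycle's instantaneous phase is
# not a uniform ramp, so placing coupled spindles by a linear phase-time
# map would make the injected phase disagree with what any Hilbert-based
# estimator measures; this lookup keeps ground truth and estimator on the
# same definition. Returns a function phase(rad) -> offset(s).
so_phase_to_time <- function(T, fs) {
  pad <- round(2 * T * fs)
  m <- round(T * fs)
  tt <- (seq_len(m) - 1) / fs
  tpl <- c(numeric(pad), -sin(2 * pi * tt / T), numeric(pad))
  ftpl <- filter_bandpass(tpl, c(0.5, 2), fs)
  ph <- Arg(analytic_signal(ftpl))
  un <- ph + 2 * pi * cumsum(c(0, diff(ph)) < -pi)   # unwrap (phase increases)
  pk <- which.max(ftpl)                              # up-state peak (phase 0)
  un <- un - 2 * pi * round(un[pk] / (2 * pi))       # anchor peak at 0
  # the filtered wavelet's phase keeps advancing into its decaying tails,
  # so the full (-pi, pi] cycle is available around the peak
  sub <- which(un >= -pi & un <= pi)
  sub <- sub[sub >= pk - 2 * m & sub <= pk + 2 * m]
  function(phase) stats::approx(un[sub], (sub - 1L - pad) / fs, xout = phase,
                                rule = 2)$y
}

# SO template: -A*sin(2*pi*t/T) over one period, i.e. a down-state
# half-wave (trough at T/4) followed by an up-state half-wave (peak at
# 3T/4); added to all channels.
add_so <- function(sig, start_s, T, A, fs) {
  i0 <- round(start_s * fs) + 1L
  m <- round(T * fs)
  if (i0 < 1L || i0 + m - 1L > ncol(sig)) return(sig)
  tt <- (seq_len(m) - 1) / fs
  w <- -A * sin(2 * pi * tt / T)
  sig[, i0:(i0 + m - 1L)] <- sweep(sig[, i0:(i0 + m - 1L), drop = FALSE], 2,
                                   w, "+")
  sig
}

# Gaussian-windowed sinusoidal spindle burst centred at center_s.
add_spindle <- function(x, center_s, dur, A, freq, fs) {
  half <- round(dur / 2 * fs)
  i0 <- round(center_s * fs) + 1L - half
  i1 <- i0 + 2L * half
  if (i0 < 1L || i1 > length(x)) return(x)
  tt <- ((i0:i1) - (round(center_s * fs) + 1L)) / fs
  x[i0:i1] <- x[i0:i1] + A * exp(-0.5 * (tt / (dur / 6))^2) *
    sin(2 * pi * freq * tt)
  x
}

# Simple nap architecture in 30-s epochs: brief wake/N1 onset, then
# alternating N2/N3 blocks. Recordings up to 2 min are scored N2
# throughout so that short test fixtures are fully eligible.
sim_hypnogram <- function(duration) {
  n_ep <- ceiling(duration / 30)
  if (duration <= 120) {
    stage <- rep("N2", n_ep)
  } else {
    stage <- character(n_ep)
    stage[1] <- "W"; stage[2] <- "N1"
    i <- 3L; block <- c("N2", "N3")
    b <- 1L
    while (i <= n_ep) {
      len <- min(10L, n_ep - i + 1L)
      stage[i:(i + len - 1L)] <- block[b]
      b <- 3L - b
      i <- i + len
    }
  }
  data.frame(epoch_start_s = (seq_len(n_ep) - 1) * 30, stage = stage)
}

# logical sample mask of stages
stage_mask <- function(hyp, stages, n_samples, fs) {
  m <- logical(n_samples)
  for (i in seq_len(nrow(hyp))) {
    if (!hyp$stage[i] %in% stages) next
    i0 <- round(hyp$epoch_start_s[i] * fs) + 1L
    i1 <- min(round((hyp$epoch_start_s[i] + 30) * fs), n_samples)
    if (i0 <= n_samples) m[i0:i1] <- TRUE
  }
  m
}

# Cue schedule: rounds of old-object / old-scene / control adjectives in
# shuffled order, ISI = cue_isi +/- cue_isi_jitter, restricted to N2/N3
# stretches with margins wide enough for the full post-cue analysis window.
sim_cue_schedule <- function(cfg, hyp, n_adj = 12L) {
  runs <- stage_runs(hyp, c("N2", "N3"), cfg$duration)
  adj <- data.frame(
    condition = rep(c("old-object", "old-scene", "control"), each = n_adj),
    category = rep(c("object", "scene", NA_character_), each = n_adj),
    adjective_id = c(sprintf("obj%02d", seq_len(n_adj)),
                     sprintf("scn%02d", seq_len(n_adj)),
                     sprintf("ctl%02d", seq_len(n_adj)))
  )
  out <- list(); round_i <- 1L; pos <- 0L; order_i <- sample.int(nrow(adj))
  for (r in seq_len(nrow(runs))) {
    t <- runs$start[r] + 2
    while (t + 3.2 <= runs$end[r]) {
      pos <- pos + 1L
      if (pos > nrow(adj)) {          # next cueing round, reshuffled
        pos <- 1L; round_i <- round_i + 1L
        order_i <- sample.int(nrow(adj))
      }
      a <- adj[order_i[pos], ]
      out[[length(out) + 1L]] <- data.frame(
        onset_s = t, condition = a$condition, category = a$category,
        adjective_id = a$adjective_id, round = round_i)
      t <- t + cfg$cue_isi +
        stats::runif(1, -cfg$cue_isi_jitter, cfg$cue_isi_jitter)
    }
  }
  if (length(out) == 0)
    return(data.frame(onset_s = numeric(0), condition = character(0),
                      category = character(0), adjective_id = character(0),
                      round = integer(0)))
  do.call(rbind, out)
}

stage_runs <- function(hyp, stages, duration) {
  in_run <- hyp$stage %in% stages
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = hyp$epoch_start_s[starts[keep]],
    end = pmin(hyp$epoch_start_s[ends[keep]] + 30, duration)
  )
}

# Condition-independent sustained evoked activity: a per-subject slow
# (1-2.5 Hz) waveform over 1.2-2.6 s post-cue, added on every trial with
# small latency jitter. This is the shared late evoked response all cues
# elicit; it gives between-category similarity a positive baseline that
# category-specific patterns dilute.
common_tail_wave <- function(cfg, offset = 1.2, span = 1.4) {
  m <- round(span * cfg$fs) + 1L
  tt <- (seq_len(m) - 1) / cfg$fs
  f1 <- stats::runif(1, 1, 2.5); ph1 <- stats::runif(1, 0, 2 * pi)
  f2 <- stats::runif(1, 1, 2.5); ph2 <- stats::runif(1, 0, 2 * pi)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
  list(offset = offset,
       wave = 2.4 * cfg$background_amplitude * taper *
         (sin(2 * pi * f1 * tt + ph1) + sin(2 * pi * f2 * tt + ph2)) / 2)
}

# Category-specific patterns: channel-weighted slow (<4 Hz) waveforms over
# the pattern window, Hann-tapered; identical on every trial of a category
# so trial-to-trial pattern similarity carries the category signal. The
# scene channel-weight vector is orthogonalized against the object one
# (anti-parallel when only one channel exists), so the two categories'
# patterns are maximally distinguishable and between-category similarity
# shrinks toward zero as the pattern amplitude grows.
category_patterns <- function(cfg, strength) {
  m <- round((cfg$pattern_window[2] - cfg$pattern_window[1]) * cfg$fs) + 1L
  tt <- (seq_len(m) - 1) / cfg$fs
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
  amp <- cfg$category_pattern_snr * strength * cfg$background_amplitude
  w_obj <- stats::rnorm(cfg$n_channels)
  w_obj <- w_obj / sqrt(sum(w_obj^2))
  if (cfg$n_channels > 1L) {
    w_scn <- stats::rnorm(cfg$n_channels)
    w_scn <- w_scn - sum(w_scn * w_obj) * w_obj
    w_scn <- w_scn / sqrt(sum(w_scn^2))
  } else {
    w_scn <- -w_obj
  }
  weights <- list(object = w_obj, scene = w_scn)
  out <- list()
  for (cat in c("object", "scene")) {
    f1 <- stats::runif(1, 1, 3.5); ph1 <- stats::runif(1, 0, 2 * pi)
    f2 <- stats::runif(1, 1, 3.5); ph2 <- stats::runif(1, 0, 2 * pi)
    wave <- (sin(2 * pi * f1 * tt + ph1) + sin(2 * pi * f2 * tt + ph2)) / 2
    out[[cat]] <- outer(weights[[cat]], amp * wave * taper)
  }
  out
}
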