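# shared fixture builders; everything is generated in code at test time

# minimal recording wrapper around a raw signal matrix
make_recording <- function(signal, fs = 200, labels = NULL, events = NULL,
                           stages = "N2") {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(signal)))
  rownames(signal) <- labels
  dur <- ncol(signal) / fs
  n_ep <- ceiling(dur / 30)
  hyp <- data.frame(epoch_start_s = (seq_len(n_ep) - 1) * 30,
                    stage = rep(stages, length.out = n_ep))
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), condition = character(0),
                         category = character(0), adjective_id = character(0),
                         round = integer(0))
  structure(list(signal = signal, fs = fs, channel_labels = labels,
                 hypnogram = hyp, events = events, subject = 1L),
            class = "nap_recording")
}

# epochs straight from a trials x channels x time array
make_epochs <- function(dat, fs = 200, tmin = -1, condition = NULL,
                        category = NULL) {
  n_tr <- dim(dat)[1]
  if (is.null(condition)) condition <- rep("old-object", n_tr)
  if (is.null(category))
    category <- ifelse(condition == "old-scene", "scene",
                       ifelse(condition == "old-object", "object", NA))
  meta <- data.frame(condition = condition, category = category,
                     adjective_id = sprintf("adj%03d", seq_len(n_tr)),
                     round = 1L, onset_s = seq_len(n_tr) * 10,
                     artifact_flag = FALSE)
  naptools:::new_epochs(dat, fs, paste0("ch", seq_len(dim(dat)[2])), tmin, meta,
                        subject = 1L)
}

# Hann-edged constant-amplitude burst, for detector fixtures
flat_burst <- function(n, fs, center_s, dur, amp, freq, edge = 0.1) {
  x <- numeric(n)
  i0 <- round((center_s - dur / 2) * fs) + 1L
  m <- round(dur * fs)
  tt <- (seq_len(m) - 1) / fs
  env <- rep(1, m)
  ne <- round(edge * fs)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(ne) / ne)
  env[seq_len(ne)] <- ramp
  env[m - ne + seq_len(ne)] <- rev(ramp)
  x[i0:(i0 + m - 1L)] <- amp * env * sin(2 * pi * freq * tt)
  x
}

# 3 s, 200 Hz constructed coupling segment: 1 Hz SO plus a 14 Hz burst
# whose Gaussian envelope is centred at a chosen time offset from the
# segment midpoint; so_shift moves the SO so its peak/trough sits at the
# midpoint
coupling_segment <- function(env_center = 0, so_shift = 0, sigma = 0.15,
                             so_amp = 75, sp_amp = 20) {
  tc <- (0:600) / 200 - 1.5
  so_amp * cos(2 * pi * (tc - so_shift)) +
    sp_amp * exp(-0.5 * ((tc - env_center) / sigma)^2) * sin(2 * pi * 14 * tc)
}

circ_err_deg <- function(a_deg, b_deg) {
  abs(deg(circ_dist(rad(a_deg), rad(b_deg))))
}
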