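# independent brute-force spindle detector used as oracle: the same
# envelope-threshold rule, implemented directly with plain loops
oracle_spindles <- function(rec, band = c(13, 16), thresh_sd = 1.25,
                            min_dur = 0.5, max_dur = 3, merge_gap = 0.1) {
  fs <- rec$fs
  out <- NULL
  for (ch in rec$channel_labels) {
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    n <- ncol(rec$signal)
    np <- max(1L, min(n - 2L, as.integer(3 * fs / band[1])))
    x0 <- rec$signal[ch, ] - mean(rec$signal[ch, ])
    xp <- c(2 * x0[1] - x0[(np + 1):2], x0, 2 * x0[n] - x0[(n - 1):(n - np)])
    xf <- as.numeric(signal::filtfilt(bf, xp))[(np + 1):(np + n)]
    nn <- length(xf); H <- numeric(nn)
    if (nn %% 2 == 0) { H[1] <- 1; H[nn / 2 + 1] <- 1; H[2:(nn / 2)] <- 2 }
    else { H[1] <- 1; H[2:((nn + 1) / 2)] <- 2 }
    env <- Mod(fft(fft(xf) * H, inverse = TRUE) / nn)
    thr <- mean(env) + thresh_sd * sd(env)
    above <- env > thr
    # collect runs by explicit scan, merging sub-threshold gaps < merge_gap
    runs <- list(); i <- 1
    while (i <= length(above)) {
      if (above[i]) {
        j <- i
        while (j < length(above) && above[j + 1]) j <- j + 1
        runs[[length(runs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (length(runs) > 1) {
      merged <- list(runs[[1]])
      for (k in 2:length(runs)) {
        last <- merged[[length(merged)]]
        if ((runs[[k]][1] - last[2] - 1) / fs < merge_gap)
          merged[[length(merged)]] <- c(last[1], runs[[k]][2])
        else merged[[length(merged) + 1]] <- runs[[k]]
      }
      runs <- merged
    }
    for (r in runs) {
      dur <- (r[2] - r[1] + 1) / fs
      if (dur < min_dur || dur > max_dur) next
      seg <- r[1]:r[2]
      pk <- seg[which.max(env[seg])]
      out <- rbind(out, data.frame(channel = ch, start_s = (r[1] - 1) / fs,
                                   end_s = (r[2] - 1) / fs,
                                   peak_s = (pk - 1) / fs))
    }
  }
  out
}

test_that("a clean burst yields exactly one spindle; short bursts are dropped", {
  set.seed(12)
  fs <- 200; n <- 30 * fs
  bg <- naptools:::one_over_f_noise(n, 1, 3)
  x <- bg + flat_burst(n, fs, center_s = 15, dur = 1, amp = 5 * sd(bg),
                       freq = 14)
  rec <- make_recording(rbind(x), fs, labels = "C3")
  ev <- detect_spindles(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "spindle_fast")
  expect_true(ev$start_s < 15 && ev$end_s > 15)   # contains burst midpoint
  expect_true(abs(ev$peak_s - 15) < 0.5)

  # supra-threshold (threshold ~0.9 uV here) but too short once the
  # envelope decays back below threshold
  x2 <- bg + flat_burst(n, fs, 15, dur = 0.3, amp = 1.5, freq = 14,
                        edge = 0.05)
  expect_equal(nrow(detect_spindles(make_recording(rbind(x2), fs,
                                                   labels = "C3"))), 0)
})

test_that("spindle detector agrees exactly with the brute-force oracle", {
  set.seed(27)
  fs <- 200; n <- 30 * fs
  x <- naptools:::one_over_f_noise(n, 1, 5) +
    flat_burst(n, fs, 8, 1.2, 12, 14) +
    flat_burst(n, fs, 21, 0.8, 10, 15)
  y <- naptools:::one_over_f_noise(n, 1, 5) + flat_burst(n, fs, 14, 1.0, 11, 13.5)
  rec <- make_recording(rbind(x, y), fs, labels = c("C3", "P3"))
  got <- detect_spindles(rec)
  want <- oracle_spindles(rec)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start_s, want$start_s, tolerance = 1e-12)
  expect_equal(got$end_s, want$end_s, tolerance = 1e-12)
  expect_equal(got$peak_s, want$peak_s, tolerance = 1e-12)
})

test_that("white noise alone yields a near-zero spindle rate", {
  set.seed(41)
  fs <- 200
  sig <- rbind(naptools:::one_over_f_noise(120 * fs, 0, 10),
               naptools:::one_over_f_noise(120 * fs, 0, 10))
  ev <- detect_spindles(make_recording(sig, fs, labels = c("C3", "P3")))
  expect_lte(nrow(ev), 6)    # < 1.5 events/min/channel from noise crossings
})

test_that("SO detector handles degenerate, scaled and too-fast sinusoids", {
  fs <- 200; n <- 120 * fs
  tt <- (seq_len(n) - 1) / fs
  pure <- 40 * sin(2 * pi * 1 * tt)
  expect_equal(nrow(detect_sos(make_recording(rbind(pure), fs, labels = "F3"))),
               0)   # identical cycles: nothing exceeds mean + 1.25 SD

  # one candidate cycle smoothly scaled to ~3x: the modulation covers the
  # trough (60.75 s) and following up-state peak (61.25 s) of the crossing
  # pair [60.5, 61.5], so exactly that candidate passes both thresholds
  amp <- 1 + 2 * exp(-0.5 * ((tt - 61) / 0.25)^2)
  one_big <- 40 * amp * sin(2 * pi * 1 * tt)
  ev <- detect_sos(make_recording(rbind(one_big), fs, labels = "F3"))
  expect_equal(nrow(ev), 1)
  expect_true(all(ev$peak_s > 60.5 & ev$peak_s < 61))
  # trough of sin cycle starting at 60 s sits at 60.75 s
  expect_equal(ev$peak_s, 60.75, tolerance = 0.05)

  fast <- 40 * sin(2 * pi * 3 * tt)
  expect_equal(nrow(detect_sos(make_recording(rbind(fast), fs, labels = "F3"))),
               0)   # 0.33 s crossing spacing fails the 0.8-2 s gate
})

test_that("SO candidate metrics match a brute-force zero-crossing oracle", {
  set.seed(61)
  fs <- 200; n <- 60 * fs
  x <- naptools:::one_over_f_noise(n, 1, 8)
  for (c0 in c(12, 30, 47))
    x <- x + naptools:::add_so(rbind(x * 0), c0, 1.4, 70, fs)[1, ]
  rec <- make_recording(rbind(x), fs, labels = "F3")
  got <- detect_sos(rec)

  xf <- filter_bandpass(x, c(0.5, 2), fs)
  pn <- which(xf[-n] > 0 & xf[-1] <= 0)
  cand <- NULL
  for (i in seq_len(length(pn) - 1)) {
    span <- (pn[i + 1] - pn[i]) / fs
    if (span < 0.8 || span > 2) next
    seg <- pn[i]:pn[i + 1]
    tr <- seg[which.min(xf[seg])]
    cand <- rbind(cand, data.frame(trough = xf[tr], t2p = max(xf[tr:pn[i + 1]]) -
                                     xf[tr], trough_s = (tr - 1) / fs))
  }
  keep <- -cand$trough > mean(-cand$trough) + 1.25 * sd(-cand$trough) &
    cand$t2p > mean(cand$t2p) + 1.25 * sd(cand$t2p)
  expect_equal(nrow(got), sum(keep))
  expect_equal(got$peak_s, cand$trough_s[keep], tolerance = 1e-12)
})

test_that("detection ignores DC offsets and padded artifact samples", {
  set.seed(71)
  fs <- 200; n <- 60 * fs
  x <- naptools:::one_over_f_noise(n, 1, 4) + flat_burst(n, fs, 30, 1, 15, 14)
  rec0 <- make_recording(rbind(x), fs, labels = "C3")
  rec_dc <- make_recording(rbind(x + 500), fs, labels = "C3")
  e0 <- detect_spindles(rec0); e_dc <- detect_spindles(rec_dc)
  expect_equal(e0$start_s, e_dc$start_s)
  expect_equal(e0$peak_s, e_dc$peak_s)

  mask <- rep(FALSE, n); mask[round(29.9 * fs)] <- TRUE   # artifact near burst
  e_mask <- detect_spindles(rec0, artifact_mask = mask)
  expect_false(any(e_mask$peak_s > 28.9 & e_mask$peak_s < 30.9))
})

test_that("post-cue window counts respect the closed-interval rule", {
  dat <- array(0, dim = c(4, 1, 800))
  ep <- make_epochs(dat, condition = c("old-object", "old-scene",
                                       "control", "control"))
  ep$metadata$onset_s <- c(10, 20, 30, 40)
  ev <- data.frame(kind = "spindle_fast", channel = "ch1",
                   start_s = c(11.2, 21.9, 30.1, 41.0),
                   end_s = c(12.2, 22.9, 31.1, 42.0),
                   peak_s = c(11.5, 22.5, 30.5, 41.6),   # 41.6 = edge 40+1.6
                   amplitude = 1)
  # window [1.5, 2.5]: trial peaks at +1.5, +2.5, +0.5, +1.6
  cnt <- count_events_window(ev, ep, window = c(1.5, 2.5), channels = "ch1")
  expect_equal(cnt$per_trial$count, c(1, 1, 0, 1))
  expect_equal(unname(cnt$per_condition["control"]), 0.5)
  expect_equal(cnt$old_minus_control, 1 - 0.5)

  expect_error(count_events_window(ev, ep, window = c(1.5, 5)), "outside")
  cnt0 <- count_events_window(ev[0, ], ep, window = c(1.5, 2.5),
                              channels = "ch1")
  expect_true(all(cnt0$per_trial$count == 0))
})

test_that("grand averages reproduce identical bursts and single events", {
  fs <- 200; n <- 60 * fs
  x <- numeric(n)
  for (c0 in c(10, 20, 30, 40)) x <- x + flat_burst(n, fs, c0, 1, 10, 14)
  rec <- make_recording(rbind(x), fs, labels = "C3")
  ev <- data.frame(channel = rep("C3", 4), peak_s = c(10, 20, 30, 40))
  ga <- grand_average_event(rec, ev, half_width = 1)
  expect_equal(ga$n_events, 4)
  seg <- x[(round(9 * fs) + 1):(round(11 * fs) + 1)]
  expect_equal(ga$average, seg, tolerance = 1e-12)

  ga1 <- grand_average_event(rec, ev[1, , drop = FALSE], half_width = 1)
  expect_equal(ga1$average, seg, tolerance = 1e-12)
  expect_error(grand_average_event(rec, data.frame(channel = "C3",
                                                   peak_s = 0.1), 1),
               "no event")
})

test_that("random carrier phases cancel in the average while envelopes add", {
  set.seed(83)
  fs <- 200; n <- 120 * fs
  x <- numeric(n)
  centers <- seq(5, 115, by = 2.5)
  for (c0 in centers) {
    ph <- runif(1, 0, 2 * pi)
    tt <- seq(-0.5, 0.5, by = 1 / fs)
    idx <- round((c0 - 0.5) * fs):(round((c0 - 0.5) * fs) + length(tt) - 1) + 1
    x[idx] <- x[idx] + 10 * exp(-0.5 * (tt / 0.17)^2) * sin(2 * pi * 14 * tt + ph)
  }
  rec <- make_recording(rbind(x), fs, labels = "C3")
  ga <- grand_average_event(rec, data.frame(channel = "C3", peak_s = centers),
                            half_width = 0.5)
  expect_lt(max(abs(ga$average)), 10 * 0.35)   # carrier attenuated
  env_avg <- mean(sapply(centers, function(c0) {
    max(abs(x[(round((c0 - 0.1) * fs)):(round((c0 + 0.1) * fs))]))
  }))
  expect_gt(env_avg, 8)                        # per-event envelope intact
})
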