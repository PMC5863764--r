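test_that("generation is bit-identical under a fixed config and seed", {
  cfg <- sim_config(duration = 150, seed = 5)
  g1 <- generate_recording(cfg, subject = 2)
  g2 <- generate_recording(cfg, subject = 2)
  expect_identical(g1$recording$signal, g2$recording$signal)
  expect_identical(g1$truth, g2$truth)
  b1 <- generate_behavior(cfg, g1$truth)
  b2 <- generate_behavior(cfg, g2$truth)
  expect_identical(b1, b2)
})

test_that("a no-event config injects nothing and leaves the spindle band flat", {
  cfg <- sim_config(duration = 150, so_rate = 0, spindle_rate = 0,
                    so_amplitude = 0, evoked_spindle_prob = 0,
                    category_pattern_snr = 0, seed = 9)
  g <- generate_recording(cfg, 1)
  expect_equal(nrow(g$truth$so), 0)
  expect_equal(nrow(g$truth$spindles), 0)
  # 13-16 Hz envelope indistinguishable from a pure-noise realization
  env_rec <- band_envelope(g$recording$signal[1, ], c(13, 16), cfg$fs)
  set.seed(1)
  env_ref <- band_envelope(naptools:::one_over_f_noise(ncol(g$recording$signal),
                                                       1, 15), c(13, 16), cfg$fs)
  expect_lt(abs(mean(env_rec) / mean(env_ref) - 1), 0.2)
  expect_lt(max(env_rec) / mean(env_rec), max(env_ref) / mean(env_ref) * 1.5)
})

test_that("degenerate von Mises concentration pins injected phases", {
  cfg <- sim_config(duration = 300, coupling_concentration = 1e7,
                    coupling_phase = 0, evoked_spindle_prob = 0, seed = 3)
  g <- generate_recording(cfg, 1)
  ph <- g$truth$spindles$phase_rad
  ph <- ph[!is.na(ph)]
  expect_gt(length(ph), 5)
  expect_lt(sqrt(-2 * log(circ_mean(ph)$r)), 1e-3)  # circular SD -> 0
})

test_that("injected events respect recording bounds, labels and stages", {
  cfg <- sim_config(duration = 400, seed = 11)
  g <- generate_recording(cfg, 1)
  dur <- ncol(g$recording$signal) / cfg$fs
  expect_true(all(g$truth$so$start_s >= 0 & g$truth$so$peak_s <= dur))
  expect_true(all(g$truth$spindles$center_s > 0 &
                  g$truth$spindles$center_s < dur))
  expect_true(all(g$truth$spindles$channel %in% cfg$channel_labels))
  expect_true(all(g$recording$events$condition %in%
                  c("old-object", "old-scene", "control")))
  # cue onsets only in N2/N3 epochs
  hyp <- g$recording$hypnogram
  stage_at <- hyp$stage[findInterval(g$recording$events$onset_s,
                                     hyp$epoch_start_s)]
  expect_true(all(stage_at %in% c("N2", "N3")))
})

test_that("old cues evoke more ground-truth spindles than control cues", {
  cfg <- sim_config(duration = 900, evoked_spindle_gain_old = 1.5, seed = 21)
  g <- generate_recording(cfg, 1)
  sp <- g$truth$spindles[g$truth$spindles$evoked, ]
  cues_per_cond <- table(g$recording$events$condition)
  ev_per_cue <- table(sp$condition[!duplicated(sp$cue_index)])
  rate_old <- sum(ev_per_cue[c("old-object", "old-scene")]) /
    sum(cues_per_cond[c("old-object", "old-scene")])
  rate_ctl <- ev_per_cue["control"] / cues_per_cond["control"]
  expect_gt(rate_old, rate_ctl)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(coupling_phase = 200), "coupling_phase")
  expect_error(sim_config(spindle_freq = 11), "13")
  expect_error(sim_config(fs = 20), "twice the spindle frequency")
  expect_error(sim_config(spindle_duration = 0.3))
  expect_error(generate_recording(sim_config(duration = 5, seed = 1)),
               "too short")
})

test_that("behavioral generator recovers a null effect and respects ceilings", {
  cfg0 <- sim_config(behavior_effect = 0, seed = 13)
  ben <- vapply(1:30, function(s) {
    tmr_benefit(generate_behavior(cfg0, list(subject = s, true_benefit = 0)))
  }, 0)
  expect_lt(abs(mean(ben)), 0.06)   # binomial error at ~25 items/side, n=30

  cfg1 <- sim_config(seed = 13)
  tab <- generate_behavior(cfg1, list(subject = 1, true_benefit = 0),
                           p_t2 = 1, p_t3 = 1)
  expect_equal(retention(tab, "t1", "t2", "all"), 1)
  expect_equal(retention(tab, "t2", "t3", "all"), 1)

  expect_warning(
    generate_behavior(cfg1, list(subject = 2, true_benefit = 0.9)),
    "clipped")
})

test_that("inclusion criterion guarantees at least 14 recalled per category", {
  cfg <- sim_config(n_pairs_per_category = 20, seed = 2)
  for (s in 1:5) {
    tab <- generate_behavior(cfg, list(subject = s, true_benefit = 0.1),
                             p_t1 = 0.3)
    ok <- tab$t1 & tab$categorisation_correct
    expect_gte(sum(ok & tab$category == "object"), 14)
    expect_gte(sum(ok & tab$category == "scene"), 14)
  }
})

test_that("realized benefit tracks true distinctiveness across subjects", {
  cfg <- sim_config(behavior_effect = 0.25, seed = 17)
  u <- runif(40, 0.6, 1.4)   # subject-level pattern strengths
  ben <- vapply(seq_along(u), function(s) {
    tmr_benefit(generate_behavior(cfg, list(subject = s,
                                            true_benefit = 0.25 * u[s])))
  }, 0)
  expect_gt(cor(u, ben, method = "spearman"), 0.3)
})

test_that("fixtures round-trip through disk within EDF quantization", {
  cfg <- sim_config(duration = 150, seed = 4)
  g <- generate_recording(cfg, 1)
  dir <- tempfile()
  paths <- write_fixture(g$recording, g$truth, dir)
  expect_true(all(file.exists(paths)))
  rec <- read_recording(paths["edf"], paths["events"], paths["hypnogram"],
                        expected_labels = cfg$channel_labels)
  phys_max <- max(1, ceiling(max(abs(g$recording$signal))))
  qstep <- 2 * phys_max / 65535
  expect_lte(max(abs(rec$signal - g$recording$signal)), qstep)
  expect_identical(rec$channel_labels, cfg$channel_labels)
  expect_equal(rec$events$onset_s, g$recording$events$onset_s)

  # empty event list still yields a valid header-only TSV
  g$recording$events <- g$recording$events[0, ]
  p2 <- write_fixture(g$recording, NULL, tempfile())
  ev <- read.delim(p2["events"])
  expect_equal(nrow(ev), 0)
  expect_true(all(c("onset_s", "condition") %in% names(ev)))
})
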