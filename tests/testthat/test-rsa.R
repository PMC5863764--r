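test_that("feature vectors have the configured geometry", {
  set.seed(2)
  dat <- array(rnorm(4 * 8 * 800), dim = c(4, 8, 800))
  ep <- make_epochs(dat)
  fe <- build_feature_vectors(ep)
  expect_equal(dim(fe$features)[2], 8 * 41)        # 41 samples per channel
  expect_equal(length(fe$times), 271)              # -0.2..2.5 s in 10 ms steps
  expect_equal(fe$n_per_channel, 41)

  expect_error(build_feature_vectors(ep, tmax = 3.2),
               "exceeds epoch bounds")
})

test_that("constant signals surface as zero-variance cells", {
  dat <- array(1, dim = c(3, 2, 800))
  fe <- build_feature_vectors(make_epochs(dat), step_ms = 500)
  expect_warning(cm <- similarity_matrix(fe$features[, , 1]), "zero-variance")
  expect_true(all(is.na(cm[upper.tri(cm)])))
})

test_that("similarity matrix equals an independent Spearman computation", {
  # hand-listed rank patterns
  f <- rbind(c(1, 2, 3, 4, 5, 6),
             c(2, 4, 6, 8, 10, 12),     # monotone transform of row 1
             c(6, 5, 4, 3, 2, 1),       # reversed
             c(1, 3, 2, 5, 4, 6),
             c(2, 2, 2, 5, 5, 9))       # ties
  cm <- similarity_matrix(f)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  # brute-force oracle: Pearson on average ranks, written out directly
  sp <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  for (i in 1:5) for (j in 1:5)
    expect_equal(cm[i, j], sp(f[i, ], f[j, ]), tolerance = 1e-12)
  expect_true(isSymmetric(cm))
  expect_equal(diag(cm), rep(1, 5))
})

test_that("cell bookkeeping removes self- and same-adjective pairs", {
  md <- data.frame(adjective_id = c("a", "b", "a", "c"),
                   category = c("object", "object", "scene", "scene"))
  m <- naptools:::rsa_cell_mask(md)
  expect_false(any(diag(m)))
  expect_false(any(m[lower.tri(m)]))
  expect_false(m[1, 3])            # same adjective across rounds
  expect_true(m[1, 2]); expect_true(m[2, 4])
})

test_that("constructed category structure separates within from between", {
  set.seed(9)
  n_per <- 6; n_feat <- 80; n_times <- 3
  pat_o <- rnorm(n_feat); pat_s <- rnorm(n_feat)
  feats <- array(NA_real_, dim = c(2 * n_per, n_feat, n_times))
  for (i in seq_len(2 * n_per)) {
    base <- if (i <= n_per) pat_o else pat_s
    for (t in seq_len(n_times)) feats[i, , t] <- base + rnorm(n_feat, sd = 0.1)
  }
  fe <- list(features = feats, times = c(0.1, 0.2, 0.3),
             metadata = data.frame(
               adjective_id = sprintf("a%02d", seq_len(2 * n_per)),
               category = rep(c("object", "scene"), each = n_per)),
             n_per_channel = 40)
  ser <- within_between_series(fe, seed = 1)
  expect_true(all(ser$within > 1))          # z(rho ~ 1) is large
  expect_true(all(abs(ser$between) < 0.3))

  # permuted labels kill the separation in expectation
  set.seed(4)
  diffs <- replicate(20, {
    fe_p <- fe
    fe_p$metadata$category <- sample(fe$metadata$category)
    s <- within_between_series(fe_p, seed = 1)
    mean(s$within - s$between)
  })
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("equal cell counts make sub-selection a no-op for any seed", {
  set.seed(11)
  feats <- array(rnorm(4 * 50 * 2), dim = c(4, 50, 2))
  fe <- list(features = feats, times = c(0, 0.1),
             metadata = data.frame(adjective_id = c("a", "b", "c", "d"),
                                   category = c("object", "object",
                                                "scene", "scene")),
             n_per_channel = 25)
  # 1 within-object + 1 within-scene = 2 within; 4 between -> subsampled
  s1 <- within_between_series(fe, seed = 1)
  s2 <- within_between_series(fe, seed = 99)
  expect_identical(s1$within, s2$within)   # within cells never subsampled here
})

test_that("distinctiveness maps orthogonal and identical categories correctly", {
  ser <- data.frame(time = seq(1.5, 2.5, by = 0.1),
                    within = 1, between = 0)
  expect_equal(distinctiveness(ser, c(1.76, 2.06))$value, 1)
  ser$between <- 1
  expect_equal(distinctiveness(ser, c(1.76, 2.06))$value, 0)
  expect_error(distinctiveness(ser, c(5, 6)), "empty window")
})

test_that("distinctiveness grows with the injected pattern amplitude", {
  snr_levels <- c(0, 1.5, 3)
  d <- sapply(snr_levels, function(snr) {
    mean(sapply(1:8, function(s) {
      cfg <- sim_config(n_channels = 2, channel_labels = c("C3", "P3"),
                        category_pattern_snr = snr, seed = 31)
      ep <- simulate_epochs(cfg, n_trials = 10, subject = s)
      fe <- build_feature_vectors(ep, step_ms = 50)
      distinctiveness(within_between_series(fe, seed = s))$value
    }))
  })
  expect_true(all(diff(d) > 0))
})

test_that("pre-cue similarity carries no category information", {
  cfg <- sim_config(n_channels = 2, channel_labels = c("C3", "P3"),
                    category_pattern_snr = 3, seed = 41)
  dif <- sapply(1:6, function(s) {
    ep <- simulate_epochs(cfg, n_trials = 10, subject = s)
    fe <- build_feature_vectors(ep, step_ms = 50)
    ser <- within_between_series(fe, seed = s)
    pre <- ser$time <= 0
    mean(ser$within[pre] - ser$between[pre])
  })
  expect_lt(abs(mean(dif)), 0.05)
})

test_that("brain-behavior correlation responds to monotone structure", {
  d <- c(0.1, 0.25, 0.3, 0.42, 0.55, 0.61)
  expect_equal(brain_behavior_correlation(d, d^2 + 1)$rho, 1)
  expect_equal(brain_behavior_correlation(d, -d)$rho, -1)
  expect_error(brain_behavior_correlation(rep(1, 6), d), "tied")
  expect_error(brain_behavior_correlation(d[1:4], d[1:4]), "at least 5")

  set.seed(3)
  rej <- mean(replicate(200, {
    brain_behavior_correlation(rnorm(10), rnorm(10))$p < 0.05
  }))
  expect_gt(rej, 0.0198); expect_lt(rej, 0.0802)
})
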