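test_that("paired t map matches the textbook statistic point by point", {
  set.seed(14)
  a <- array(rnorm(8 * 5 * 6, mean = 0.4), dim = c(8, 5, 6))
  b <- array(rnorm(8 * 5 * 6), dim = c(8, 5, 6))
  tm <- paired_t_map(a, b)
  expect_equal(dim(tm), c(5, 6))
  for (i in c(1, 3, 5)) for (j in c(2, 6)) {
    want <- unname(t.test(a[, i, j], b[, i, j], paired = TRUE)$statistic)
    expect_equal(tm[i, j], want, tolerance = 1e-10)
  }
  expect_true(all(paired_t_map(a, a) == 0))
  expect_equal(paired_t_map(b, a), -tm, tolerance = 1e-10)
})

test_that("cluster formation follows the declared adjacency", {
  tg <- c(0, 3, 0, 3, 3, 0, -3, -3)
  cl <- form_clusters(array(tg, dim = 8), threshold = 2)
  expect_length(cl, 3)
  masses <- sort(vapply(cl, `[[`, 0, "mass"))
  expect_equal(masses, c(-6, 3, 6))

  # hand-drawn grid versus a brute-force component search
  tg2 <- array(0, dim = c(3, 3))
  tg2[1, 1] <- 4; tg2[1, 2] <- 4; tg2[3, 3] <- 5; tg2[3, 1] <- 4.5
  cl2 <- form_clusters(tg2, threshold = 2)
  supra <- which(tg2 > 2)
  # brute force: repeatedly merge any two supra points differing by one
  # step in exactly one dimension
  comp <- as.list(supra)
  repeat {
    merged <- FALSE
    for (i in seq_along(comp)) for (j in seq_along(comp)) {
      if (i >= j || merged) next
      pts_i <- arrayInd(comp[[i]], dim(tg2)); pts_j <- arrayInd(comp[[j]], dim(tg2))
      touch <- any(outer(seq_len(nrow(pts_i)), seq_len(nrow(pts_j)),
                         Vectorize(function(a_, b_)
                           sum(abs(pts_i[a_, ] - pts_j[b_, ])) == 1)))
      if (touch) {
        comp[[i]] <- c(comp[[i]], comp[[j]]); comp[[j]] <- NULL
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  expect_equal(length(cl2), length(comp))
  got_sets <- lapply(cl2, function(c_) sort(c_$indices))
  want_sets <- lapply(comp, sort)
  expect_setequal(got_sets, want_sets)

  expect_length(form_clusters(array(0.5, dim = c(2, 2)), 2), 0)
})

test_that("montage adjacency joins hemispheres through homologous pairs", {
  adj <- montage_adjacency()
  expect_setequal(adj$C3, c("F3", "P3", "C4"))
  expect_setequal(adj$O1, c("P3", "O2"))
  # symmetric relation
  for (ch in names(adj)) for (nb in adj[[ch]])
    expect_true(ch %in% adj[[nb]])

  # channel x time grid: same channel adjacent in time, neighbours at the
  # same time point
  tg <- array(0, dim = c(8, 4))
  tg[1, 2] <- 3            # F3
  tg[3, 2] <- 3            # C3 (neighbour of F3)
  tg[8, 2] <- 3            # O2 (not a neighbour of F3/C3)
  cl <- form_clusters(tg, 2, channel_dim = 1,
                      channel_labels = c("F3", "F4", "C3", "C4",
                                         "P3", "P4", "O1", "O2"),
                      channel_adjacency = adj)
  expect_length(cl, 2)
})

test_that("permutation p-values saturate, stay empty, and shrink with effect", {
  set.seed(21)
  n_sub <- 10; n_t <- 30
  noise_a <- matrix(rnorm(n_sub * n_t), n_sub)
  noise_b <- matrix(rnorm(n_sub * n_t), n_sub)

  res0 <- permutation_p(noise_a, noise_a, n_perm = 200, seed = 1)
  expect_length(res0$clusters, 0)

  big <- noise_a; big[, 10:20] <- big[, 10:20] + 5
  res_big <- permutation_p(big, noise_b, n_perm = 200, seed = 1)
  expect_equal(min(vapply(res_big$clusters, `[[`, 0, "p")), 1 / 201)

  small <- noise_a; small[, 10:14] <- small[, 10:14] + 0.75
  medium <- noise_a; medium[, 10:14] <- medium[, 10:14] + 1.5
  p_small <- min(c(1, vapply(permutation_p(small, noise_b, 500, seed = 2)$clusters,
                             `[[`, 0, "p")))
  p_medium <- min(c(1, vapply(permutation_p(medium, noise_b, 500, seed = 2)$clusters,
                              `[[`, 0, "p")))
  expect_lte(p_medium, p_small)

  expect_warning(permutation_p(noise_a, noise_b, n_perm = 50, seed = 1),
                 "fewer than 100")
})

test_that("inference is invariant to channel relabelling", {
  set.seed(31)
  labs <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  n_sub <- 8
  a <- array(rnorm(n_sub * 8 * 12), dim = c(n_sub, 8, 12))
  a[, 3, 4:7] <- a[, 3, 4:7] + 1.5
  b <- array(rnorm(n_sub * 8 * 12), dim = c(n_sub, 8, 12))
  adj <- montage_adjacency()
  res1 <- permutation_p(a, b, n_perm = 200, seed = 5, channel_dim = 1,
                        channel_labels = labs, channel_adjacency = adj)
  perm <- c(5, 1, 7, 3, 2, 8, 4, 6)
  res2 <- permutation_p(a[, perm, ], b[, perm, ], n_perm = 200, seed = 5,
                        channel_dim = 1, channel_labels = labs[perm],
                        channel_adjacency = adj)
  p1 <- sort(vapply(res1$clusters, `[[`, 0, "p"))
  p2 <- sort(vapply(res2$clusters, `[[`, 0, "p"))
  expect_equal(p1, p2)
  expect_equal(sort(vapply(res1$clusters, `[[`, 0, "mass")),
               sort(vapply(res2$clusters, `[[`, 0, "mass")), tolerance = 1e-10)
})
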