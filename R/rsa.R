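#' Sliding-window spatiotemporal feature vectors
#'
#' At each centre time from `tmin` to `tmax` (10 ms steps by default) the
#' feature vector concatenates all channels over a 200 ms window: at
#' 200 Hz that is 41 samples per channel (centre +/- 20), i.e. 8 x 41 = 328
#' features for the standard montage. Epochs are expected to be high-pass
#' filtered (0.5 Hz) beforehand; an optional low-pass pre-filter restricts
#' the features to slow components.
#'
#' @param epochs a `nap_epochs`.
#' @param window_ms window span in ms (realized as an odd sample count).
#' @param step_ms centre spacing in ms.
#' @param tmin,tmax centre-time range in seconds (closed interval).
#' @param lowpass optional low-pass cutoff in Hz applied per trial/channel
#'   before windowing (NULL = none).
#' @return list of class `nap_features`: `features` (trials x n_features x
#'   n_times array), `times`, `metadata`, `n_per_channel`.
#' @export
build_feature_vectors <- function(epochs, window_ms = 200, step_ms = 10,
                                  tmin = -0.2, tmax = 2.5, lowpass = NULL) {
  fs <- epochs$fs
  half <- round(window_ms / 1000 * fs / 2)
  n_win <- 2L * half + 1L
  centers <- seq(tmin, tmax, by = step_ms / 1000)
  c_idx <- vapply(centers, function(tc) which.min(abs(epochs$times - tc)), 0L)
  n_t <- dim(epochs$data)[3]
  if (any(c_idx - half < 1L) || any(c_idx + half > n_t))
    stop("build_feature_vectors: window exceeds epoch bounds at requested centres")
  dat <- epochs$data
  if (!is.null(lowpass)) {
    for (tr in seq_len(dim(dat)[1]))
      for (ch in seq_len(dim(dat)[2]))
        dat[tr, ch, ] <- filter_lowpass(dat[tr, ch, ], lowpass, fs)
  }
  keep <- retained_idx(epochs)
  nch <- dim(dat)[2]
  feats <- array(NA_real_,
                 dim = c(length(keep), nch * n_win, length(centers)))
  for (ti in seq_along(centers)) {
    idx <- (c_idx[ti] - half):(c_idx[ti] + half)
    for (k in seq_along(keep))
      feats[k, , ti] <- as.numeric(t(dat[keep[k], , idx]))
  }
  list(features = feats, times = centers,
       metadata = epochs$metadata[keep, , drop = FALSE],
       n_per_channel = n_win)
}

#' Trial-by-trial Spearman similarity matrix
#'
#' Symmetric matrix of Spearman rank correlations between trial feature
#' vectors at one time point. Zero-variance vectors produce missing cells
#' with a warning. Exclusions (diagonal, lower triangle, same-adjective
#' cross-round cells) are applied downstream by [within_between_series()].
#'
#' @param featmat trials x features numeric matrix.
#' @return trials x trials correlation matrix.
#' @export
similarity_matrix <- function(featmat) {
  if (nrow(featmat) < 2L) stop("similarity_matrix: need at least 2 trials")
  v <- apply(featmat, 1, stats::var)
  bad <- which(v == 0 | is.na(v))
  if (length(bad) > 0)
    warning("similarity_matrix: zero-variance feature vector(s); cells set missing")
  r <- t(apply(featmat, 1, rank))
  cm <- suppressWarnings(stats::cor(t(r)))
  if (length(bad) > 0) { cm[bad, ] <- NA_real_; cm[, bad] <- NA_real_ }
  cm
}

# valid upper-triangle cell mask given trial metadata: removes diagonal,
# lower triangle, and same-adjective pairs across cueing rounds
rsa_cell_mask <- function(metadata) {
  n <- nrow(metadata)
  m <- upper.tri(matrix(0, n, n))
  same_adj <- outer(metadata$adjective_id, metadata$adjective_id, "==")
  m & !same_adj
}

#' Within- and between-category similarity time series
#'
#' For each time point: build the trial similarity matrix, keep valid
#' upper-triangle cells, average object-object and scene-scene cells
#' (within) and object-scene cells (between), after randomly sub-selecting
#' cells from the majority class so both means use the same number of
#' cells. Means are Fisher z-transformed (rho clipped to +/-(1 - 1e-6)).
#'
#' @param feats a `nap_features` from [build_feature_vectors()].
#' @param seed RNG seed for the cell sub-selection.
#' @return data.frame of class `nap_similarity`: `time`, `within`,
#'   `between` (Fisher-z units), `n_cells`.
#' @export
within_between_series <- function(feats, seed = 1L) {
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  md <- feats$metadata
  if (!all(c("object", "scene") %in% md$category))
    stop("within_between_series: both categories required")
  mask <- rsa_cell_mask(md)
  cat_ <- md$category
  ww <- mask & outer(cat_, cat_, "==") &
    outer(cat_ %in% c("object", "scene"), cat_ %in% c("object", "scene"), "&")
  bb <- mask & outer(cat_, cat_, "!=") &
    outer(cat_ %in% c("object", "scene"), cat_ %in% c("object", "scene"), "&")
  w_idx <- which(ww); b_idx <- which(bb)
  set.seed(seed)
  n_cell <- min(length(w_idx), length(b_idx))
  if (n_cell < 1L) stop("within_between_series: a category is absent")
  if (length(w_idx) > n_cell) w_idx <- sample(w_idx, n_cell)
  if (length(b_idx) > n_cell) b_idx <- sample(b_idx, n_cell)
  fz <- function(r) atanh(pmin(pmax(r, -1 + 1e-6), 1 - 1e-6))
  out <- data.frame(time = feats$times, within = NA_real_, between = NA_real_,
                    n_cells = n_cell)
  for (ti in seq_along(feats$times)) {
    cm <- similarity_matrix(feats$features[, , ti])
    out$within[ti] <- fz(mean(cm[w_idx], na.rm = TRUE))
    out$between[ti] <- fz(mean(cm[b_idx], na.rm = TRUE))
  }
  class(out) <- c("nap_similarity", "data.frame")
  out
}

#' Category distinctiveness
#'
#' 1 minus the mean between-category similarity over a time window; the
#' decoding-fidelity score correlated with spindle counts and with the
#' behavioral benefit of cueing.
#'
#' @param series a `nap_similarity`.
#' @param window length-2 closed window in seconds (default the 1.76-2.06 s
#'   effect window).
#' @return list with `value` and `window`.
#' @export
distinctiveness <- function(series, window = c(1.76, 2.06)) {
  idx <- which(series$time >= window[1] & series$time <= window[2])
  if (length(idx) == 0) stop("distinctiveness: empty window")
  list(value = 1 - mean(series$between[idx]), window = window)
}

#' Brain-behavior Spearman correlation
#'
#' Rank correlation across subjects between a neural score (e.g. category
#' distinctiveness) and a behavioral score (e.g. TMR benefit).
#'
#' @param neural,behavior numeric vectors, one value per subject (>= 5).
#' @return list with `rho`, `p`, `n`.
#' @export
brain_behavior_correlation <- function(neural, behavior) {
  ok <- stats::complete.cases(neural, behavior)
  if (sum(ok) < 5L) stop("brain_behavior_correlation: need at least 5 subjects")
  if (stats::sd(rank(neural[ok])) == 0 || stats::sd(rank(behavior[ok])) == 0)
    stop("brain_behavior_correlation: all ranks tied; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(neural[ok], behavior[ok],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

# within/between cell means for a similarity matrix stack given category
# labels; cells below/on the diagonal and same-adjective pairs are already
# excluded by `mask`. Returns Fisher-z series for each.
wb_means <- function(mats, mask, categories, seed) {
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  ww <- mask & outer(categories, categories, "==")
  bb <- mask & outer(categories, categories, "!=")
  w_idx <- which(ww); b_idx <- which(bb)
  n_cell <- min(length(w_idx), length(b_idx))
  set.seed(seed)
  if (length(w_idx) > n_cell) w_idx <- sample(w_idx, n_cell)
  if (length(b_idx) > n_cell) b_idx <- sample(b_idx, n_cell)
  fz <- function(r) atanh(pmin(pmax(r, -1 + 1e-6), 1 - 1e-6))
  w <- vapply(mats, function(m) fz(mean(m[w_idx], na.rm = TRUE)), 0)
  b <- vapply(mats, function(m) fz(mean(m[b_idx], na.rm = TRUE)), 0)
  list(within = w, between = b)
}

#' Cluster permutation test for within- versus between-category similarity
#'
#' Group-level inference over the within-minus-between similarity time
#' course. Because that contrast is a squared distance between category
#' centroids, its null distribution is right-skewed rather than symmetric,
#' and subject-level sign flips (appropriate for paired condition
#' contrasts such as old versus control TFRs) are anticonservative here.
#' The exact null for representational contrasts instead permutes the
#' trial category labels within each subject: per permutation the
#' within/between cell sets are rebuilt from each subject's (fixed)
#' similarity matrices, the paired t map across subjects is recomputed
#' over time, and the maximum absolute cluster mass forms the reference
#' distribution.
#'
#' @param feat_list list of `nap_features`, one per subject.
#' @param n_perm number of label permutations.
#' @param seed RNG seed (drives both permutations and cell sub-selection).
#' @param threshold cluster-forming |t| threshold; default two-sided
#'   alpha = 0.05 for the subject count.
#' @return a `nap_clusters` (time-only grid) plus `series`: per-subject
#'   observed within/between series.
#' @export
rsa_cluster_test <- function(feat_list, n_perm = 1000, seed = 1L,
                             threshold = NULL) {
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  n_sub <- length(feat_list)
  if (n_sub < 2L) stop("rsa_cluster_test: need at least 2 subjects")
  times <- feat_list[[1]]$times
  prep <- lapply(seq_len(n_sub), function(s) {
    fe <- feat_list[[s]]
    mats <- lapply(seq_along(fe$times), function(ti)
      similarity_matrix(fe$features[, , ti]))
    list(mats = mats, mask = rsa_cell_mask(fe$metadata),
         cats = fe$metadata$category)
  })
  obs <- lapply(seq_len(n_sub), function(s)
    wb_means(prep[[s]]$mats, prep[[s]]$mask, prep[[s]]$cats, seed + s))
  d_obs <- do.call(rbind, lapply(obs, function(o) o$within - o$between))
  if (is.null(threshold)) threshold <- stats::qt(0.975, df = n_sub - 1)
  t_of <- function(d) {
    m <- colMeans(d)
    s2 <- (colSums(d^2) - n_sub * m^2) / (n_sub - 1)
    s2[s2 < 0] <- 0
    t <- m / sqrt(s2 / n_sub)
    t[s2 == 0 & m == 0] <- 0
    t
  }
  obs_cl <- form_clusters(array(t_of(d_obs), dim = length(times)), threshold)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    d_b <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
      perm_cats <- sample(prep[[s]]$cats)
      o <- wb_means(prep[[s]]$mats, prep[[s]]$mask, perm_cats,
                    seed + s + b * 131L)
      o$within - o$between
    }))
    cl <- form_clusters(array(t_of(d_b), dim = length(times)), threshold)
    null_max[b] <- if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
  }
  for (i in seq_along(obs_cl))
    obs_cl[[i]]$p <- (1 + sum(null_max >= abs(obs_cl[[i]]$mass))) / (n_perm + 1)
  structure(list(clusters = obs_cl,
                 t_grid = array(t_of(d_obs), dim = length(times)),
                 threshold = threshold, n_perm = n_perm, null_max = null_max,
                 times = times,
                 series = obs), class = "nap_clusters")
}
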