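#' Channel adjacency for the 8-channel 10-20 montage
#'
#' Fixed hand-coded neighbour list: anterior-posterior chains within each
#' hemisphere (F3-C3-P3-O1, F4-C4-P4-O2) plus homologous cross-hemisphere
#' pairs (F3-F4, C3-C4, P3-P4, O1-O2).
#'
#' @return named list: for each channel, its neighbours.
#' @export
montage_adjacency <- function() {
  pairs <- list(c("F3", "C3"), c("C3", "P3"), c("P3", "O1"),
                c("F4", "C4"), c("C4", "P4"), c("P4", "O2"),
                c("F3", "F4"), c("C3", "C4"), c("P3", "P4"), c("O1", "O2"))
  chans <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  adj <- stats::setNames(vector("list", length(chans)), chans)
  for (p in pairs) {
    adj[[p[1]]] <- c(adj[[p[1]]], p[2])
    adj[[p[2]]] <- c(adj[[p[2]]], p[1])
  }
  adj
}

#' Paired-samples t map
#'
#' Per grid point, the paired t statistic across subjects of
#' `a - b`. Points with zero variance of the differences get a +/-Inf
#' sentinel (and a message when any occur).
#'
#' @param a,b arrays whose first dimension is subjects, remaining
#'   dimensions the analysis grid (time; channel x time; channel x
#'   frequency x time). Vectors are treated as subjects x 1.
#' @return t-value array with the grid dimensions.
#' @export
paired_t_map <- function(a, b) {
  if (is.null(dim(a))) { a <- matrix(a); b <- matrix(b) }
  if (!identical(dim(a), dim(b))) stop("paired_t_map: mismatched grids")
  n <- dim(a)[1]
  if (n < 2L) stop("paired_t_map: need at least 2 subjects")
  grid_dim <- dim(a)[-1]
  d <- matrix(a - b, nrow = n)
  m <- colMeans(d)
  s2 <- (colSums(d^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  t <- m / sqrt(s2 / n)
  zv <- s2 == 0
  if (any(zv)) {
    message(sprintf("paired_t_map: %d grid point(s) with zero variance; +/-Inf sentinel",
                    sum(zv)))
    t[zv & m == 0] <- 0
  }
  array(t, dim = if (length(grid_dim)) grid_dim else 1L)
}

# neighbours of a grid point (vector of dim indices) under lattice
# adjacency, with an optional channel dimension using a neighbour list
grid_neighbours <- function(pt, dims, channel_dim = NULL, channel_nb = NULL) {
  out <- list()
  for (d in seq_along(dims)) {
    if (!is.null(channel_dim) && d == channel_dim) {
      for (nb in channel_nb[[pt[d]]]) {
        q <- pt; q[d] <- nb
        out[[length(out) + 1L]] <- q
      }
    } else {
      for (step in c(-1L, 1L)) {
        v <- pt[d] + step
        if (v >= 1L && v <= dims[d]) {
          q <- pt; q[d] <- v
          out[[length(out) + 1L]] <- q
        }
      }
    }
  }
  out
}

#' Form supra-threshold clusters
#'
#' Groups grid points with |t| above the cluster-forming threshold into
#' connected components, separately per polarity. Adjacency: +/-1 grid
#' steps along time and frequency; montage neighbour list along an
#' optional channel dimension. Cluster mass is the sum of member t values.
#'
#' @param t_grid t-value array from [paired_t_map()].
#' @param threshold positive cluster-forming threshold on |t|.
#' @param channel_dim index of the channel dimension of `t_grid` (NULL if
#'   none).
#' @param channel_labels channel labels along that dimension.
#' @param channel_adjacency neighbour list as from [montage_adjacency()].
#' @return list of clusters, each with `points` (matrix of array indices),
#'   `mass`, `polarity` ("pos"/"neg"). Empty list when nothing is
#'   supra-threshold.
#' @export
form_clusters <- function(t_grid, threshold, channel_dim = NULL,
                          channel_labels = NULL, channel_adjacency = NULL) {
  if (threshold <= 0) stop("form_clusters: threshold must be positive")
  dims <- dim(t_grid)
  if (is.null(dims)) dims <- length(t_grid)
  channel_nb <- NULL
  if (!is.null(channel_dim)) {
    stopifnot(!is.null(channel_labels), !is.null(channel_adjacency))
    channel_nb <- lapply(seq_len(dims[channel_dim]), function(i)
      match(channel_adjacency[[channel_labels[i]]], channel_labels))
    channel_nb <- lapply(channel_nb, function(v) v[!is.na(v)])
  }
  out <- list()
  for (pol in c("pos", "neg")) {
    supra <- if (pol == "pos") t_grid > threshold else t_grid < -threshold
    supra[is.na(supra)] <- FALSE
    todo <- which(supra)
    if (length(todo) == 0) next
    seen <- logical(length(t_grid))
    for (start in todo) {
      if (seen[start]) next
      stack <- start; seen[start] <- TRUE
      members <- integer(0)
      while (length(stack) > 0) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        members <- c(members, cur)
        pt <- arrayInd(cur, dims)[1, ]
        for (q in grid_neighbours(pt, dims, channel_dim, channel_nb)) {
          lin <- sum((q - 1L) * cumprod(c(1L, dims[-length(dims)]))) + 1L
          if (!seen[lin] && supra[lin]) { seen[lin] <- TRUE; stack <- c(stack, lin) }
        }
      }
      out[[length(out) + 1L]] <- list(
        points = arrayInd(members, dims), indices = members,
        mass = sum(t_grid[members]), polarity = pol)
    }
  }
  out
}

#' Cluster-based permutation test for a paired design
#'
#' Re-implementation of the nonparametric max-cluster-mass permutation
#' method: subject-wise condition labels are randomly exchanged (sign flips
#' of the paired differences), the t map and its supra-threshold clusters
#' recomputed, and the maximum absolute cluster mass recorded per
#' permutation. Each observed cluster's Monte Carlo p is the proportion of
#' null maxima at least as large as its absolute mass (with the +1
#' correction), which controls the family-wise error rate two-sidedly at
#' the nominal alpha.
#'
#' @inheritParams form_clusters
#' @param a,b subject x grid arrays (see [paired_t_map()]).
#' @param n_perm number of random sign-flip permutations (default 1000).
#' @param seed RNG seed.
#' @param threshold cluster-forming threshold on |t|; default is the
#'   two-sided alpha = 0.05 paired-t critical value.
#' @return list of class `nap_clusters`: `clusters` (each with `points`,
#'   `mass`, `polarity`, `p`), `t_grid`, `threshold`, `n_perm`,
#'   `null_max`.
#' @export
permutation_p <- function(a, b, n_perm = 1000, seed = 1L, threshold = NULL,
                          channel_dim = NULL, channel_labels = NULL,
                          channel_adjacency = NULL) {
  if (n_perm < 100) warning("permutation_p: fewer than 100 permutations")
  old_rng <- preserve_seed()
  on.exit(restore_seed(old_rng), add = TRUE)
  if (is.null(dim(a))) { a <- matrix(a); b <- matrix(b) }
  n <- dim(a)[1]
  grid_dim <- dim(a)[-1]
  if (is.null(threshold)) threshold <- stats::qt(0.975, df = n - 1)
  d <- matrix(a - b, nrow = n)
  ss <- colSums(d^2)
  t_from <- function(signs) {
    m <- as.vector(signs %*% d) / n
    s2 <- (ss - n * m^2) / (n - 1)
    s2[s2 < 0] <- 0
    t <- m / sqrt(s2 / n)
    t[s2 == 0 & m == 0] <- 0
    array(t, dim = if (length(grid_dim)) grid_dim else 1L)
  }
  obs_t <- t_from(matrix(1, 1, n))
  obs_cl <- form_clusters(obs_t, threshold, channel_dim, channel_labels,
                          channel_adjacency)
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- matrix(sample(c(-1, 1), n, replace = TRUE), nrow = 1)
    cl <- form_clusters(t_from(signs), threshold, channel_dim,
                        channel_labels, channel_adjacency)
    null_max[p] <- if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
  }
  for (i in seq_along(obs_cl)) {
    obs_cl[[i]]$p <- (1 + sum(null_max >= abs(obs_cl[[i]]$mass))) / (n_perm + 1)
  }
  structure(list(clusters = obs_cl, t_grid = obs_t, threshold = threshold,
                 n_perm = n_perm, null_max = null_max),
            class = "nap_clusters")
}

#' Significant clusters at a family-wise alpha
#'
#' @param result a `nap_clusters`.
#' @param alpha family-wise significance level.
#' @return the subset of clusters with p < alpha.
#' @export
significant_clusters <- function(result, alpha = 0.05) {
  Filter(function(cl) cl$p < alpha, result$clusters)
}
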