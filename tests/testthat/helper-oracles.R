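# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's compiled kernels and
# igraph: distances come from Floyd-Warshall, clustering from explicit
# triangle counting, betweenness from geodesic-count dynamic programming.

# random symmetric 0/1 adjacency on n nodes with edge probability p
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  ut <- upper.tri(m)
  m[ut] <- as.integer(runif(sum(ut)) < p)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (sum(m) == 0) {  # guarantee at least one edge
    m[1, 2] <- m[2, 1] <- 1L
  }
  m
}

# all-pairs shortest path lengths by Floyd-Warshall
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  inv <- ifelse(is.finite(off), 1 / off, 0)
  # clustering by triangle enumeration
  cp_i <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        links <- links + (adj[nb[i], nb[j]] != 0)
      }
    }
    2 * links / (k * (k - 1))
  }, 1.0)
  # local efficiency via recursion into the oracle on the subgraph
  eloc_i <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] != 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- oracle_distances(sub)
    offs <- ds[row(ds) != col(ds)]
    mean(ifelse(is.finite(offs), 1 / offs, 0))
  }, 1.0)
  list(Cp = mean(cp_i),
       Lp = mean(off[is.finite(off)]),
       Eglob = mean(inv),
       Eloc = mean(eloc_i),
       efficiency = vapply(seq_len(n), function(i) {
         oi <- d[i, -i]
         mean(ifelse(is.finite(oi), 1 / oi, 0))
       }, 1.0))
}

# Brandes-equivalent betweenness by geodesic-count dynamic programming:
# sigma[s, t] geodesic counts via BFS layers, dependencies accumulated
# pairwise (each unordered pair counted once)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  # geodesic counts
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      if (d[s, t] == 1) {
        sigma[s, t] <- 1
      } else {
        pred <- which(adj[, t] != 0 & d[s, ] == d[s, t] - 1)
        sigma[s, t] <- sum(sigma[s, pred])
      }
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# small synthetic cohort spec used across tests (fast to generate)
tiny_spec <- function(seed = 1, ...) {
  args <- list(
    group_sizes = c(SleET = 3, NorET = 3, HC = 3),
    n_rois = 12, voxels_per_roi = c(60, 120), seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

# subject with regions drawn from shifted Gaussians (no cohort machinery)
simple_subject <- function(n_rois = 8, n_vox = 150, seed = 1,
                           id = "subj") {
  set.seed(seed)
  samples <- lapply(seq_len(n_rois), function(r) {
    rnorm(n_vox, mean = 5 + 0.3 * r, sd = 0.8)
  })
  names(samples) <- sprintf("R%02d", seq_len(n_rois))
  roi_sample_set(id, samples)
}
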