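# Network-based statistics (NBS).
#
# Edgewise group statistics over subject similarity matrices are
# thresholded (F = 4.64 for the omnibus contrast, |T| = 2.64 for signed
# pairwise contrasts, following the study's settings), connected
# components of the suprathreshold graph are scored by their edge count
# ("extent"), and family-wise inference compares each observed component
# with the permutation null of the maximal component size.

#' NBS configuration
#'
#' @param f_threshold edge-level F threshold for the omnibus contrast
#'   (default 4.64).
#' @param t_threshold edge-level |t| threshold for pairwise contrasts
#'   (default 2.64).
#' @param n_perm label permutations (default 10000).
#' @param alpha component-level significance level.
#' @param node_subset optional character vector of preselected regions
#'   (e.g. FDR-significant nodes); edges outside the subset are ignored.
#' @return object of class `nbs_config`.
#' @export
nbs_config <- function(f_threshold = 4.64, t_threshold = 2.64,
                       n_perm = 10000, alpha = 0.05, node_subset = NULL) {
  .check_scalar(f_threshold, "f_threshold", 1e-12)
  .check_scalar(t_threshold, "t_threshold", 1e-12)
  .check_scalar(n_perm, "n_perm", 1)
  .check_scalar(alpha, "alpha", 1e-12, 1 - 1e-12)
  structure(list(f_threshold = f_threshold, t_threshold = t_threshold,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 node_subset = node_subset),
            class = "nbs_config")
}

# stack a list of morph_network (or matrices) into subjects x edges rows
# over the upper triangle, verifying a shared region ordering
.stack_edges <- function(networks) {
  mats <- lapply(networks, function(x) {
    if (inherits(x, "morph_network")) x$matrix else x
  })
  rois <- rownames(mats[[1]])
  if (is.null(rois)) rois <- paste0("ROI", seq_len(nrow(mats[[1]])))
  for (m in mats) {
    nm <- rownames(m)
    if (!is.null(nm) && !identical(nm, rois)) {
      stop("subject matrices do not share the region ordering")
    }
    if (!identical(dim(m), dim(mats[[1]]))) {
      stop("subject matrices have differing dimensions")
    }
  }
  ut <- upper.tri(mats[[1]])
  X <- t(vapply(mats, function(m) m[ut], numeric(sum(ut))))
  idx <- which(ut, arr.ind = TRUE)
  list(X = X, idx = idx, rois = rois, n = nrow(mats[[1]]))
}

# vectorized one-way F across columns of X (subjects x edges)
.f_stat_cols <- function(X, g) {
  ns <- tabulate(g)
  k <- length(ns)
  n <- nrow(X)
  sums <- rowsum(X, g, reorder = TRUE)
  means <- sums / ns
  gm <- colSums(X) / n
  ssb <- colSums(ns * (means - matrix(gm, k, ncol(X), byrow = TRUE))^2)
  sst <- colSums(X^2) - n * gm^2
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw <= 0 & ssb > 0] <- Inf
  f[ssw <= 0 & ssb <= 0] <- 0
  f
}

# vectorized pooled two-sample t across columns (group 1 minus group 2)
.t_stat_cols <- function(X, g) {
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  s <- rowsum(X, g, reorder = TRUE)
  m1 <- s[1, ] / n1; m2 <- s[2, ] / n2
  ss <- rowsum(X^2, g, reorder = TRUE)
  v1 <- (ss[1, ] - n1 * m1^2) / (n1 - 1)
  v2 <- (ss[2, ] - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d <- m1 - m2
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[sp2 <= 0 & d == 0] <- 0
  t[sp2 <= 0 & d != 0] <- sign(d[sp2 <= 0 & d != 0]) * Inf
  t
}

#' Edgewise group statistics over subject networks
#'
#' Computes, for every region pair, a one-way ANOVA F across all groups
#' (`contrast = "anova"`) or a signed pooled t between two named groups
#' (`contrast = c(group_a, group_b)`, positive t meaning `group_a` has
#' the larger mean).
#'
#' @param networks list of [morph_network] objects (or matrices) sharing
#'   one region ordering.
#' @param groups group label per network.
#' @param contrast `"anova"` or a length-2 character vector of group
#'   names.
#' @return symmetric matrix of edge statistics with zero diagonal.
#' @export
edgewise_stats <- function(networks, groups, contrast = "anova") {
  st <- .stack_edges(networks)
  groups <- as.factor(groups)
  if (length(groups) != nrow(st$X)) {
    stop("one group label per subject network is required")
  }
  if (identical(contrast, "anova")) {
    if (nlevels(groups) < 2) stop("need at least 2 groups")
    stat <- .f_stat_cols(st$X, as.integer(groups))
  } else {
    if (length(contrast) != 2 || !all(contrast %in% levels(groups))) {
      stop("contrast must be 'anova' or two group names")
    }
    keep <- groups %in% contrast
    g <- ifelse(groups[keep] == contrast[1], 1L, 2L)
    stat <- .t_stat_cols(st$X[keep, , drop = FALSE], g)
  }
  out <- matrix(0, st$n, st$n, dimnames = list(st$rois, st$rois))
  out[st$idx] <- stat
  out[st$idx[, c(2, 1), drop = FALSE]] <- stat
  out
}

#' Connected components of suprathreshold edges
#'
#' Keeps edges whose statistic strictly exceeds `threshold` (optionally
#' restricted to a node subset) and returns the connected components of
#' the resulting graph, largest first.
#'
#' @param stat_matrix symmetric edge-statistic matrix.
#' @param threshold edge-level threshold.
#' @param node_subset optional character vector of region names.
#' @return list of components, each a list with `nodes`, `edges` (2-column
#'   character matrix) and `n_edges`; empty list if nothing survives.
#' @export
suprathreshold_components <- function(stat_matrix, threshold,
                                      node_subset = NULL) {
  stopifnot(is.matrix(stat_matrix), nrow(stat_matrix) == ncol(stat_matrix))
  .check_scalar(threshold, "threshold")
  rois <- rownames(stat_matrix)
  if (is.null(rois)) {
    rois <- paste0("ROI", seq_len(nrow(stat_matrix)))
    dimnames(stat_matrix) <- list(rois, rois)
  }
  if (!is.null(node_subset)) {
    missing <- setdiff(node_subset, rois)
    if (length(missing)) {
      stop("node_subset contains unknown regions: ",
           paste(missing, collapse = ", "))
    }
    mask <- rois %in% node_subset
    stat_matrix[!mask, ] <- -Inf
    stat_matrix[, !mask] <- -Inf
  }
  ut <- which(upper.tri(stat_matrix) & stat_matrix > threshold,
              arr.ind = TRUE)
  if (nrow(ut) == 0) return(list())
  g <- igraph::graph_from_edgelist(
    cbind(rois[ut[, 1]], rois[ut[, 2]]), directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  edge_comp <- membership[rois[ut[, 1]]]
  comps <- lapply(seq_len(comp$no), function(ci) {
    rows <- edge_comp == ci
    list(nodes = names(membership)[membership == ci],
         edges = cbind(rois[ut[rows, 1]], rois[ut[rows, 2]]),
         n_edges = sum(rows))
  })
  comps[order(vapply(comps, `[[`, 1L, "n_edges"), decreasing = TRUE)]
}

# max suprathreshold component size (edges) for a statistic vector on the
# upper triangle; avoids building matrices inside the permutation loop
.max_component_edges <- function(stat, idx, threshold, n) {
  keep <- stat > threshold
  if (!any(keep)) return(0L)
  e <- idx[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[e[, 1]]
  max(tabulate(memb))
}

#' NBS permutation test
#'
#' Scores the observed suprathreshold components by edge count and
#' compares each against the permutation null distribution of the maximal
#' component size under reshuffled group labels:
#' `p = (1 + #{max_null >= size_obs}) / (1 + n_perm)`.
#'
#' @param networks list of subject networks sharing a region ordering.
#' @param groups group label per network.
#' @param contrast `"anova"`, or a length-2 character vector for a signed
#'   pairwise contrast; with `direction = "increase"` edges with
#'   `t > t_threshold` (first group larger) are kept, with `"decrease"`
#'   edges with `t < -t_threshold`.
#' @param config an [nbs_config()].
#' @param direction for pairwise contrasts, `"increase"` or `"decrease"`.
#' @param seed RNG seed.
#' @return object of class `nbs_result`: `components` (with per-component
#'   p-values), `stat_matrix`, `threshold`, `direction`, `null_max`
#'   (permutation distribution) and the config used.
#' @export
nbs_permutation_test <- function(networks, groups, contrast = "anova",
                                 config = nbs_config(),
                                 direction = c("increase", "decrease"),
                                 seed = 1) {
  stopifnot(inherits(config, "nbs_config"))
  direction <- match.arg(direction)
  st <- .stack_edges(networks)
  groups <- as.factor(groups)
  if (length(groups) != nrow(st$X)) {
    stop("one group label per subject network is required")
  }
  if (!is.null(config$node_subset)) {
    missing <- setdiff(config$node_subset, st$rois)
    if (length(missing)) {
      stop("node_subset contains unknown regions: ",
           paste(missing, collapse = ", "))
    }
    inset <- st$rois %in% config$node_subset
    edge_ok <- inset[st$idx[, 1]] & inset[st$idx[, 2]]
  } else {
    edge_ok <- rep(TRUE, nrow(st$idx))
  }
  anova_mode <- identical(contrast, "anova")
  if (anova_mode) {
    X <- st$X
    g <- as.integer(groups)
    thr <- config$f_threshold
    stat_fun <- function(gg) .f_stat_cols(X, gg)
  } else {
    if (length(contrast) != 2 || !all(contrast %in% levels(groups))) {
      stop("contrast must be 'anova' or two group names")
    }
    keep <- groups %in% contrast
    X <- st$X[keep, , drop = FALSE]
    g <- ifelse(groups[keep] == contrast[1], 1L, 2L)
    thr <- config$t_threshold
    sgn <- if (direction == "increase") 1 else -1
    stat_fun <- function(gg) sgn * .t_stat_cols(X, gg)
  }
  stat_obs <- stat_fun(g)
  stat_obs[!edge_ok] <- -Inf
  obs_mat <- matrix(0, st$n, st$n, dimnames = list(st$rois, st$rois))
  fill <- stat_obs
  fill[fill == -Inf] <- 0                       # masked edges
  fill[fill == Inf] <- .Machine$double.xmax     # zero within-group variance
  obs_mat[st$idx] <- fill
  obs_mat[st$idx[, c(2, 1), drop = FALSE]] <- fill
  comps <- suprathreshold_components(obs_mat, thr,
                                     node_subset = config$node_subset)
  null_max <- with_seed(derive_seed(seed, "nbs"), {
    vapply(seq_len(config$n_perm), function(b) {
      sp <- stat_fun(sample(g))
      sp[!edge_ok] <- -Inf
      .max_component_edges(sp, st$idx, thr, st$n)
    }, 1L)
  })
  for (ci in seq_along(comps)) {
    comps[[ci]]$p <- (1 + sum(null_max >= comps[[ci]]$n_edges)) /
      (1 + config$n_perm)
    comps[[ci]]$significant <- comps[[ci]]$p < config$alpha
  }
  structure(
    list(components = comps, stat_matrix = obs_mat, threshold = thr,
         contrast = contrast,
         direction = if (anova_mode) NA_character_ else direction,
         null_max = null_max, config = config, seed = seed),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("nbs_result: %d suprathreshold component(s) at threshold %.3g\n",
              length(x$components), x$threshold))
  for (c_ in x$components) {
    cat(sprintf("  %d nodes / %d edges, p = %.4g%s\n",
                length(c_$nodes), c_$n_edges, c_$p,
                if (isTRUE(c_$significant)) " *" else ""))
  }
  invisible(x)
}

#' Tidy edge table of an NBS result
#'
#' @param x an `nbs_result`.
#' @return data.frame with columns `roi_a`, `roi_b`, `statistic`,
#'   `component_id`, `p`.
#' @export
nbs_edge_table <- function(x) {
  stopifnot(inherits(x, "nbs_result"))
  rows <- lapply(seq_along(x$components), function(ci) {
    comp <- x$components[[ci]]
    data.frame(
      roi_a = comp$edges[, 1], roi_b = comp$edges[, 2],
      statistic = x$stat_matrix[comp$edges],
      component_id = ci, p = comp$p, stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(roi_a = character(), roi_b = character(),
                      statistic = numeric(), component_id = integer(),
                      p = numeric()))
  }
  do.call(rbind, rows)
}
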