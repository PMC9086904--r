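# Nonparametric permutation inference on AUC metrics.
#
# Group differences are tested by permuting group labels: the omnibus
# statistic is the one-way ANOVA F, post-hoc contrasts use the pooled
# two-sample t, and p-values follow the add-one convention
# p = (1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm), which is unbiased
# and never returns zero. Exhaustive enumeration replaces Monte-Carlo
# sampling on request (tiny samples), in which case the identity
# arrangement is counted among the enumerated ones.

# one-way ANOVA F for a numeric vector and a group factor; returns Inf
# when within-group variance is 0 but between-group variance is not
.f_stat <- function(x, g) {
  if (anyNA(x)) return(NaN)
  means <- tapply(x, g, mean)
  ns <- tabulate(g)
  k <- length(means)
  n <- length(x)
  gm <- mean(x)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((x - means[as.integer(g)])^2)
  if (ssw == 0 && ssb == 0) return(NaN)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# pooled-variance two-sample t
.t_stat <- function(x, g) {
  if (anyNA(x)) return(NaN)
  x1 <- x[g == 1L]; x2 <- x[g == 2L]
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  d <- mean(x1) - mean(x2)
  if (sp2 == 0) {
    if (d == 0) return(NaN)
    return(sign(d) * Inf)
  }
  d / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# all distinct arrangements of a group-label multiset (tiny n only)
.enumerate_labels <- function(g) {
  n <- length(g)
  counts <- tabulate(g)
  out <- list()
  recurse <- function(remaining, assigned) {
    if (sum(remaining) == 0) {
      out[[length(out) + 1]] <<- assigned
      return(invisible())
    }
    lvl <- which(remaining > 0)
    for (l in lvl) {
      r2 <- remaining
      r2[l] <- r2[l] - 1L
      recurse(r2, c(assigned, l))
    }
  }
  recurse(counts, integer(0))
  out
}

.as_group_list <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    stop("need a list of at least 2 groups")
  }
  if (any(vapply(values_by_group, length, 1L) < 2)) {
    stop("each group needs at least 2 values")
  }
  values_by_group
}

#' Permutation one-way ANOVA
#'
#' Observed F statistic across the groups, with a permutation null built
#' by reshuffling group labels.
#'
#' @param values_by_group list of numeric vectors, one per group.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed.
#' @param exact enumerate all distinct label arrangements instead of
#'   sampling; p is then `#{F_perm >= F_obs} / n_arrangements` with the
#'   identity arrangement included. Feasible only for tiny samples.
#' @return object of class `group_test`: statistic, p-value, group means,
#'   number of permutations, `flagged` when the statistic is undefined
#'   (no variance anywhere).
#' @export
permutation_anova <- function(values_by_group, n_perm = 10000, seed = 1,
                              exact = FALSE) {
  vals <- .as_group_list(values_by_group)
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(seq_along(vals), vapply(vals, length, 1L)))
  f_obs <- .f_stat(x, g)
  if (is.nan(f_obs)) {
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          group_means = vapply(vals, mean, 1.0),
                          n_perm = 0L, flagged = TRUE, type = "anova"),
                     class = "group_test"))
  }
  if (exact) {
    arr <- .enumerate_labels(as.integer(g))
    fp <- vapply(arr, function(a) .f_stat(x, factor(a)), 1.0)
    p <- sum(fp >= f_obs) / length(fp)
    n_used <- length(fp)
  } else {
    fp <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) .f_stat(x, sample(g)), 1.0)
    })
    p <- (1 + sum(fp >= f_obs)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = f_obs, p = p,
                 group_means = vapply(vals, mean, 1.0),
                 n_perm = n_used, flagged = FALSE, type = "anova"),
            class = "group_test")
}

#' Permutation two-sample test
#'
#' Pooled-variance t statistic with a two-sided permutation p-value
#' (comparisons on `|t|`).
#'
#' @param values_a,values_b numeric vectors.
#' @inheritParams permutation_anova
#' @return a `group_test` object.
#' @export
permutation_pairwise <- function(values_a, values_b, n_perm = 10000,
                                 seed = 1, exact = FALSE) {
  vals <- .as_group_list(list(values_a, values_b))
  x <- unlist(vals, use.names = FALSE)
  g <- rep(1:2, vapply(vals, length, 1L))
  t_obs <- .t_stat(x, g)
  if (is.nan(t_obs)) {
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          group_means = vapply(vals, mean, 1.0),
                          n_perm = 0L, flagged = TRUE, type = "t"),
                     class = "group_test"))
  }
  if (exact) {
    arr <- .enumerate_labels(g)
    tp <- vapply(arr, function(a) .t_stat(x, a), 1.0)
    p <- sum(abs(tp) >= abs(t_obs)) / length(tp)
    n_used <- length(tp)
  } else {
    # canonical null draw (sorted values, smaller group first) so the
    # two-sided p is exactly invariant to swapping the two samples
    x_null <- sort(x)
    g_null <- rep(1:2, sort(vapply(vals, length, 1L)))
    tp <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) .t_stat(x_null, sample(g_null)),
             1.0)
    })
    p <- (1 + sum(abs(tp) >= abs(t_obs))) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = t_obs, p = p,
                 group_means = vapply(vals, mean, 1.0),
                 n_perm = n_used, flagged = FALSE, type = "t"),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("permutation %s test: stat = %.4g, p = %.4g (%d perms)\n",
              x$type, x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `q`; adjusted p-values are monotone
#' nondecreasing in the raw values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `significant` (logical mask) and `adjusted`
#'   (BH-adjusted p-values).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  .check_scalar(q, "q", 1e-12, 1 - 1e-12)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(significant = adj <= q, adjusted = adj)
}

#' Group comparison of AUC metrics
#'
#' Runs the permutation ANOVA across the three groups for every metric
#' column, post-hoc pairwise permutation tests, and FDR correction within
#' each nodal metric family (degree, betweenness and efficiency are
#' corrected separately across regions, global metrics as one family).
#' Subjects are permuted as whole rows, preserving the dependence between
#' metrics within a subject.
#'
#' @param auc matrix or data.frame of AUC values, subjects x metrics.
#' @param groups factor or character vector of group labels per row.
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @param fdr_q FDR level.
#' @param families optional character vector assigning each metric column
#'   to a correction family; defaults to the prefix before the first `|`
#'   in the column name (so `degree|Thalamus_L` belongs to family
#'   `degree`), with unprefixed columns forming the `global` family.
#' @return data.frame with one row per metric: F, raw p, adjusted p,
#'   significance flag, group means and pairwise t/p columns.
#' @export
compare_groups <- function(auc, groups, n_perm = 10000, seed = 1,
                           fdr_q = 0.05, families = NULL) {
  auc <- as.matrix(auc)
  groups <- as.factor(groups)
  if (nrow(auc) != length(groups)) {
    stop("one group label per AUC row is required")
  }
  metrics <- colnames(auc)
  if (is.null(metrics)) {
    stop("AUC matrix must have metric column names")
  }
  if (is.null(families)) {
    families <- ifelse(grepl("|", metrics, fixed = TRUE),
                       sub("\\|.*", "", metrics), "global")
  }
  lv <- levels(groups)
  pair_idx <- utils::combn(length(lv), 2)
  rows <- lapply(seq_along(metrics), function(m) {
    vals <- split(auc[, m], groups)
    at <- permutation_anova(vals, n_perm = n_perm,
                            seed = derive_seed(seed, metrics[m]))
    row <- data.frame(metric = metrics[m], family = families[m],
                      F = at$statistic, p = at$p,
                      stringsAsFactors = FALSE)
    for (gi in seq_along(lv)) {
      row[[paste0("mean_", lv[gi])]] <- at$group_means[[gi]]
    }
    for (pc in seq_len(ncol(pair_idx))) {
      a <- lv[pair_idx[1, pc]]; b <- lv[pair_idx[2, pc]]
      pt <- permutation_pairwise(
        vals[[a]], vals[[b]], n_perm = n_perm,
        seed = derive_seed(seed, paste0(metrics[m], "|", a, "|", b)))
      row[[paste0("t_", a, "_vs_", b)]] <- pt$statistic
      row[[paste0("p_", a, "_vs_", b)]] <- pt$p
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  out$significant <- NA
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    ok <- sel & !is.na(out$p)
    if (any(ok)) {
      fc <- fdr_correct(out$p[ok], q = fdr_q)
      out$p_fdr[ok] <- fc$adjusted
      out$significant[ok] <- fc$significant
    }
  }
  out
}
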