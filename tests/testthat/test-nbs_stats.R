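# Network-based statistics.

# stack of synthetic similarity matrices with optional planted edge shifts
make_stack <- function(n_sub, n_nodes, seed, shift_edges = NULL,
                       shift = 0, shift_subjects = integer(0)) {
  set.seed(seed)
  rois <- sprintf("N%02d", seq_len(n_nodes))
  lapply(seq_len(n_sub), function(s) {
    m <- matrix(0, n_nodes, n_nodes, dimnames = list(rois, rois))
    ut <- upper.tri(m)
    m[ut] <- plogis(rnorm(sum(ut), 0, 1))
    m <- m + t(m)
    if (s %in% shift_subjects && !is.null(shift_edges)) {
      for (r in seq_len(nrow(shift_edges))) {
        i <- shift_edges[r, 1]; j <- shift_edges[r, 2]
        m[i, j] <- m[j, i] <- min(1, m[i, j] + shift)
      }
    }
    diag(m) <- 0
    morph_network(sprintf("s%03d", s), m)
  })
}

test_that("identical groups give all-zero edge statistics", {
  nets <- make_stack(6, 8, seed = 1)
  nets <- c(nets[1:3], nets[1:3])  # same matrices in both groups
  f <- edgewise_stats(nets, rep(c("A", "B"), each = 3))
  expect_true(all(abs(f) < 1e-10))  # zero up to float summation order
  t_ <- edgewise_stats(nets, rep(c("A", "B"), each = 3),
                       contrast = c("A", "B"))
  expect_true(all(t_ == 0))
})

test_that("a planted edge attains the maximal statistic", {
  edges <- matrix(c(2, 5), ncol = 2)
  nets <- make_stack(30, 10, seed = 2, shift_edges = edges, shift = 0.9,
                     shift_subjects = 1:15)
  groups <- rep(c("A", "B"), each = 15)
  f <- edgewise_stats(nets, groups)
  ut <- which(upper.tri(f), arr.ind = TRUE)
  top <- ut[which.max(f[ut]), ]
  expect_identical(unname(top), c(2L, 5L))
})

test_that("swapping the two groups negates the t matrix", {
  nets <- make_stack(12, 7, seed = 3)
  groups <- rep(c("A", "B"), each = 6)
  t_ab <- edgewise_stats(nets, groups, contrast = c("A", "B"))
  t_ba <- edgewise_stats(nets, groups, contrast = c("B", "A"))
  expect_equal(t_ab, -t_ba, tolerance = 1e-12)
})

test_that("suprathreshold components match hand-worked union-find", {
  rois <- c("A", "B", "C", "D", "E")
  m <- matrix(0, 5, 5, dimnames = list(rois, rois))
  m["A", "B"] <- m["B", "A"] <- 5
  m["B", "C"] <- m["C", "B"] <- 6
  m["D", "E"] <- m["E", "D"] <- 7
  comps <- suprathreshold_components(m, threshold = 4)
  expect_identical(length(comps), 2L)
  expect_identical(comps[[1]]$n_edges, 2L)
  expect_setequal(comps[[1]]$nodes, c("A", "B", "C"))
  expect_identical(comps[[2]]$n_edges, 1L)
  expect_setequal(comps[[2]]$nodes, c("D", "E"))
  expect_identical(suprathreshold_components(m, threshold = 10), list())
})

test_that("a planted clique forms one component with C(4,2) edges", {
  rois <- sprintf("N%02d", 1:9)
  m <- matrix(1, 9, 9, dimnames = list(rois, rois))
  clique <- c(2, 4, 6, 8)
  m[clique, clique] <- 9
  diag(m) <- 0
  comps <- suprathreshold_components(m, threshold = 5)
  expect_identical(length(comps), 1L)
  expect_identical(comps[[1]]$n_edges, 6L)
  expect_setequal(comps[[1]]$nodes, rois[clique])
})

test_that("components are monotone in the threshold and order-invariant", {
  set.seed(4)
  m <- matrix(0, 10, 10)
  m[upper.tri(m)] <- runif(45, 0, 10)
  m <- m + t(m)
  sizes <- function(th) {
    vapply(suprathreshold_components(m, th), `[[`, 1L, "n_edges")
  }
  s1 <- sizes(2); s2 <- sizes(5); s3 <- sizes(8)
  expect_gte(sum(s1), sum(s2))
  expect_gte(sum(s2), sum(s3))
  # idempotence: recomputing on the same matrix gives identical output
  expect_identical(suprathreshold_components(m, 5),
                   suprathreshold_components(m, 5))
})

test_that("node_subset bounds component size and unknown nodes error", {
  rois <- sprintf("N%02d", 1:8)
  m <- matrix(9, 8, 8, dimnames = list(rois, rois))
  diag(m) <- 0
  sub <- rois[1:4]
  comps <- suprathreshold_components(m, 5, node_subset = sub)
  expect_lte(comps[[1]]$n_edges, length(sub) * (length(sub) - 1) / 2)
  expect_setequal(comps[[1]]$nodes, sub)
  expect_error(suprathreshold_components(m, 5, node_subset = c("zz")),
               "unknown")
})

test_that("the NBS permutation test is deterministic and finds planted effects", {
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4),
                 c(4, 5), c(4, 6), c(5, 6), c(5, 7))
  nets <- make_stack(45 + 59, 12, seed = 6, shift_edges = edges,
                     shift = 0.5, shift_subjects = 1:45)
  groups <- rep(c("SleET", "NorET"), c(45, 59))
  cfg <- nbs_config(n_perm = 199)
  res <- nbs_permutation_test(nets, groups, contrast = c("SleET", "NorET"),
                              config = cfg, direction = "increase",
                              seed = 9)
  res2 <- nbs_permutation_test(nets, groups,
                               contrast = c("SleET", "NorET"),
                               config = cfg, direction = "increase",
                               seed = 9)
  expect_identical(res$components, res2$components)
  expect_gte(length(res$components), 1L)
  expect_lt(res$components[[1]]$p, 0.05)
  planted_nodes <- sprintf("N%02d", 1:7)
  expect_true(all(res$components[[1]]$nodes %in% planted_nodes))
  # decreasing direction finds nothing here
  res_dec <- nbs_permutation_test(nets, groups,
                                  contrast = c("SleET", "NorET"),
                                  config = cfg, direction = "decrease",
                                  seed = 9)
  expect_true(length(res_dec$components) == 0 ||
                res_dec$components[[1]]$p > 0.05)
})

test_that("nbs_edge_table flattens components", {
  nets <- make_stack(20, 6, seed = 8,
                     shift_edges = rbind(c(1, 2), c(2, 3)), shift = 0.9,
                     shift_subjects = 1:10)
  res <- nbs_permutation_test(nets, rep(c("A", "B"), each = 10),
                              contrast = c("A", "B"),
                              config = nbs_config(n_perm = 99), seed = 2)
  tab <- nbs_edge_table(res)
  expect_true(all(c("roi_a", "roi_b", "statistic", "component_id", "p")
                  %in% names(tab)))
  if (nrow(tab)) {
    expect_true(all(tab$statistic > res$threshold))
  }
})

test_that("region-order mismatch between subjects is rejected", {
  nets <- make_stack(4, 6, seed = 10)
  m <- nets[[2]]$matrix
  perm <- c(2, 1, 3:6)
  nets[[2]] <- morph_network("s002", m[perm, perm])
  expect_error(edgewise_stats(nets, rep(c("A", "B"), each = 2)),
               "ordering")
})
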