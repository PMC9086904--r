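# Thresholding, metrics, null normalization and AUC.

test_that("threshold_graph keeps exactly round(s*N(N-1)/2) strongest edges", {
  set.seed(1)
  n <- 116
  m <- matrix(0, n, n)
  w <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- w
  m <- m + t(m)
  adj <- threshold_graph(m, 0.10)
  expect_identical(sum(adj) / 2, round(0.10 * 6670))  # 667 edges
  # top-k by explicit sort must match
  ut <- which(upper.tri(m), arr.ind = TRUE)
  keep <- order(-m[upper.tri(m)])[seq_len(667)]
  expected <- matrix(0L, n, n)
  expected[ut[keep, , drop = FALSE]] <- 1L
  expected <- expected + t(expected)
  expect_identical(unname(adj[, ]), expected)
})

test_that("thresholding saturates to the complete graph and rejects s=0-ish", {
  m <- matrix(runif(36), 6, 6)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  adj <- threshold_graph(m, 0.999)
  expect_identical(sum(adj) / 2, 15)
  expect_error(threshold_graph(m, 0.01), "zero edges")
})

test_that("tie-break is deterministic", {
  m <- matrix(0.5, 5, 5)
  diag(m) <- 0
  a1 <- threshold_graph(m, 0.3)
  a2 <- threshold_graph(m, 0.3)
  expect_identical(a1, a2)
  expect_identical(sum(a1) / 2, round(0.3 * 10))
})

test_that("complete K4 attains the complete-graph limits", {
  adj <- matrix(1L, 4, 4)
  diag(adj) <- 0L
  gm <- global_metrics(adj)
  expect_equal(unlist(gm[c("Cp", "Lp", "Eglob", "Eloc")]),
               c(Cp = 1, Lp = 1, Eglob = 1, Eloc = 1))
})

test_that("path A-B-C matches hand enumeration", {
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1L
  gm <- global_metrics(adj)
  expect_equal(gm$Cp, 0)
  expect_equal(gm$Lp, 4 / 3)   # distances 1,1,2 over unordered pairs
  expect_equal(gm$Eglob, 5 / 6)
  nd <- nodal_metrics(adj)
  expect_equal(unname(nd$betweenness), c(0, 1, 0))
  expect_equal(unname(nd$efficiency[2]), 1)
})

test_that("star betweenness is C(k,2) at the hub and 0 at leaves", {
  adj <- matrix(0L, 5, 5)
  adj[1, 2:5] <- adj[2:5, 1] <- 1L
  nd <- nodal_metrics(adj)
  expect_equal(unname(nd$betweenness), c(6, 0, 0, 0, 0))
  expect_equal(unname(nd$degree), c(4, 1, 1, 1, 1))
})

test_that("all metrics match the brute-force oracle on random small graphs", {
  for (i in 1:60) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.8), seed = 1000 + i)
    gm <- global_metrics(adj)
    nd <- nodal_metrics(adj)
    og <- oracle_global(adj)
    expect_equal(gm$Cp, og$Cp, tolerance = 1e-10)
    expect_equal(gm$Lp, og$Lp, tolerance = 1e-10)
    expect_equal(gm$Eglob, og$Eglob, tolerance = 1e-10)
    expect_equal(gm$Eloc, og$Eloc, tolerance = 1e-10)
    expect_equal(unname(nd$efficiency), og$efficiency, tolerance = 1e-10)
    expect_equal(unname(nd$betweenness), oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(unname(nd$degree), rowSums(adj != 0))
  }
})

test_that("Eglob never decreases when an edge is added", {
  for (i in 1:25) {
    adj <- random_adjacency(7, 0.35, seed = 2000 + i)
    absent <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
    expect_gte(global_metrics(adj2)$Eglob, global_metrics(adj)$Eglob)
  }
})

test_that("mean nodal efficiency equals Eglob (ordered-pair bookkeeping)", {
  for (i in 1:10) {
    adj <- random_adjacency(8, 0.6, seed = 3000 + i)
    gm <- global_metrics(adj)
    nd <- nodal_metrics(adj)
    expect_equal(mean(nd$efficiency), gm$Eglob, tolerance = 1e-12)
  }
})

test_that("rewired nulls preserve the degree sequence exactly", {
  adj <- random_adjacency(20, 0.25, seed = 42)
  edges <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  storage.mode(edges) <- "integer"
  for (s in 1:5) {
    re <- morphnet:::.rewire_cpp(edges - 1L, 20L, 10, s)
    expect_identical(nrow(re), nrow(edges))
    expect_true(all(re[, 1] != re[, 2]))  # no self-loops
    key <- paste(pmin(re[, 1], re[, 2]), pmax(re[, 1], re[, 2]))
    expect_identical(anyDuplicated(key), 0L)  # no multi-edges
    deg_null <- tabulate(c(re[, 1], re[, 2]) + 1L, nbins = 20)
    expect_identical(deg_null, as.integer(rowSums(adj != 0)))
  }
})

test_that("rewiring-invariant graphs give gamma = lambda = sigma = 1", {
  adj <- matrix(1L, 6, 6)
  diag(adj) <- 0L
  nm <- normalized_metrics(adj, n_nulls = 10, seed = 1)
  expect_equal(c(nm$gamma, nm$lambda, nm$sigma), c(1, 1, 1))
  expect_true(nm$degenerate_nulls)
})

test_that("normalized metrics are deterministic in the seed", {
  adj <- random_adjacency(30, 0.2, seed = 9)
  a <- normalized_metrics(adj, n_nulls = 20, seed = 7)
  b <- normalized_metrics(adj, n_nulls = 20, seed = 7)
  expect_identical(a, b)
})

test_that("a ring lattice is small-world against rewired nulls", {
  # circulant graph: each node tied to its 4 nearest ring neighbors
  n <- 60
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (off in 1:2) {
      j <- ((i - 1 + off) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  nm <- normalized_metrics(adj, n_nulls = 30, seed = 3)
  expect_gt(nm$gamma, 1)
  expect_gt(nm$sigma, 1)
})

test_that("metric_auc matches analytic integrals", {
  spec <- threshold_spec()
  expect_identical(length(spec$levels), 26L)
  expect_lt(abs(metric_auc(rep(2, 26), spec) - 0.5), 1e-12)
  expect_lt(abs(metric_auc(spec$levels, spec) - 0.056250), 1e-12)
  expect_error(metric_auc(rep(1, 25), spec), "26")
  expect_error(metric_auc(1, threshold_spec(0.2, 0.2, 0.01)), "at least 2")
})

test_that("sweep_metrics is deterministic and internally consistent", {
  rs <- simple_subject(n_rois = 14, n_vox = 80, seed = 10)
  nw <- build_network(rs, n_grid = 128)
  spec <- threshold_spec(0.15, 0.30, 0.05)
  p1 <- sweep_metrics(nw, spec, n_nulls = 5, seed = 3)
  p2 <- sweep_metrics(nw, spec, n_nulls = 5, seed = 3)
  expect_identical(p1, p2)
  expect_identical(nrow(p1$global), length(spec$levels))
  expect_equal(p1$auc_global[["Eglob"]],
               metric_auc(p1$global$Eglob, spec))
  expect_equal(unname(p1$auc_nodal["degree", ]),
               unname(apply(p1$nodal$degree, 2, metric_auc, spec = spec)))
  # degree sum = 2|E| at every threshold
  n <- 14
  for (t in seq_along(spec$levels)) {
    k <- round(spec$levels[t] * n * (n - 1) / 2)
    expect_identical(sum(p1$nodal$degree[t, ]), 2 * k)
  }
})
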