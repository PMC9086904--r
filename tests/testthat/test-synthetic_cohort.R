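# Synthetic cohort generator: determinism, structure, planted effects.

test_that("a fixed seed reproduces the cohort byte-for-byte", {
  a <- generate_cohort(tiny_spec(seed = 42))
  b <- generate_cohort(tiny_spec(seed = 42))
  expect_identical(a$table, b$table)
  expect_identical(a$samples, b$samples)
  expect_identical(a$expected_degree, b$expected_degree)
  c_ <- generate_cohort(tiny_spec(seed = 43))
  expect_false(identical(a$table, c_$table))
})

test_that("the default design yields 45+59+66 subjects with 116 regions", {
  spec <- cohort_spec(seed = 7, voxels_per_roi = c(20, 40))
  co <- generate_cohort(spec)
  expect_identical(nrow(co$table), 170L)
  expect_identical(as.integer(table(co$table$group)[c("SleET", "NorET", "HC")]),
                   c(45L, 59L, 66L))
  expect_identical(length(co$samples), 170L)
  expect_true(all(vapply(co$samples,
                         function(s) length(s$samples) == 116L, TRUE)))
  expect_identical(co$roi_names, aal116_labels()$name)
})

test_that("invalid specifications are rejected with messages", {
  expect_error(cohort_spec(group_sizes = c(SleET = 1, NorET = 5, HC = 5)),
               "at least 2")
  expect_error(cohort_spec(n_rois = 2), "n_rois")
  expect_error(
    cohort_spec(n_rois = 10,
                planted_edges = data.frame(roi_a = 1, roi_b = 11,
                                           group = "SleET", effect = 0.5)),
    "unknown ROI index")
  expect_error(
    cohort_spec(planted_edges = data.frame(roi_a = 1, roi_b = 2,
                                           group = "XX", effect = 0.5)),
    "unknown group")
  expect_error(cohort_spec(trs_degree_rho = 1.5), "trs_degree_rho")
})

test_that("clinical scores respect instrument ranges and the PSQI rule", {
  co <- generate_cohort(tiny_spec(seed = 3,
                                  group_sizes = c(SleET = 20, NorET = 20,
                                                  HC = 20)),
                        include_samples = FALSE)
  tb <- co$table
  expect_true(all(tb$PSQI >= 0 & tb$PSQI <= 21))
  expect_true(all(tb$MMSE >= 24 & tb$MMSE <= 30))
  expect_true(all(tb$HAMA <= 14) && all(tb$HAMD <= 17))
  et <- tb[tb$group != "HC", ]
  expect_identical(unname(classify_sleep_group(et$PSQI)), et$group)
  # every generated subject passes the screening rules by construction
  ok <- vapply(seq_len(nrow(tb)),
               function(i) apply_eligibility(tb[i, ])$include, TRUE)
  expect_true(all(ok))
  expect_true(all(tb$TRS[tb$group != "HC"] >= 0))
  expect_true(all(is.na(tb$TRS[tb$group == "HC"])))
})

test_that("planted edges pull the pair's distributions together", {
  pe <- data.frame(roi_a = 2, roi_b = 9, group = "SleET", effect = 0.9)
  spec <- tiny_spec(seed = 11, planted_edges = pe, trs_degree_rho = 0,
                    group_sizes = c(SleET = 6, NorET = 6, HC = 2))
  co <- generate_cohort(spec)
  sims <- vapply(names(co$samples), function(id) {
    s <- co$samples[[id]]
    g <- seq(min(s$samples[[2]], s$samples[[9]]) - 1,
             max(s$samples[[2]], s$samples[[9]]) + 1, length.out = 256)
    kl_similarity(estimate_pdf(s$samples[[2]], grid = g),
                  estimate_pdf(s$samples[[9]], grid = g))
  }, 1.0)
  grp <- co$table$group[match(names(sims), co$table$subject_id)]
  expect_gt(mean(sims[grp == "SleET"]), mean(sims[grp == "NorET"]))
})

test_that("plant_degree_trs_correlation behaves across rho regimes", {
  spec <- tiny_spec(seed = 13, trs_degree_rho = 0,
                    group_sizes = c(SleET = 40, NorET = 5, HC = 5))
  co <- generate_cohort(spec, include_samples = FALSE)

  # rho = 0: leaves TRS independent of degree (small sample correlation)
  cors0 <- vapply(1:40, function(s) {
    sp <- tiny_spec(seed = 1000 + s, trs_degree_rho = 0,
                    group_sizes = c(SleET = 40, NorET = 5, HC = 5))
    cc <- generate_cohort(sp, include_samples = FALSE)
    sel <- cc$table$group == "SleET"
    suppressWarnings(cor(cc$expected_degree[sel, sp$trs_target_roi],
                         cc$table$TRS[sel]))
  }, 1.0)
  expect_lt(abs(mean(cors0, na.rm = TRUE)), 0.1)

  # planting a strong negative rho flips the sample correlation negative
  planted <- plant_degree_trs_correlation(co, target_roi = "ROI006",
                                          rho = -0.8, group = "SleET")
  sel <- planted$table$group == "SleET"
  expect_lt(cor(planted$expected_degree[sel, "ROI006"],
                planted$table$TRS[sel]), -0.3)
  # non-planted groups untouched
  expect_identical(planted$table$TRS[planted$table$group == "NorET"],
                   co$table$TRS[co$table$group == "NorET"])

  # degenerate degrees are an error
  broken <- co
  broken$expected_degree[broken$table$group == "SleET", "ROI006"] <- 5
  expect_error(plant_degree_trs_correlation(broken, "ROI006", -0.5,
                                            "SleET"),
               "degenerate")
  expect_error(plant_degree_trs_correlation(co, "ROI006", rho = 1.2),
               "rho")
  expect_error(plant_degree_trs_correlation(co, "NOPE", rho = 0.5),
               "unknown target")
})

test_that("generate -> plant is reproducible as a two-call sequence", {
  spec <- tiny_spec(seed = 21, trs_degree_rho = 0)
  a <- plant_degree_trs_correlation(
    generate_cohort(spec, include_samples = FALSE), "ROI004", -0.4)
  b <- plant_degree_trs_correlation(
    generate_cohort(spec, include_samples = FALSE), "ROI004", -0.4)
  expect_identical(a$table, b$table)
})

test_that("with no planted effects the groups are exchangeable", {
  # permutation ANOVA on a generator statistic (mean expected degree)
  # rejects at ~ the nominal rate over null cohorts
  n_rep <- 200
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sp <- tiny_spec(seed = 5000 + i, trs_degree_rho = 0,
                    planted_global_effect = 0,
                    group_sizes = c(SleET = 8, NorET = 8, HC = 8),
                    n_rois = 10)
    co <- generate_cohort(sp, include_samples = FALSE)
    # a single region's analytic degree (the row mean is constant by
    # construction: thresholding fixes the total edge count)
    stat <- co$expected_degree[, 3]
    res <- permutation_anova(split(stat, co$table$group), n_perm = 199,
                             seed = i)
    rej[i] <- res$p < 0.05
  }
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])
})

test_that("cohort TSV export round-trips", {
  co <- generate_cohort(tiny_spec(seed = 31, n_rois = 5,
                                  group_sizes = c(SleET = 2, NorET = 2,
                                                  HC = 2)))
  dir <- tempfile()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  back <- read_roi_table(file.path(dir, "SleET001.tsv"))
  expect_equal(back$samples, co$samples[["SleET001"]]$samples,
               tolerance = 0)
})
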