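# Screening rules and partial correlations.

test_that("eligibility boundaries follow the strict inequalities", {
  rec <- function(mmse = 28, hama = 5, hamd = 5) {
    list(MMSE = mmse, HAMA = hama, HAMD = hamd)
  }
  expect_false(apply_eligibility(rec(mmse = 23))$include)
  expect_identical(apply_eligibility(rec(mmse = 23))$reason, "cognition")
  expect_true(apply_eligibility(rec(mmse = 24))$include)
  expect_false(apply_eligibility(rec(hama = 15))$include)
  expect_identical(apply_eligibility(rec(hama = 15))$reason, "anxiety")
  expect_false(apply_eligibility(rec(hamd = 18))$include)
  expect_identical(apply_eligibility(rec(hamd = 18))$reason, "depression")
  # boundary complement: all three at their inclusive limits
  expect_true(apply_eligibility(rec(mmse = 24, hama = 14,
                                    hamd = 17))$include)
  expect_error(apply_eligibility(list(MMSE = 25, HAMA = 3)), "HAMD")
})

test_that("sleep classification splits exactly at PSQI 6", {
  expect_identical(classify_sleep_group(6), "SleET")
  expect_identical(classify_sleep_group(5), "NorET")
  expect_identical(classify_sleep_group(0), "NorET")
  expect_identical(classify_sleep_group(21), "SleET")
  expect_error(classify_sleep_group(22), "\\[0, 21\\]")
  expect_error(classify_sleep_group(-1), "\\[0, 21\\]")
})

test_that("classification and eligibility partition random tables", {
  set.seed(31)
  for (i in 1:10) {
    tab <- data.frame(
      PSQI = sample(0:21, 50, replace = TRUE),
      MMSE = sample(18:30, 50, replace = TRUE),
      HAMA = sample(0:25, 50, replace = TRUE),
      HAMD = sample(0:25, 50, replace = TRUE)
    )
    inc <- vapply(seq_len(50),
                  function(r) apply_eligibility(tab[r, ])$include, TRUE)
    brute <- !(tab$MMSE < 24 | tab$HAMA > 14 | tab$HAMD > 17)
    expect_identical(inc, brute)
    grp <- classify_sleep_group(tab$PSQI)
    expect_identical(grp == "SleET", tab$PSQI >= 6)
    expect_true(all(grp %in% c("SleET", "NorET")))
  }
})

test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(41)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  res <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("conditioning on the common driver removes the correlation", {
  set.seed(42)
  z <- rnorm(10000)
  x <- z + rnorm(10000)
  y <- -z + rnorm(10000)
  raw <- partial_correlation(x, y)
  adj <- partial_correlation(x, y, covariates = data.frame(z = z))
  expect_lt(raw$r, -0.3)
  expect_lt(abs(adj$r), 0.05)
})

test_that("partial r is invariant to affine rescaling", {
  set.seed(43)
  x <- rnorm(60); y <- rnorm(60)
  cov <- data.frame(a = rnorm(60), sex = sample(c("M", "F"), 60, TRUE))
  r1 <- partial_correlation(x, y, cov)$r
  r2 <- partial_correlation(10 * x - 3, -2 * y + 7,
                            transform(cov, a = 5 * a + 1))$r
  expect_equal(abs(r2), abs(r1), tolerance = 1e-12)
  expect_equal(sign(r2), -sign(r1))  # y was negated
})

test_that("degenerate correlation inputs error clearly", {
  set.seed(44)
  x <- rnorm(20)
  expect_error(partial_correlation(x, rnorm(19)), "equal length")
  cov <- data.frame(a = rnorm(20), b = rnorm(20))
  cov$c <- cov$a + cov$b
  expect_error(partial_correlation(x, rnorm(20), cov), "rank-deficient")
  expect_error(partial_correlation(x[1:4], rnorm(4),
                                   data.frame(a = rnorm(4), b = rnorm(4))),
               "n > k \\+ 2")
  expect_error(partial_correlation(x, rep(1, 20)), "constant")
})

test_that("the planted degree-TRS correlation is recovered", {
  negs <- vapply(1:20, function(s) {
    sp <- cohort_spec(group_sizes = c(SleET = 45, NorET = 5, HC = 5),
                      n_rois = 116, trs_degree_rho = -0.35,
                      seed = 7000 + s)
    co <- generate_cohort(sp, include_samples = FALSE)
    sel <- co$table$group == "SleET"
    res <- partial_correlation(
      co$expected_degree[sel, "Thalamus_L"], co$table$TRS[sel],
      covariates = co$table[sel, c("age", "sex", "education", "HAMA",
                                   "HAMD")])
    res$r
  }, 1.0)
  expect_gte(mean(negs < 0), 0.9)
  expect_lt(mean(negs), -0.15)
})

test_that("clinical_correlations returns the full grid with raw p", {
  sp <- cohort_spec(group_sizes = c(SleET = 20, NorET = 5, HC = 5),
                    n_rois = 12, trs_degree_rho = -0.5,
                    trs_target_roi = "ROI006", seed = 77)
  co <- generate_cohort(sp, include_samples = FALSE)
  auc <- co$expected_degree
  colnames(auc) <- paste0("degree|", colnames(auc))
  res <- clinical_correlations(auc, co$table, group = "SleET",
                               metrics = c("degree|ROI006",
                                           "degree|ROI001"))
  expect_true(all(c("metric", "variable", "r", "p", "n") %in% names(res)))
  expect_identical(nrow(res), 8L)  # 2 metrics x 4 variables
  expect_true(all(abs(res$r) <= 1))
})
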