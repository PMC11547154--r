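# Mann-Whitney, BH adjustment, Spearman, tiers, design comparisons and the
# clinical summary.

test_that("Mann-Whitney matches hand-enumerated cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 * 1/20 from full enumeration

  same <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$U, 16 / 2)
  expect_equal(same$p, 1)
})

test_that("Mann-Whitney agrees with the permutation oracle to 1e-12", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # unique values so the exact path is exercised
    v <- sample(seq(0, 1, length.out = 50), n1 + n2)
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    r <- mann_whitney(a, b)
    expect_equal(r$U, perm_mw_u(a, b), tolerance = 1e-12)
    expect_equal(r$p, perm_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("U statistics of the two orderings sum to n1*n2", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(2:15, 1)); b <- rnorm(sample(2:15, 1))
    if (i %% 2 == 0) b[1] <- a[1]  # exercise ties
    expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U,
                 length(a) * length(b))
  }
})

test_that("Mann-Whitney rejects empty or non-finite groups", {
  expect_error(mann_whitney(numeric(0), 1:3), "group a")
  expect_error(mann_whitney(1:3, numeric(0)), "group b")
  expect_error(mann_whitney(c(1, NA), 1:3), "non-finite")
})

test_that("BH adjustment matches hand-applied step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order invariance: adjustments attach to original positions
  p <- c(0.04, 0.001, 0.2, 0.03)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  expect_error(bh_adjust(1.2), "0, 1")
})

test_that("Spearman matches the ranks-Pearson oracle and handles ties", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rs, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rs, -1)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    if (i %% 3 == 0) { x[2] <- x[5]; y[1] <- y[9] }
    expect_equal(spearman_cor(x, y)$rs, ranks_pearson(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_cor(x, y)$rs
  expect_equal(spearman_cor(exp(x), y)$rs, base)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rs, base)
  expect_equal(spearman_cor(-1 / (x - min(x) + 1), y)$rs, base)
})

test_that("Spearman degenerate input reports undefined rs", {
  r <- spearman_cor(rep(1, 5), 1:5)
  expect_true(is.na(r$rs))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("significance tiers follow the figure-caption thresholds", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "*", "**", "***", "#"))
  expect_equal(significance_tier(0.05), "ns")  # strict inequality
})

test_that("planted tumor/normal shifts are detected in every gene", {
  co <- simulate_cohort(cohort_spec(seed = 101))
  res <- compare_design(co, "T_vs_N")
  expect_equal(nrow(res), 10)
  expect_true(all(res$p < 0.001))
  expect_true(all(res$delta_median > 0))
  expect_true(all(res$tier %in% c("***", "#")))
})

test_that("comparison designs validate strata and names", {
  co <- simulate_cohort(cohort_spec(n_patients = 10, n_normal = 8,
                                    n_donors = 2, n_pm_samples = 2,
                                    with_ct = FALSE, seed = 2))
  expect_error(compare_design(co, "no_such_design"), "unknown design")
  co$clinical$met_distant[co$clinical$tissue == "T"] <- FALSE
  expect_error(compare_design(co, "distant"), "empty stratum")
})

test_that("paired PM design restricts both groups to shared patients", {
  co <- simulate_cohort(cohort_spec(n_patients = 40, n_normal = 30,
                                    n_donors = 5, n_pm_samples = 12,
                                    with_ct = FALSE, seed = 3))
  res <- compare_design(co, "PM_vs_T_paired")
  expect_true(all(res$n1 == 12) && all(res$n2 == 12))
})

test_that("clinical summary reports percentages at printed precision", {
  cl <- data.frame(tissue = "T",
                   histology = rep(c("serous", "other"), c(106, 34)))
  s <- summarize_clinical(cl, "histology")
  expect_equal(s$percent[s$level == "serous"], 76)
  expect_equal(s$n[s$level == "serous"], 106)
})

test_that("hypermethylation calls use the N+D reference percentile", {
  co <- simulate_cohort(cohort_spec(seed = 12))
  calls <- call_hypermethylation(co, percentile = 0.95)
  thr <- attr(calls, "thresholds")
  cl <- co$clinical
  ref <- cl$sample_id[cl$tissue %in% c("N", "D")]
  for (g in c("GAS5", "ZNF667-AS1")) {
    expect_equal(unname(thr[g]),
                 unname(quantile(co$methylation[g, ref], 0.95)))
    # tumors sit mostly above the normal reference under the default shift
    expect_gt(mean(calls[, g]), 0.5)
  }
})
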