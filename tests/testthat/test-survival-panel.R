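# Kaplan-Meier, log-rank, Cox cumulative risk and the marker panel.

test_that("KM with no events is flat at 1", {
  cur <- km_curve(c(3, 6, 9), c(0, 0, 0))
  expect_equal(nrow(cur), 0)
  expect_equal(km_surv_at(cur, c(1, 100)), c(1, 1))
})

test_that("KM without censoring equals the empirical survival function", {
  cur <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cur$surv, c(2 / 3, 1 / 3, 0))
  set.seed(2)
  t <- round(rexp(40, 0.1), 1) + 0.1
  cur2 <- km_curve(t, rep(1, 40))
  emp <- vapply(cur2$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(cur2$surv, emp, tolerance = 1e-12)
})

test_that("KM matches a hand product-limit computation with censoring", {
  # subjects: times 1, 2, 2, 3, 4+, 5 (+ = censored at 4)
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 0, 1, 1, 0, 1)
  cur <- km_curve(time, event)
  # t=1: 6 at risk, 1 event -> 5/6
  # t=2: 5 at risk, 1 event (one censored at 2 stays in the risk set at 2)
  #      -> 5/6 * 4/5 = 2/3
  # t=3: 3 at risk, 1 event -> 2/3 * 2/3 = 4/9
  # t=5: 1 at risk, 1 event -> 0
  expect_equal(cur$time, c(1, 2, 3, 5))
  expect_equal(cur$surv, c(5 / 6, 2 / 3, 4 / 9, 0), tolerance = 1e-12)
  expect_error(km_curve(c(0, 1), c(1, 1)), "non-positive")
})

test_that("log-rank of a group against itself is zero", {
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("log-rank matches the O-E / variance oracle and is symmetric", {
  set.seed(3)
  for (i in 1:10) {
    n <- 30
    time <- rexp(n, 0.1) + 0.01
    event <- runif(n) < 0.7
    grp <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(grp)) < 2) next
    lr <- logrank_test(time, event, grp)
    expect_equal(lr$chisq, logrank_oracle(time, event, grp),
                 tolerance = 1e-8)
    flip <- logrank_test(time, event, ifelse(grp == "A", "B", "A"))
    expect_equal(lr$chisq, flip$chisq, tolerance = 1e-12)
  }
})

test_that("log-rank attains nominal type-I error under the null", {
  set.seed(4)
  rej <- vapply(1:200, function(i) {
    time <- rexp(60, 0.02); event <- time < runif(60, 0, 80)
    time <- pmin(time, runif(60, 0, 80))
    logrank_test(time + 0.01, event, rep(c("A", "B"), 30))$p < 0.05
  }, logical(1))
  rate <- mean(rej)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("Cox fit is stationary and recovers a null coefficient", {
  set.seed(5)
  n <- 500
  x <- cbind(marker = runif(n) < 0.5)
  time <- rexp(n, 0.05)
  cens <- runif(n, 0, 40)
  obs <- pmin(time, cens); event <- time <= cens
  fit <- cox_cumulative(obs, event, x)
  expect_lt(abs(fit$coef), 0.1)
  expect_lt(fit$score_norm, 1e-6)
  expect_true(fit$converged)
})

test_that("Cox rejects constant covariates", {
  expect_error(cox_cumulative(1:10, rep(1, 10),
                              cbind(flat = rep(1, 10))), "constant")
})

test_that("Cox recovers a planted hazard ratio of 2", {
  set.seed(6)
  n <- 1000
  x <- runif(n) < 0.5
  time <- rexp(n, 0.02 * ifelse(x, 2, 1))
  cens <- runif(n, 0, 200)
  fit <- cox_cumulative(pmin(time, cens), time <= cens, cbind(m = x))
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.3)
})

test_that("perfectly separating panel calls give sensitivity, specificity and AUC 1", {
  truth <- rep(c(TRUE, FALSE), each = 20)
  calls <- matrix(0, 40, 6)
  calls[truth, 1:5] <- 1
  pe <- panel_evaluate(calls, truth, k = 4)
  expect_equal(pe$sensitivity, 1)
  expect_equal(pe$specificity, 1)
  expect_equal(pe$auc, 1)
})

test_that("the printed operating point arises from its confusion counts", {
  # TP = 44, FN = 1, TN = 35, FP = 7 at k = 4
  truth <- rep(c(TRUE, FALSE), c(45, 42))
  score <- c(rep(5, 44), 3,            # one metastatic patient below k
             rep(4, 7), rep(0, 35))    # seven false positives at k
  calls <- t(vapply(score, function(s) as.numeric(seq_len(6) <= s),
                    numeric(6)))
  pe <- panel_evaluate(calls, truth, k = 4)
  expect_equal(unname(pe$confusion), c(44, 7, 35, 1))
  expect_equal(round(pe$sensitivity, 3), 0.978)
  expect_equal(round(pe$specificity, 3), 0.833)
})

test_that("label-independent calls give a chance-level AUC", {
  set.seed(7)
  calls <- matrix(runif(4000 * 6) < 0.5, 4000, 6)
  truth <- runif(4000) < 0.5
  pe <- panel_evaluate(calls, truth)
  expect_gt(pe$auc, 0.45)
  expect_lt(pe$auc, 0.55)
})

test_that("the ROC is monotone in k and the AUC is permutation invariant", {
  set.seed(8)
  calls <- matrix(runif(80 * 6) < 0.4, 80, 6)
  truth <- rowSums(calls) + rnorm(80) > 2
  pe <- panel_evaluate(calls, truth)
  expect_true(all(diff(pe$roc$tpr) >= 0))   # k decreases down the sweep
  expect_true(all(diff(pe$roc$fpr) >= 0))
  expect_equal(pe$roc$tpr[1], 0); expect_equal(pe$roc$fpr[1], 0)
  expect_equal(pe$roc$tpr[8], 1); expect_equal(pe$roc$fpr[8], 1)
  perm <- sample(80)
  expect_equal(panel_evaluate(calls[perm, ], truth[perm])$auc, pe$auc)
  expect_error(panel_evaluate(calls, truth, k = 9), "0..6")
})

test_that("planted methylation hazard separates the KM strata", {
  co <- simulate_cohort(cohort_spec(seed = 101, with_ct = FALSE))
  sv <- survival_by_methylation(co)
  expect_equal(nrow(sv$strata), 3)
  # hypermethylated stratum has worse survival at the horizon
  expect_true(all(sv$strata$surv_horizon_hyper <
                    sv$strata$surv_horizon_normal))
})
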