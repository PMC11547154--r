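# Survival analysis stratified by hypermethylation status and the k-of-n
# methylation marker panel for metastasis prediction.

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimator with ties handled by simultaneous events;
#' censored subjects leave the risk set just after their time.
#'
#' @param time follow-up times, months (> 0)
#' @param event logical/0-1 event indicator (TRUE = death observed)
#' @return data.frame of class `km_curve`: time (distinct event times),
#'   n_risk, n_event, surv (S(t)), std_err (Greenwood)
#' @export
km_curve <- function(time, event) {
  .check(length(time) >= 1, "need at least one record")
  .check(all(is.finite(time) & time > 0), "non-positive follow-up time")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep],
                    std_err = fit$std.err[keep] * fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability from a KM curve at given times
#' @param curve a [km_curve()]
#' @param t times at which to evaluate S(t)
#' @return numeric vector of survival probabilities (S(0) = 1)
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom chi-square from observed-minus-expected events
#' summed over the distinct event times.
#'
#' @param time follow-up times
#' @param event event indicators
#' @param group two-level grouping (factor/character/logical)
#' @return list with `chisq`, `p`, `n` (per-group sizes), `observed`,
#'   `expected`
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  .check(nlevels(g) == 2, "log-rank test needs exactly two groups")
  .check(all(table(g) > 0), "a group has zero subjects")
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ g)
  list(chisq = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.integer(table(g)), observed = unname(sd$obs),
       expected = unname(sd$exp))
}

#' Cox cumulative-risk regression on binary methylation factors
#'
#' Proportional-hazards fit with Breslow tie handling (Newton-Raphson
#' partial-likelihood maximization). Non-convergence and constant
#' covariates are reported explicitly.
#'
#' @param time follow-up times
#' @param event event indicators
#' @param covariates data.frame (or matrix) of binary covariates, e.g. the
#'   hypermethylation calls of the three survival marker genes
#' @return list with `coef`, `hr` (hazard ratios), `se`, `p` per covariate,
#'   `loglik`, `converged`, `score_norm` (partial-likelihood gradient norm
#'   at the optimum), `notes` (captured fitter diagnostics, e.g. separation)
#'   and the underlying `fit`
#' @export
cox_cumulative <- function(time, event, covariates) {
  X <- as.matrix(covariates) * 1
  .check(ncol(X) >= 1, "need at least one covariate")
  constant <- apply(X, 2, function(v) length(unique(v)) == 1)
  .check(!any(constant),
         sprintf("covariate(s) constant across subjects: %s",
                 paste(colnames(X)[constant], collapse = ", ")))
  notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(time, as.integer(event)) ~ X,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50)),
    warning = function(w) {
      # capture separation / infinite-beta diagnostics into the result
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  beta <- unname(stats::coef(fit))
  sn <- sqrt(sum(cox_breslow_score(beta, time, as.integer(event), X)^2))
  converged <- is.finite(sn) && sn < 1e-6
  if (!converged)
    warning("Cox partial-likelihood maximization did not converge ",
            sprintf("(score norm %.3g)", sn))
  list(coef = setNames(beta, colnames(X)),
       hr = setNames(unname(sm$coefficients[, "exp(coef)"]), colnames(X)),
       se = setNames(unname(sm$coefficients[, "se(coef)"]), colnames(X)),
       p = setNames(unname(sm$coefficients[, "Pr(>|z|)"]), colnames(X)),
       loglik = fit$loglik[2], converged = converged, score_norm = sn,
       notes = notes, fit = fit)
}

#' Breslow partial-likelihood score vector
#'
#' Gradient of the Cox log partial likelihood with Breslow tie handling at a
#' given coefficient vector; used as a stationarity diagnostic for
#' [cox_cumulative()].
#'
#' @param beta coefficient vector
#' @param time,event survival outcome
#' @param X covariate matrix
#' @return numeric gradient vector
#' @export
cox_breslow_score <- function(beta, time, event, X) {
  X <- as.matrix(X) * 1
  eta <- drop(X %*% beta)
  w <- exp(eta)
  score <- numeric(ncol(X))
  for (tt in unique(time[event == 1])) {
    risk <- time >= tt
    dead <- time == tt & event == 1
    d <- sum(dead)
    sw <- sum(w[risk])
    xbar <- colSums(X[risk, , drop = FALSE] * w[risk]) / sw
    score <- score + colSums(X[dead, , drop = FALSE]) - d * xbar
  }
  score
}

#' Evaluate the k-of-n methylation marker panel
#'
#' Predicts metastasis when at least `k` of the panel genes carry a
#' hypermethylation call. Reports the confusion table, sensitivity and
#' specificity at the given k, the full ROC traced by sweeping k from
#' n_genes + 1 (predict none) down to 0 (predict all), and the trapezoidal
#' AUC over those ROC points.
#'
#' @param calls logical/0-1 matrix, patients x panel genes
#' @param truth logical vector: the metastasis flag per patient
#' @param k call threshold (count of methylated markers), 0..n_genes
#' @return list of class `panel_evaluation`: k, confusion (TP/FP/TN/FN),
#'   sensitivity, specificity, roc (data.frame k, tpr, fpr), auc
#' @export
panel_evaluate <- function(calls, truth, k = 4) {
  calls <- as.matrix(calls) * 1
  truth <- as.logical(truth)
  .check(nrow(calls) == length(truth), "calls and truth sizes differ")
  .check(!anyNA(truth), "truth must be defined for all patients")
  ng <- ncol(calls)
  .check(k >= 0 && k <= ng, sprintf("k must lie in 0..%d", ng))
  score <- rowSums(calls)

  at_k <- function(kk) {
    pred <- score >= kk
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    c(TP = tp, FP = fp, TN = tn, FN = fn,
      tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  }
  roc <- t(vapply((ng + 1):0, at_k, numeric(6)))
  roc <- data.frame(k = (ng + 1):0, tpr = roc[, "tpr"], fpr = roc[, "fpr"])
  ord <- order(roc$fpr, roc$tpr)
  auc <- sum(diff(roc$fpr[ord]) *
               (roc$tpr[ord][-1] + roc$tpr[ord][-nrow(roc)]) / 2)

  cm <- at_k(k)
  structure(list(
    k = k, genes = colnames(calls),
    confusion = c(TP = unname(cm["TP"]), FP = unname(cm["FP"]),
                  TN = unname(cm["TN"]), FN = unname(cm["FN"])),
    sensitivity = unname(cm["tpr"]), specificity = 1 - unname(cm["fpr"]),
    roc = roc, auc = auc), class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf(
    "panel (k >= %d of %d markers): sensitivity %.3f, specificity %.3f, AUC %.3f\n",
    x$k, length(x$genes), x$sensitivity, x$specificity, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Survival analysis stratified by per-gene hypermethylation
#'
#' For each requested gene, compares overall survival of tumors with vs
#' without a hypermethylation call (KM curves, log-rank test), and reports
#' survival at a descriptive horizon (default 120 months).
#'
#' @param cohort an `lnc_cohort`
#' @param genes genes to stratify by (default the three survival markers)
#' @param percentile hypermethylation-call reference percentile
#' @param horizon descriptive survival horizon, months
#' @return list with `strata` (per-gene data.frame: n per stratum, chisq, p,
#'   S(horizon) per stratum) and `curves` (per gene, per stratum KM curves)
#' @export
survival_by_methylation <- function(cohort,
                                    genes = lnc_gene_sets()$survival,
                                    percentile = 0.95, horizon = 120) {
  calls <- call_hypermethylation(cohort, percentile)
  cl <- cohort$clinical
  tum <- cl[cl$tissue == "T" & is.finite(cl$os_months), ]
  curves <- list()
  rows <- lapply(genes, function(g) {
    hyper <- calls[tum$sample_id, g]
    if (length(unique(hyper)) < 2) {
      # a degenerate stratification (every tumor on one side of the cutoff)
      # is reported, not an error: small cohorts can produce it
      return(data.frame(gene = g, n_hyper = sum(hyper),
                        n_normal = sum(!hyper), chisq = NA_real_,
                        p = NA_real_, surv_horizon_hyper = NA_real_,
                        surv_horizon_normal = NA_real_,
                        stringsAsFactors = FALSE))
    }
    lr <- logrank_test(tum$os_months, tum$os_event, hyper)
    km1 <- km_curve(tum$os_months[hyper], tum$os_event[hyper])
    km0 <- km_curve(tum$os_months[!hyper], tum$os_event[!hyper])
    curves[[g]] <<- list(hyper = km1, normal = km0)
    data.frame(gene = g, n_hyper = sum(hyper), n_normal = sum(!hyper),
               chisq = lr$chisq, p = lr$p,
               surv_horizon_hyper = km_surv_at(km1, horizon),
               surv_horizon_normal = km_surv_at(km0, horizon),
               stringsAsFactors = FALSE)
  })
  list(strata = do.call(rbind, rows), curves = curves)
}
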