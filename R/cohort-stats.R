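# Cohort statistics: two-group Mann-Whitney comparisons with BH-FDR and
# figure-style significance tiers, Spearman methylation-expression
# correlation, hypermethylation calls and the clinical-table summary.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed with midrank ties. The p-value is exact (full enumeration of
#' the U distribution) when n1 + n2 <= 20 and there are no ties, otherwise
#' the normal approximation with tie and continuity correction is used.
#'
#' @param a,b numeric value vectors (each non-empty)
#' @return list with `U` (statistic for group a), `p` (two-sided), `n1`, `n2`
#' @export
mann_whitney <- function(a, b) {
  .check(length(a) >= 1, "group a is empty")
  .check(length(b) >= 1, "group b is empty")
  .check(all(is.finite(a)) && all(is.finite(b)),
         "non-finite values in input groups")
  n1 <- length(a); n2 <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(wilcox.test(a, b, exact = (n1 + n2 <= 20) && !ties,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1] (no NAs)
#' @return q-values in the original order, monotone over the sorted p-values
#'   and clipped at 1
#' @export
bh_adjust <- function(p) {
  .check(!anyNA(p), "NA p-values are not allowed")
  .check(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rs is the Pearson correlation of midranks; the two-sided p-value uses the
#' t-distribution approximation t = rs * sqrt((n-2) / (1-rs^2)) on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list with `rs`, `p`, `n`; `rs` is NA (with p NA) when either rank
#'   vector has zero variance
#' @export
spearman_cor <- function(x, y) {
  .check(length(x) == length(y), "x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  .check(n >= 3, "need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rs = NA_real_, p = NA_real_, n = n))
  rs <- cor(rx, ry)
  if (abs(rs) >= 1) return(list(rs = sign(rs), p = 0, n = n))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  list(rs = rs, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Figure-caption significance tiers
#'
#' @param p numeric vector of p-values
#' @return character vector: "#" for p < 1e-4, "***" for p < 1e-3, "**" for
#'   p < 0.01, "*" for p < 0.05, "ns" otherwise
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("#", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

# the comparison designs: each returns two sample-id sets from the cohort
.design_groups <- function(cohort, design) {
  cl <- cohort$clinical
  tum <- cl[cl$tissue == "T", ]
  flag_design <- function(col)
    list(g1 = tum$sample_id[tum[[col]]], g2 = tum$sample_id[!tum[[col]]],
         label = sprintf("T(%s+) vs T(%s-)", col, col))
  switch(design,
    "T_vs_N" = list(g1 = cl$sample_id[cl$tissue == "T"],
                    g2 = cl$sample_id[cl$tissue == "N"],
                    label = "T vs N"),
    "T_vs_D" = list(g1 = cl$sample_id[cl$tissue == "T"],
                    g2 = cl$sample_id[cl$tissue == "D"],
                    label = "T vs D"),
    "PM_vs_T_paired" = {
      pm <- cl[cl$tissue == "PM", ]
      both <- intersect(pm$patient, tum$patient)
      list(g1 = pm$sample_id[pm$patient %in% both],
           g2 = tum$sample_id[tum$patient %in% both],
           label = "PM vs paired T")
    },
    "stage" = list(g1 = tum$sample_id[tum$stage %in% c("III", "IV")],
                   g2 = tum$sample_id[tum$stage %in% c("I", "II")],
                   label = "stage III+IV vs I+II"),
    "extent" = list(g1 = tum$sample_id[tum$t_stage == "T3"],
                    g2 = tum$sample_id[tum$t_stage %in% c("T1", "T2")],
                    label = "T3 vs T1-T2"),
    "grade" = list(g1 = tum$sample_id[tum$grade %in% c("G3", "G4")],
                   g2 = tum$sample_id[tum$grade %in% c("G1", "G2")],
                   label = "G3-G4 vs G1-G2"),
    "lymphatic" = flag_design("met_lymphatic"),
    "peritoneal" = flag_design("met_peritoneal"),
    "omental" = flag_design("met_omental"),
    "distant" = flag_design("met_distant"),
    "ascites" = flag_design("ascites"),
    "any_metastasis" = flag_design("met_any"),
    stop(sprintf("unknown design '%s'", design), call. = FALSE)
  )
}

#' Available comparison designs
#' @return character vector of design names accepted by [compare_design()]
#' @export
comparison_designs <- function() {
  c("T_vs_N", "T_vs_D", "PM_vs_T_paired", "stage", "extent", "grade",
    "lymphatic", "peritoneal", "omental", "distant", "ascites",
    "any_metastasis")
}

#' Per-gene two-group comparison for one study design
#'
#' Runs the Mann-Whitney U test per gene for the chosen grouping of cohort
#' samples, adjusts the ten-gene family by Benjamini-Hochberg, and assigns
#' the figure-style significance tiers on the raw p-values. The paired
#' PM-vs-T design restricts both groups to patients contributing both a
#' primary tumor and a peritoneal metastasis sample.
#'
#' @param cohort an `lnc_cohort` (see [simulate_cohort()]) or a compatible
#'   list with `clinical` and `methylation` components
#' @param design one of [comparison_designs()]
#' @param values which matrix to compare: "methylation" (PMR) or
#'   "expression" (log2 level)
#' @return data.frame: gene, design, n1, n2, U, p, q, tier, delta_median
#'   (median of group 1 minus median of group 2)
#' @export
compare_design <- function(cohort, design,
                           values = c("methylation", "expression")) {
  values <- match.arg(values)
  g <- .design_groups(cohort, design)
  mat <- cohort[[values]]
  g$g1 <- intersect(g$g1, colnames(mat))
  g$g2 <- intersect(g$g2, colnames(mat))
  .check(length(g$g1) > 0 && length(g$g2) > 0,
         sprintf("design '%s' has an empty stratum (sizes %d and %d)",
                 design, length(g$g1), length(g$g2)))
  res <- lapply(rownames(mat), function(gene) {
    a <- mat[gene, g$g1]; b <- mat[gene, g$g2]
    mw <- mann_whitney(a, b)
    data.frame(gene = gene, design = design, label = g$label,
               n1 = mw$n1, n2 = mw$n2, U = mw$U, p = mw$p,
               delta_median = median(a) - median(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$tier <- significance_tier(out$p)
  out[, c("gene", "design", "label", "n1", "n2", "U", "p", "q",
          "tier", "delta_median")]
}

#' Methylation-expression correlation per gene
#'
#' Spearman correlation between per-sample methylation (PMR) and expression
#' (log2 level) across the chosen tissue class, one result per gene.
#'
#' @param cohort an `lnc_cohort`
#' @param tissue tissue class to correlate within (default "T")
#' @return data.frame: gene, rs, p, n
#' @export
methylation_expression_correlation <- function(cohort, tissue = "T") {
  ids <- cohort$clinical$sample_id[cohort$clinical$tissue == tissue]
  ids <- intersect(ids, colnames(cohort$methylation))
  ids <- intersect(ids, colnames(cohort$expression))
  do.call(rbind, lapply(rownames(cohort$methylation), function(gene) {
    s <- spearman_cor(cohort$methylation[gene, ids],
                      cohort$expression[gene, ids])
    data.frame(gene = gene, rs = s$rs, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  }))
}

#' Binary hypermethylation calls for tumor samples
#'
#' A tumor is called hypermethylated at a gene when its PMR exceeds the
#' reference percentile (default the 95th) of the pooled normal-tissue and
#' donor distributions for that gene.
#'
#' @param cohort an `lnc_cohort`
#' @param percentile reference percentile defining the cutoff
#' @param tissue tissue class to call (default "T")
#' @return logical matrix samples x genes, plus attribute `thresholds`
#' @export
call_hypermethylation <- function(cohort, percentile = 0.95, tissue = "T") {
  cl <- cohort$clinical
  ref_ids <- intersect(cl$sample_id[cl$tissue %in% c("N", "D")],
                       colnames(cohort$methylation))
  .check(length(ref_ids) >= 5, "too few reference (N/D) samples for calling")
  ids <- intersect(cl$sample_id[cl$tissue == tissue],
                   colnames(cohort$methylation))
  thr <- apply(cohort$methylation[, ref_ids, drop = FALSE], 1,
               quantile, probs = percentile, names = FALSE)
  calls <- t(cohort$methylation[, ids, drop = FALSE] > thr)
  attr(calls, "thresholds") <- thr
  calls
}

#' Summarize a clinical table
#'
#' Counts and percentages (two significant figures) per level of each
#' categorical clinical characteristic of the tumor samples.
#'
#' @param clinical clinical data.frame (rows = samples); tumor rows are
#'   selected by `tissue == "T"` when a tissue column is present
#' @param columns characteristics to tabulate (default: all of histology,
#'   stage, t_stage, n_stage, m_stage, grade and the metastasis/ascites
#'   flags that are present)
#' @return data.frame: characteristic, level, n, percent
#' @export
summarize_clinical <- function(clinical, columns = NULL) {
  df <- if ("tissue" %in% names(clinical))
    clinical[clinical$tissue == "T", ] else clinical
  if (is.null(columns))
    columns <- intersect(c("histology", "stage", "t_stage", "n_stage",
                           "m_stage", "grade", "met_lymphatic",
                           "met_peritoneal", "met_omental", "met_distant",
                           "met_any", "ascites"), names(df))
  n_total <- nrow(df)
  do.call(rbind, lapply(columns, function(col) {
    tab <- table(df[[col]], useNA = "no")
    data.frame(characteristic = col, level = names(tab),
               n = as.integer(tab),
               percent = signif(100 * as.integer(tab) / n_total, 2),
               stringsAsFactors = FALSE)
  }))
}
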