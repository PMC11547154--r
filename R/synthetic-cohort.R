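# Synthetic cohort generator. Defaults encode the study conditions the
# analysis is designed for: 140 primary tumors (with and without metastases),
# 123 matched normals, 18 donor tissues and 59 peritoneal metastases paired
# to primary tumors of the same patients; beta-distributed methylation on a
# 0-100 PMR scale with planted tumor/normal, metastasis-type and
# PM-reversal shifts; inversely coupled log2 expression; exponential
# survival tied to hypermethylation calls.

#' Specification of a synthetic study cohort
#'
#' All methylation quantities are on the beta (0-1) scale internally and
#' reported as PMR (0-100). Shifts are differences of beta-distribution
#' means.
#'
#' @param n_patients number of patients with a primary tumor sample (>= 2)
#' @param n_normal number of patients with a matched normal sample
#' @param n_donors number of cancer-free donor tissue samples
#' @param n_pm_samples number of peritoneal-metastasis samples, each paired
#'   to the primary tumor of the same (peritoneally disseminated) patient
#' @param fraction_with_metastasis named proportions of patients carrying
#'   each metastasis type (lymphatic, peritoneal, omental, distant) among
#'   the metastatic patients; `fraction_any` is the proportion of patients
#'   with any metastasis
#' @param fraction_any proportion of patients with at least one metastasis
#' @param fraction_ascites proportion of patients with ascites
#' @param gene_panel gene identifiers (default the ten lncRNA genes)
#' @param baseline_mean normal-tissue beta mean methylation
#' @param concentration beta concentration (a+b); larger = tighter marginals
#' @param methylation_shift per-gene normal-to-tumor mean shift (recycled)
#' @param metastasis_shift named list per metastasis type of per-gene extra
#'   shifts applied to tumors of patients with that metastasis type
#' @param pm_reversal per-gene signed shift applied to PM samples on top of
#'   the patient's tumor mean (negative = reversal)
#' @param coupling_slope per-gene slope of log2 expression on methylation
#'   proportion; must be <= 0 for inversely coupled genes
#' @param expr_intercept intercept of the expression model, log2 units
#' @param noise_sd expression noise standard deviation, log2 units (> 0)
#' @param survival_hazard_ratio per-gene hazard multiplier applied when the
#'   patient's tumor methylation exceeds the reference 95th percentile
#' @param baseline_hazard baseline event hazard per month
#' @param followup_max administrative follow-up horizon, months
#' @param censoring_rate probability that a patient's censoring time is
#'   drawn uniformly on (0, followup_max) (staggered accrual) rather than
#'   fixed at the horizon
#' @param with_ct also emit raw Ct tables that back-compute exactly to the
#'   planted methylation and expression values
#' @param seed integer seed; identical spec + seed gives identical output
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_patients = 140,
                        n_normal = 123,
                        n_donors = 18,
                        n_pm_samples = 59,
                        fraction_with_metastasis = c(lymphatic = 30 / 96,
                                                     peritoneal = 70 / 96,
                                                     omental = 70 / 96,
                                                     distant = 15 / 96),
                        fraction_any = 96 / 140,
                        fraction_ascites = 61 / 140,
                        gene_panel = lnc_genes(),
                        baseline_mean = 0.15,
                        concentration = 12,
                        methylation_shift = 0.25,
                        metastasis_shift = NULL,
                        pm_reversal = NULL,
                        coupling_slope = NULL,
                        expr_intercept = 2,
                        noise_sd = 0.5,
                        survival_hazard_ratio = NULL,
                        baseline_hazard = 0.0007,
                        followup_max = 180,
                        censoring_rate = 1,
                        with_ct = TRUE,
                        seed = 1L) {
  genes <- gene_panel
  named_per_gene <- function(x, default, field) {
    if (is.null(x)) x <- default
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, length(genes)), genes)
    if (is.null(names(x))) {
      .check(length(x) == length(genes),
             sprintf("%s must be named or of panel length", field))
      names(x) <- genes
    } else {
      full <- setNames(rep(0, length(genes)), genes)
      full[intersect(names(x), genes)] <- x[intersect(names(x), genes)]
      x <- full
    }
    .check(all(is.finite(x)), sprintf("non-finite value in %s", field))
    x
  }
  sets <- lnc_gene_sets()
  methylation_shift <- named_per_gene(methylation_shift, 0.25,
                                      "methylation_shift")
  if (is.null(pm_reversal))
    pm_reversal <- setNames(rep(-0.15, length(sets$reversal)), sets$reversal)
  pm_reversal <- named_per_gene(pm_reversal, 0, "pm_reversal")
  if (is.null(coupling_slope)) {
    coupling_slope <- setNames(rep(-3.5, length(genes)), genes)
    if ("GAS5" %in% genes) coupling_slope["GAS5"] <- -1.5
  }
  coupling_slope <- named_per_gene(coupling_slope, -3.5, "coupling_slope")
  .check(all(coupling_slope <= 0),
         "coupling_slope must be <= 0 for inversely coupled genes")
  if (is.null(survival_hazard_ratio))
    survival_hazard_ratio <- setNames(rep(2.2, length(sets$survival)),
                                      sets$survival)
  survival_hazard_ratio[setdiff(names(survival_hazard_ratio), genes)] <- NULL
  hr <- setNames(rep(1, length(genes)), genes)
  hr[names(survival_hazard_ratio)] <- survival_hazard_ratio
  if (is.null(metastasis_shift)) {
    metastasis_shift <- lapply(sets$metastasis_map, function(gs)
      setNames(rep(0.10, length(gs)), gs))
  }
  ms <- lapply(c(lymphatic = "lymphatic", peritoneal = "peritoneal",
                 omental = "omental", distant = "distant"), function(ty) {
    v <- setNames(rep(0, length(genes)), genes)
    x <- metastasis_shift[[ty]]
    v[intersect(names(x), genes)] <- x[intersect(names(x), genes)]
    v
  })

  props <- c(fraction_with_metastasis, any = fraction_any,
             ascites = fraction_ascites, censoring = censoring_rate)
  for (nm in names(props))
    .check(is.finite(props[[nm]]) && props[[nm]] >= 0 && props[[nm]] <= 1,
           sprintf("proportion '%s' must lie in [0, 1]", nm))
  .check(n_patients >= 2, "n_patients must be >= 2")
  .check(n_normal <= n_patients, "n_normal cannot exceed n_patients")
  .check(is.finite(noise_sd) && noise_sd > 0, "noise_sd must be positive")
  .check(is.finite(baseline_hazard) && baseline_hazard > 0,
         "baseline_hazard must be positive")
  .check(all(hr > 0), "survival_hazard_ratio must be positive")
  .check(baseline_mean > 0 && baseline_mean < 1,
         "baseline_mean must lie in (0, 1)")

  structure(list(
    n_patients = n_patients, n_normal = n_normal, n_donors = n_donors,
    n_pm_samples = n_pm_samples,
    fraction_with_metastasis = fraction_with_metastasis,
    fraction_any = fraction_any, fraction_ascites = fraction_ascites,
    gene_panel = genes, baseline_mean = baseline_mean,
    concentration = concentration,
    methylation_shift = methylation_shift, metastasis_shift = ms,
    pm_reversal = pm_reversal, coupling_slope = coupling_slope,
    expr_intercept = expr_intercept, noise_sd = noise_sd,
    survival_hazard_ratio = hr, baseline_hazard = baseline_hazard,
    followup_max = followup_max, censoring_rate = censoring_rate,
    with_ct = isTRUE(with_ct), seed = as.integer(seed)
  ), class = "cohort_spec")
}

# histology / stage / extent / grade composition of the simulated tumors,
# proportional to the reference clinical table
.CLINICAL_COMPOSITION <- list(
  histology = c("serous" = 106, "endometrioid" = 21, "mucinous" = 8,
                "clear cell" = 4, "undifferentiated" = 1),
  stage = c("I" = 25, "II" = 22, "III" = 78, "IV" = 15),
  t_stage = c("T1" = 27, "T2" = 24, "T3" = 89),
  grade = c("G1" = 36, "G2" = 36, "G3" = 66, "G4" = 2)
)

# deterministic counts for n samples from reference proportions
.proportional_counts <- function(ref, n) {
  cum <- round(cumsum(ref) / sum(ref) * n)
  counts <- diff(c(0, cum))
  rep(names(ref), counts)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.rbeta_mean <- function(n, mean, k) {
  mean <- .clamp(mean, 0.02, 0.97)
  rbeta(n, mean * k, (1 - mean) * k)
}

#' Simulate a synthetic study cohort
#'
#' Generates the clinical table, per-gene methylation (PMR) and log2
#' expression matrices, survival outcomes and (optionally) raw Ct tables
#' that quantify back to exactly the planted values through the qPCR module.
#'
#' @param spec a [cohort_spec()]
#' @return object of class `lnc_cohort`: list with `clinical` (data.frame),
#'   `methylation` and `expression` (gene x sample matrices),
#'   `ct_methylation`/`ct_expression` (when `spec$with_ct`) and `spec`
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  .check(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  genes <- spec$gene_panel
  np <- spec$n_patients
  k <- spec$concentration
  m0 <- spec$baseline_mean

  patients <- sprintf("P%03d", seq_len(np))

  # clinical composition (shuffled deterministic counts)
  comp <- lapply(.CLINICAL_COMPOSITION, .proportional_counts, n = np)
  ord <- lapply(comp, function(v) sample(v))

  # metastasis pattern: draw the any-metastasis set, then per-type flags
  met_any <- rep(FALSE, np)
  met_any[sample.int(np, round(spec$fraction_any * np))] <- TRUE
  fm <- spec$fraction_with_metastasis
  flags <- sapply(c("lymphatic", "peritoneal", "omental", "distant"),
                  function(ty) met_any & (runif(np) < fm[[ty]]))
  none <- met_any & rowSums(flags) == 0
  flags[none, "peritoneal"] <- TRUE  # guarantee at least one type
  ascites <- runif(np) < spec$fraction_ascites

  clinical_t <- data.frame(
    sample_id = paste0(patients, "_T"), patient = patients, tissue = "T",
    histology = ord$histology, stage = ord$stage, t_stage = ord$t_stage,
    grade = ord$grade,
    n_stage = ifelse(flags[, "lymphatic"], "N1-N3", "N0"),
    m_stage = ifelse(flags[, "distant"], "M1", "M0"),
    met_lymphatic = flags[, "lymphatic"],
    met_peritoneal = flags[, "peritoneal"],
    met_omental = flags[, "omental"],
    met_distant = flags[, "distant"],
    met_any = met_any, ascites = ascites,
    stringsAsFactors = FALSE)

  # matched normals, donors, PM samples
  n_ids <- sort(sample.int(np, spec$n_normal))
  pm_candidates <- which(flags[, "peritoneal"])
  if (length(pm_candidates) < spec$n_pm_samples)
    pm_candidates <- union(pm_candidates, which(met_any))
  .check(length(pm_candidates) >= spec$n_pm_samples,
         "not enough metastatic patients to draw PM samples from")
  pm_ids <- sort(sample(pm_candidates, spec$n_pm_samples))

  blank_clinical <- function(ids, patient, tissue) data.frame(
    sample_id = ids, patient = patient, tissue = tissue,
    histology = NA, stage = NA, t_stage = NA, grade = NA,
    n_stage = NA, m_stage = NA,
    met_lymphatic = NA, met_peritoneal = NA, met_omental = NA,
    met_distant = NA, met_any = NA, ascites = NA,
    stringsAsFactors = FALSE)

  clinical <- rbind(
    clinical_t,
    blank_clinical(paste0(patients[n_ids], "_N"), patients[n_ids], "N"),
    blank_clinical(sprintf("D%03d", seq_len(spec$n_donors)),
                   sprintf("D%03d", seq_len(spec$n_donors)), "D"),
    blank_clinical(paste0(patients[pm_ids], "_PM"), patients[pm_ids], "PM"))

  # per-gene per-sample beta means
  tumor_mean <- function(g) {
    extra <- Reduce(`+`, lapply(names(spec$metastasis_shift), function(ty)
      spec$metastasis_shift[[ty]][g] * flags[, ty]))
    m0 + spec$methylation_shift[g] + extra
  }
  samples <- clinical$sample_id
  meth <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (g in genes) {
    tm <- tumor_mean(g)
    meth[g, clinical$tissue == "T"] <-
      vapply(tm, function(mu) .rbeta_mean(1, mu, k), numeric(1))
    meth[g, clinical$tissue == "N"] <-
      .rbeta_mean(spec$n_normal, m0, k)
    meth[g, clinical$tissue == "D"] <-
      .rbeta_mean(spec$n_donors, m0, k)
    meth[g, clinical$tissue == "PM"] <-
      vapply(tm[pm_ids] + spec$pm_reversal[g], function(mu)
        .rbeta_mean(1, mu, k), numeric(1))
  }

  # expression: log2 level coupled to methylation proportion
  expr <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (g in genes) {
    expr[g, ] <- spec$expr_intercept +
      spec$coupling_slope[g] * meth[g, ] +
      rnorm(length(samples), sd = spec$noise_sd)
  }

  # survival: hazard multiplied per hypermethylation call at the true
  # reference 95th percentile of the normal beta
  thr <- qbeta(0.95, m0 * k, (1 - m0) * k)
  calls <- meth[, clinical$tissue == "T", drop = FALSE] > thr
  hazard <- spec$baseline_hazard *
    apply(spec$survival_hazard_ratio ^ calls, 2, prod)
  t_event <- rexp(np, rate = hazard)
  staggered <- runif(np) < spec$censoring_rate
  t_censor <- ifelse(staggered, runif(np, 0, spec$followup_max),
                     spec$followup_max)
  clinical$os_months <- NA_real_
  clinical$os_event <- NA
  tix <- clinical$tissue == "T"
  clinical$os_months[tix] <- pmin(t_event, t_censor)
  clinical$os_event[tix] <- t_event <= t_censor

  meth <- meth * 100  # PMR scale

  out <- list(clinical = clinical, methylation = meth, expression = expr,
              spec = spec)
  if (spec$with_ct) {
    out$ct_methylation <- .cohort_ct_methylation(meth)
    out$ct_expression <- .cohort_ct_expression(expr)
  }
  class(out) <- "lnc_cohort"
  out
}

# Ct tables that back-compute exactly: qMSP with control delta-Ct 0 and
# ACTB at 25 cycles; expression with reference at 20 cycles so that
# delta-Ct = -log2 level. PMR of 0 is encoded as an undetermined locus well.
.cohort_ct_methylation <- function(meth_pmr) {
  genes <- rownames(meth_pmr); samples <- colnames(meth_pmr)
  grid <- expand.grid(sample = samples, gene = genes,
                      stringsAsFactors = FALSE)
  pmr <- meth_pmr[cbind(grid$gene, grid$sample)]
  locus_ct <- ifelse(pmr > 0, 25 - log2(pmr / 100), NA_real_)
  one_rep <- function(rep_i) rbind(
    data.frame(sample = grid$sample, assay = grid$gene, ct = locus_ct,
               replicate = rep_i, stringsAsFactors = FALSE),
    data.frame(sample = samples, assay = "ACTB_conv", ct = 25,
               replicate = rep_i, stringsAsFactors = FALSE),
    data.frame(sample = "FM_CONTROL",
               assay = c(genes, "ACTB_conv"), ct = 25,
               replicate = rep_i, stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(1:3, one_rep))
  ct_table(df$sample, df$assay, df$ct, df$replicate)
}

.cohort_ct_expression <- function(expr, reference = "B2M") {
  genes <- rownames(expr); samples <- colnames(expr)
  grid <- expand.grid(sample = samples, gene = genes,
                      stringsAsFactors = FALSE)
  target_ct <- 20 - expr[cbind(grid$gene, grid$sample)]
  one_rep <- function(rep_i) rbind(
    data.frame(sample = grid$sample, assay = grid$gene, ct = target_ct,
               replicate = rep_i, stringsAsFactors = FALSE),
    data.frame(sample = samples, assay = reference, ct = 20,
               replicate = rep_i, stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(1:3, one_rep))
  ct_table(df$sample, df$assay, df$ct, df$replicate)
}

#' @export
print.lnc_cohort <- function(x, ...) {
  tab <- table(x$clinical$tissue)
  cat(sprintf(
    "synthetic cohort: %s genes; samples: %s\n",
    nrow(x$methylation),
    paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  invisible(x)
}

#' Write cohort tables to a directory
#'
#' Writes the clinical table, methylation and expression matrices (genes as
#' rows, samples as columns) as TSV, plus the Ct tables when present, and
#' the spec as JSON.
#'
#' @param cohort an `lnc_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    clinical = file.path(dir, "clinical.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    spec = file.path(dir, "cohort_spec.json"))
  write.table(cohort$clinical, paths["clinical"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  .write_matrix <- function(m, p) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_matrix(cohort$methylation, paths["methylation"])
  .write_matrix(cohort$expression, paths["expression"])
  spec <- cohort$spec
  jsonlite::write_json(spec[setdiff(names(spec), "gene_panel")],
                       paths["spec"], auto_unbox = TRUE, digits = NA)
  for (nm in c("ct_methylation", "ct_expression")) {
    if (!is.null(cohort[[nm]])) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write.table(cohort[[nm]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[nm] <- p
    }
  }
  invisible(paths)
}
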