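# End-to-end orchestration: simulate -> quantify -> cohort statistics ->
# screening -> alignment -> ceRNA assembly -> survival / panel, from one
# configuration with per-stage sub-seeds and a run manifest.

#' Pipeline configuration
#'
#' A single global seed is fanned out deterministically to per-stage
#' sub-seeds so that stages can be re-run in isolation and still reproduce.
#' The default screening network and sequence set plant one ceRNA triplet
#' (MAGI2-AS3 / miR-33b-5p / ZEB1, the hypothesis class the triplet stage
#' assembles) plus a strong lncRNA-mRNA duplex pair.
#'
#' @param seed global integer seed
#' @param cohort a [cohort_spec()] (its own seed is overridden by the
#'   stage sub-seed)
#' @param n_matrix_samples sample count of the co-expression matrix
#' @param network planted co-expression network (see
#'   [simulate_expression_matrix()]); default plants the triplet
#' @param n_background background gene count of the matrix
#' @param mrna_screen,mirna_screen,mi_mrna_screen [screen_config()]s for
#'   the three edge screens
#' @param sequences a [sequence_spec()], `"auto"` for the default planted
#'   set, or `NULL` to skip the alignment and seed stages
#' @param scheme a [scoring_scheme()]
#' @param triplet a [triplet_config()]
#' @param panel_k panel call threshold
#' @param hypermeth_percentile reference percentile of the binary
#'   hypermethylation call
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_spec(),
                            n_matrix_samples = 131,
                            network = NULL,
                            n_background = 40,
                            mrna_screen = screen_config(0.4, 1e-8,
                                                        "positive", "mRNA"),
                            mirna_screen = screen_config(-0.6, 0.0025,
                                                         "negative", "miRNA"),
                            mi_mrna_screen = screen_config(-0.4, 0.05,
                                                           "negative", "mRNA"),
                            sequences = "auto",
                            scheme = scoring_scheme(),
                            triplet = triplet_config(),
                            panel_k = 4,
                            hypermeth_percentile = 0.95) {
  if (is.null(network))
    network <- data.frame(
      lncRNA = c("MAGI2-AS3", "MAGI2-AS3"),
      partner = c("miR-33b-5p", "ZEB1"),
      rs = c(-0.8, 0.8),
      class = c("miRNA", "mRNA"),
      stringsAsFactors = FALSE)
  if (identical(sequences, "auto"))
    sequences <- sequence_spec(
      n_background = 2,
      length_range = c(800, 1600),
      planted_sites = data.frame(
        host = c("ZEB1", "MAGI2-AS3"),
        guest = c("MAGI2-AS3", "miR-33b-5p"),
        length = c(32L, NA),
        kind = c("revcomp", "7mer-m8"),
        position = c(301L, 501L),
        stringsAsFactors = FALSE))
  structure(list(seed = as.integer(seed), cohort = cohort,
                 n_matrix_samples = n_matrix_samples, network = network,
                 n_background = n_background,
                 mrna_screen = mrna_screen, mirna_screen = mirna_screen,
                 mi_mrna_screen = mi_mrna_screen,
                 sequences = sequences, scheme = scheme, triplet = triplet,
                 panel_k = panel_k,
                 hypermeth_percentile = hypermeth_percentile),
            class = "pipeline_config")
}

# deterministic sub-seed for stage i (kept below 2^31)
.stage_seed <- function(seed, i) (as.integer(seed) + 1000003L * i) %% 2147483647L

.param_checksum <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and aggregates the per-figure
#' style tables: tiered group comparisons for every design,
#' methylation-expression correlation, screening hit lists, gene-set
#' intersection, duplex site and seed-site tables, ceRNA triplets,
#' survival stratification, Cox cumulative risk and the panel evaluation.
#' Each stage records its parameter block, sub-seed and a checksum in the
#' manifest. When `out_dir` is given, tables are written as TSV and the
#' manifest plus a JSON summary to disk.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory
#' @param gene_sets optional named list of gene sets (GMT-style) for the
#'   intersection stage; defaults to a set built from the planted network
#'   targets
#' @return list of class `pipeline_run` with `report` (named tables),
#'   `manifest` and the intermediate objects (`cohort`, `matrix`, `seqs`)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         gene_sets = NULL) {
  .check(inherits(config, "pipeline_config"),
         "config must be a pipeline_config")
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, params, outputs) {
    manifest$stages[[stage]] <<- list(
      stage = stage, sub_seed = .stage_seed(config$seed,
                                            length(manifest$stages) + 1L),
      params = params, checksum = .param_checksum(params),
      outputs = outputs)
  }
  report <- list()

  # 1. cohort simulation
  spec <- config$cohort
  spec$seed <- .stage_seed(config$seed, 1L)
  cohort <- simulate_cohort(spec)
  note("simulate_cohort", spec[setdiff(names(spec), "gene_panel")],
       "clinical/methylation/expression")

  # 2. quantification round trip (Ct tables back to planted levels)
  if (!is.null(cohort$ct_methylation)) {
    errs <- vapply(rownames(cohort$methylation), function(g) {
      q <- qmsp_level(cohort$ct_methylation, g)
      planted <- cohort$methylation[g, q$sample]
      max(abs(q$pmr - planted) / pmax(planted, 1e-12), 0)
    }, numeric(1))
    report$quantification_check <- data.frame(
      gene = names(errs), max_rel_error = unname(errs))
    note("quantify", list(pmr_cap = 150), "quantification_check")
  }

  # 3. cohort statistics
  report$comparisons <- do.call(rbind, lapply(comparison_designs(),
    function(d) compare_design(cohort, d)))
  report$correlation <- methylation_expression_correlation(cohort)
  note("cohort_stats", list(designs = comparison_designs(),
                            tiers = c(0.05, 0.01, 0.001, 0.0001)),
       "comparisons/correlation")

  # 4. co-expression screening
  mat <- simulate_expression_matrix(config$n_matrix_samples, config$network,
                                    n_background = config$n_background,
                                    seed = .stage_seed(config$seed, 4L))
  rc <- attr(mat, "row_class")
  lncs <- names(rc)[rc == "lncRNA"]
  mirnas <- names(rc)[rc == "miRNA"]
  mrnas <- names(rc)[rc == "mRNA"]
  hits_mrna <- screen_partners(mat, lncs, config$mrna_screen,
                               partners = mrnas)
  hits_mirna <- screen_partners(mat, lncs, config$mirna_screen,
                                partners = mirnas)
  hits_mi_mrna <- if (length(mirnas))
    screen_partners(mat, mirnas, config$mi_mrna_screen, partners = mrnas)
  else hits_mrna[0, ]
  report$screen_mrna <- hits_mrna
  report$screen_mirna <- hits_mirna
  report$screen_mi_mrna <- hits_mi_mrna
  note("coexpr_screen",
       list(mrna = unclass(config$mrna_screen),
            mirna = unclass(config$mirna_screen),
            mi_mrna = unclass(config$mi_mrna_screen)),
       "screen_mrna/screen_mirna/screen_mi_mrna")

  # 5. gene-set intersection
  if (is.null(gene_sets))
    gene_sets <- list(EMT = unique(c("ZEB1", "ZEB2", "SNAI2", "VIM",
                                     "CDH1")))
  reports <- list()
  for (l in unique(hits_mrna$lncRNA)) for (sn in names(gene_sets)) {
    h <- hits_mrna[hits_mrna$lncRNA == l &
                     hits_mrna$direction == "positive", , drop = FALSE]
    reports[[paste(l, sn)]] <- intersect_gene_sets(h, gene_sets[[sn]], sn)
  }
  report$intersections <- if (length(reports))
    rank_lncRNA_activity(reports) else NULL
  note("intersect_gene_sets", list(sets = names(gene_sets)),
       "intersections")

  # 6. sequence alignment + seed classification
  seqs <- NULL
  if (!is.null(config$sequences)) {
    sspec <- config$sequences
    sspec$seed <- .stage_seed(config$seed, 6L)
    seqs <- simulate_sequences(sspec)
    planted <- attr(seqs, "planted")
    duplex <- list()
    seed_rows <- list()
    for (i in seq_len(nrow(planted))) {
      h <- planted$host[i]; g <- planted$guest[i]
      if (planted$kind[i] == "revcomp") {
        duplex[[paste(g, h)]] <- enumerate_sites(
          seqs[[g]], seqs[[h]], config$scheme,
          query_id = g, subject_id = h)
      } else {
        seed_rows[[paste(g, h)]] <- classify_seed(
          seqs[[g]], seqs[[h]], mirna_id = g, target_id = h)
      }
    }
    report$duplex_sites <- if (length(duplex))
      do.call(rbind, lapply(duplex, function(d) {
        s <- d$sites
        s$total_matched <- d$total_matched
        s$proportion <- d$proportion
        s
      })) else NULL
    report$seed_sites <- if (length(seed_rows))
      do.call(rbind, seed_rows) else NULL
    note("duplex_align", unclass(config$scheme),
         "duplex_sites/seed_sites")
  }

  # 7. ceRNA triplets
  report$triplets <- build_triplets(
    hits_mirna, hits_mi_mrna, hits_mrna,
    seed_sites = report$seed_sites, config = config$triplet)
  note("cerna_assembly", unclass(config$triplet), "triplets")

  # 8. survival and panel
  surv <- survival_by_methylation(cohort,
                                  percentile = config$hypermeth_percentile)
  report$survival <- surv$strata
  calls <- call_hypermethylation(cohort, config$hypermeth_percentile)
  cl <- cohort$clinical
  tum <- cl[cl$tissue == "T", ]
  sets <- lnc_gene_sets()
  cx <- calls[tum$sample_id, sets$survival, drop = FALSE]
  usable <- colnames(cx)[apply(cx, 2, function(v) length(unique(v)) > 1)]
  report$cox <- if (length(usable)) {
    # non-convergence/separation is carried in the table, not re-warned
    cox <- withCallingHandlers(
      cox_cumulative(tum$os_months, tum$os_event,
                     cx[, usable, drop = FALSE]),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(gene = usable, coef = cox$coef, hr = cox$hr, p = cox$p,
               converged = cox$converged, row.names = NULL)
  } else NULL
  panel <- panel_evaluate(calls[tum$sample_id, sets$panel],
                          truth = tum$met_any, k = config$panel_k)
  report$panel <- panel
  note("survival_panel",
       list(percentile = config$hypermeth_percentile, k = config$panel_k,
            panel_genes = sets$panel, survival_genes = sets$survival),
       "survival/cox/panel")

  run <- structure(list(report = report, manifest = manifest,
                        cohort = cohort, matrix = mat, seqs = seqs,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) .write_pipeline(run, out_dir)
  run
}

.write_pipeline <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  for (nm in names(run$report)) {
    x <- run$report[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[nm] <- p
    }
  }
  panel <- run$report$panel
  summary <- list(
    seed = run$config$seed,
    panel = list(k = panel$k, sensitivity = panel$sensitivity,
                 specificity = panel$specificity, auc = panel$auc,
                 confusion = as.list(panel$confusion)),
    n_triplets = nrow(run$report$triplets))
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
  outputs["summary"] <- sp
  run$manifest$outputs <- as.list(outputs)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(outputs, manifest = mp))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run (seed", x$config$seed, ")\n")
  cat("  tables:", paste(names(x$report), collapse = ", "), "\n")
  invisible(x)
}
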