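# Assembly of candidate lncRNA / miRNA / mRNA ceRNA triplets from screened
# correlation edges, optionally gated on sequence-site evidence.

#' Configuration of the ceRNA triplet join
#'
#' The ceRNA sign pattern requires a negative lncRNA-miRNA edge, a negative
#' miRNA-mRNA edge and a positive lncRNA-mRNA edge. Default bounds mirror
#' the empirical gates of the source design (lncRNA-miRNA rs <= -0.3 at
#' p < 0.05; miRNA-mRNA rs <= -0.4; lncRNA-mRNA rs >= +0.3). Sequence
#' evidence (a miRNA seed site on the lncRNA / mRNA) is attached when
#' available and only enforced when the corresponding `require_*` flag is
#' set: candidate triplets are hypotheses, and site evidence is advisory by
#' default.
#'
#' @param lnc_mi_rs_max negative upper bound on the lncRNA-miRNA rs
#' @param mi_mrna_rs_max negative upper bound on the miRNA-mRNA rs
#' @param lnc_mrna_rs_min positive lower bound on the lncRNA-mRNA rs
#' @param lnc_mi_p,mi_mrna_p,lnc_mrna_p per-edge p-value bounds
#' @param require_seed_on_lnc,require_seed_on_mrna enforce a seed site of
#'   the triplet's miRNA on the lncRNA / mRNA
#' @return object of class `triplet_config`
#' @export
triplet_config <- function(lnc_mi_rs_max = -0.3, mi_mrna_rs_max = -0.4,
                           lnc_mrna_rs_min = 0.3,
                           lnc_mi_p = 0.05, mi_mrna_p = 0.05,
                           lnc_mrna_p = 0.05,
                           require_seed_on_lnc = FALSE,
                           require_seed_on_mrna = FALSE) {
  .check(lnc_mi_rs_max < 0, "lnc_mi_rs_max must be negative")
  .check(mi_mrna_rs_max < 0, "mi_mrna_rs_max must be negative")
  .check(lnc_mrna_rs_min > 0, "lnc_mrna_rs_min must be positive")
  structure(list(lnc_mi_rs_max = lnc_mi_rs_max,
                 mi_mrna_rs_max = mi_mrna_rs_max,
                 lnc_mrna_rs_min = lnc_mrna_rs_min,
                 lnc_mi_p = lnc_mi_p, mi_mrna_p = mi_mrna_p,
                 lnc_mrna_p = lnc_mrna_p,
                 require_seed_on_lnc = require_seed_on_lnc,
                 require_seed_on_mrna = require_seed_on_mrna),
            class = "triplet_config")
}

#' Assemble candidate ceRNA triplets
#'
#' A relational join of three screened edge lists: a triplet
#' (lncRNA, miRNA, mRNA) is emitted iff all three edges exist and satisfy
#' the configuration bounds (and sign pattern). Hit lists use the column
#' layout of [screen_partners()]: `lncRNA`/`partner` for the two lncRNA
#' edges; for the miRNA-mRNA list the miRNA is in `lncRNA` and the mRNA in
#' `partner`. Seed-site tables (from [classify_seed()]) attach evidence
#' flags. Output is sorted by the minimum |rs| across edges, descending.
#'
#' @param lnc_mi hits of the lncRNA-miRNA screen
#' @param mi_mrna hits of the miRNA-mRNA screen
#' @param lnc_mrna hits of the lncRNA-mRNA screen
#' @param seed_sites optional seed-site table with columns mirna, target
#' @param config a [triplet_config()]
#' @return data.frame: lncRNA, miRNA, mRNA, per-edge rs and p, seed evidence
#'   flags, min_abs_rs
#' @export
build_triplets <- function(lnc_mi, mi_mrna, lnc_mrna,
                           seed_sites = NULL,
                           config = triplet_config()) {
  empty <- data.frame(lncRNA = character(0), miRNA = character(0),
                      mRNA = character(0),
                      lnc_mi_rs = numeric(0), lnc_mi_p = numeric(0),
                      mi_mrna_rs = numeric(0), mi_mrna_p = numeric(0),
                      lnc_mrna_rs = numeric(0), lnc_mrna_p = numeric(0),
                      seed_on_lnc = logical(0), seed_on_mrna = logical(0),
                      min_abs_rs = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(lnc_mi) || !nrow(mi_mrna) || !nrow(lnc_mrna)) return(empty)

  e1 <- lnc_mi[lnc_mi$rs <= config$lnc_mi_rs_max &
                 lnc_mi$p < config$lnc_mi_p, , drop = FALSE]
  e2 <- mi_mrna[mi_mrna$rs <= config$mi_mrna_rs_max &
                  mi_mrna$p < config$mi_mrna_p, , drop = FALSE]
  e3 <- lnc_mrna[lnc_mrna$rs >= config$lnc_mrna_rs_min &
                   lnc_mrna$p < config$lnc_mrna_p, , drop = FALSE]
  if (!nrow(e1) || !nrow(e2) || !nrow(e3)) return(empty)

  has_seed <- function(mirna, target) {
    if (is.null(seed_sites) || !nrow(seed_sites)) return(FALSE)
    any(seed_sites$mirna == mirna & seed_sites$target == target)
  }
  rows <- list()
  for (i in seq_len(nrow(e1))) {
    lnc <- e1$lncRNA[i]; mi <- e1$partner[i]
    targets <- e2[e2$lncRNA == mi, , drop = FALSE]
    for (j in seq_len(nrow(targets))) {
      mrna <- targets$partner[j]
      lm <- e3[e3$lncRNA == lnc & e3$partner == mrna, , drop = FALSE]
      if (!nrow(lm)) next
      s_lnc <- has_seed(mi, lnc)
      s_mrna <- has_seed(mi, mrna)
      if (config$require_seed_on_lnc && !s_lnc) next
      if (config$require_seed_on_mrna && !s_mrna) next
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA = lnc, miRNA = mi, mRNA = mrna,
        lnc_mi_rs = e1$rs[i], lnc_mi_p = e1$p[i],
        mi_mrna_rs = targets$rs[j], mi_mrna_p = targets$p[j],
        lnc_mrna_rs = lm$rs[1], lnc_mrna_p = lm$p[1],
        seed_on_lnc = s_lnc, seed_on_mrna = s_mrna,
        min_abs_rs = min(abs(e1$rs[i]), abs(targets$rs[j]), abs(lm$rs[1])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$min_abs_rs, out$lncRNA, out$miRNA, out$mRNA), ,
      drop = FALSE]
}
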