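# Co-expression partner screening at fixed rank-correlation thresholds and
# intersection of screened partner lists with EMT gene sets.

#' Screening configuration
#'
#' Defaults are the strict mRNA screen (rs > 0.4 at p < 1e-8). The
#' companion miRNA screen of the source design uses rs < -0.6 at p < 0.0025
#' (`screen_config(rs_threshold = -0.6, p_threshold = 0.0025,
#' sign = "negative", partner_class = "miRNA")`); a relaxed mRNA variant
#' (rs > 0.3, p < 1e-3) is used for sparsely correlated lncRNAs.
#'
#' @param rs_threshold signed correlation bound (|rs_threshold| < 1); the
#'   sign must agree with `sign`
#' @param p_threshold p-value bound in (0, 1]
#' @param sign "positive" (retain rs > threshold), "negative" (rs <
#'   threshold) or "both" (|rs| > |threshold|)
#' @param partner_class label carried to hits ("mRNA" or "miRNA")
#' @return object of class `screen_config`
#' @export
screen_config <- function(rs_threshold = 0.4, p_threshold = 1e-8,
                          sign = c("positive", "negative", "both"),
                          partner_class = c("mRNA", "miRNA")) {
  sign <- match.arg(sign)
  partner_class <- match.arg(partner_class)
  .check(abs(rs_threshold) < 1, "|rs_threshold| must be < 1")
  .check(p_threshold > 0 && p_threshold <= 1, "p_threshold must be in (0,1]")
  .check(!(sign == "positive" && rs_threshold < 0) &&
           !(sign == "negative" && rs_threshold > 0),
         "rs_threshold sign disagrees with the requested direction")
  structure(list(rs_threshold = rs_threshold, p_threshold = p_threshold,
                 sign = sign, partner_class = partner_class),
            class = "screen_config")
}

#' Screen candidate partners of lncRNAs by rank correlation
#'
#' Evaluates every (lncRNA, partner) pair with [spearman_cor()] and retains
#' hits satisfying the direction, correlation and p-value bounds of the
#' configuration. Self-pairs and lncRNA-lncRNA pairs are excluded unless
#' requested. Pairs with fewer than 5 shared complete samples are skipped.
#'
#' @param mat expression matrix, genes x samples
#' @param lncRNAs lncRNA row ids (all must be present in the matrix)
#' @param config a [screen_config()]
#' @param partners candidate partner row ids (default: all non-lncRNA rows)
#' @param include_lnc_partners also evaluate lncRNA-lncRNA pairs
#' @return data.frame of hits: lncRNA, partner, class, rs, p, n, direction
#' @export
screen_partners <- function(mat, lncRNAs, config = screen_config(),
                            partners = NULL,
                            include_lnc_partners = FALSE) {
  missing_lnc <- setdiff(lncRNAs, rownames(mat))
  .check(length(missing_lnc) == 0,
         sprintf("lncRNA id(s) absent from matrix: %s",
                 paste(missing_lnc, collapse = ", ")))
  if (is.null(partners)) partners <- setdiff(rownames(mat), lncRNAs)
  if (!include_lnc_partners) partners <- setdiff(partners, lncRNAs)

  keep <- function(rs, p) {
    if (!is.finite(rs)) return(FALSE)
    ok <- switch(config$sign,
                 positive = rs > config$rs_threshold,
                 negative = rs < config$rs_threshold,
                 both = abs(rs) > abs(config$rs_threshold))
    ok && p < config$p_threshold
  }
  rows <- list()
  for (l in lncRNAs) for (m in setdiff(partners, l)) {
    shared <- is.finite(mat[l, ]) & is.finite(mat[m, ])
    if (sum(shared) < 5) next
    s <- spearman_cor(mat[l, shared], mat[m, shared])
    if (keep(s$rs, s$p))
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA = l, partner = m, class = config$partner_class,
        rs = s$rs, p = s$p, n = s$n,
        direction = if (s$rs > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(lncRNA = character(0), partner = character(0),
                      class = character(0), rs = numeric(0), p = numeric(0),
                      n = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member symbols.
#'
#' @param path GMT file path
#' @return named list of character vectors; descriptions kept as attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Intersect a screened partner list with a gene set
#'
#' Symbols are matched exactly after uppercase normalization. The percentage
#' is rounded to two significant figures (round-half-to-even), matching the
#' printed precision of intersection-report tables.
#'
#' @param hits data.frame of screened hits sharing one lncRNA and one
#'   direction (or a character vector of partner symbols)
#' @param gene_set character vector of gene symbols
#' @param set_name name carried into the report
#' @return list of class `intersection_report`: lncRNA, set_name,
#'   n_correlated, n_intersected, percentage (NA when n_correlated = 0),
#'   intersected (symbols)
#' @export
intersect_gene_sets <- function(hits, gene_set, set_name = "gene set") {
  if (is.data.frame(hits)) {
    lnc <- unique(hits$lncRNA)
    .check(length(lnc) <= 1, "hits must share a single lncRNA")
    .check(length(unique(hits$direction)) <= 1,
           "hits must share a single direction")
    symbols <- unique(hits$partner)
    lnc <- if (length(lnc)) lnc else NA_character_
  } else {
    symbols <- unique(as.character(hits))
    lnc <- NA_character_
  }
  inter <- symbols[toupper(symbols) %in% toupper(gene_set)]
  n <- length(symbols); k <- length(inter)
  structure(list(lncRNA = lnc, set_name = set_name,
                 n_correlated = n, n_intersected = k,
                 percentage = if (n == 0) NA_real_ else signif(100 * k / n, 2),
                 intersected = inter),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("%s x %s: %d of %d correlated partners in set (%s%%)\n",
              x$lncRNA, x$set_name, x$n_intersected, x$n_correlated,
              format(x$percentage)))
  invisible(x)
}

#' Rank lncRNAs by partner counts
#'
#' Orders intersection reports by the number of correlated partners and by
#' the number of gene-set-intersected partners (ties broken alphabetically
#' by lncRNA id).
#'
#' @param reports list of `intersection_report` objects
#' @return data.frame ordered by `n_correlated` (descending) with both rank
#'   columns
#' @export
rank_lncRNA_activity <- function(reports) {
  df <- do.call(rbind, lapply(reports, function(r) data.frame(
    lncRNA = r$lncRNA, set_name = r$set_name,
    n_correlated = r$n_correlated, n_intersected = r$n_intersected,
    percentage = r$percentage, stringsAsFactors = FALSE)))
  ord_c <- order(-df$n_correlated, df$lncRNA)
  ord_i <- order(-df$n_intersected, df$lncRNA)
  df$rank_correlated <- match(seq_len(nrow(df)), ord_c)
  df$rank_intersected <- match(seq_len(nrow(df)), ord_i)
  df[ord_c, , drop = FALSE]
}
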