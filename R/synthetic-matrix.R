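#' Simulate an expression matrix with planted rank-correlation edges
#'
#' Gaussian-copula construction: each declared (lncRNA, partner) edge draws
#' the partner as a linear mixture of the lncRNA's latent normal score with
#' mixing weight chosen so the population Spearman correlation equals the
#' declared target (`rho_pearson = 2 sin(pi rs / 6)`). Undeclared pairs are
#' independent, so their sample correlations are centered at zero.
#'
#' @param n_samples number of sample columns (>= 5)
#' @param network data.frame with columns `lncRNA`, `partner`, `rs`
#'   (target Spearman correlation, |rs| < 1) and optionally `class`
#'   (e.g. "mRNA"/"miRNA", carried to the row annotation)
#' @param n_background number of additional independent background genes
#' @param seed integer seed
#' @return numeric matrix genes x samples with attribute `row_class`
#' @export
simulate_expression_matrix <- function(n_samples, network = NULL,
                                       n_background = 0, seed = 1L) {
  .check(n_samples >= 5, "n_samples must be >= 5")
  if (is.null(network))
    network <- data.frame(lncRNA = character(0), partner = character(0),
                          rs = numeric(0))
  .check(all(c("lncRNA", "partner", "rs") %in% names(network)),
         "network needs columns lncRNA, partner, rs")
  .check(all(abs(network$rs) < 1), "|target rs| must be < 1")
  .check(!anyDuplicated(network$partner),
         "duplicate gene identifiers: each partner may appear in one edge")
  .check(!any(network$partner %in% network$lncRNA),
         "duplicate gene identifiers: a partner id equals an lncRNA id")

  set.seed(as.integer(seed))
  lncs <- unique(network$lncRNA)
  bg <- if (n_background > 0) sprintf("BG%04d", seq_len(n_background))
        else character(0)
  genes <- c(lncs, network$partner, bg)
  .check(!anyDuplicated(genes), "duplicate gene identifiers in matrix rows")

  mat <- matrix(NA_real_, length(genes), n_samples,
                dimnames = list(genes, sprintf("S%04d", seq_len(n_samples))))
  for (l in lncs) mat[l, ] <- rnorm(n_samples)
  for (i in seq_len(nrow(network))) {
    rho <- 2 * sin(pi * network$rs[i] / 6)
    z <- mat[network$lncRNA[i], ]
    mat[network$partner[i], ] <- rho * z +
      sqrt(1 - rho^2) * rnorm(n_samples)
  }
  for (g in bg) mat[g, ] <- rnorm(n_samples)

  row_class <- setNames(rep("mRNA", length(genes)), genes)
  row_class[lncs] <- "lncRNA"
  if ("class" %in% names(network))
    row_class[network$partner] <- network$class
  attr(mat, "row_class") <- row_class
  mat
}

#' Read / write an expression matrix as TSV (genes as rows)
#' @param path file path
#' @return numeric matrix with gene rownames
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param mat matrix to write
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
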