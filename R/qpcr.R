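# qPCR quantification: delta-delta-Ct relative expression and qMSP relative
# methylation (percent of methylated reference, PMR).
#
# A Ct table is a long data.frame with columns sample, assay, replicate, ct.
# Undetermined wells are recorded as NA ct. Replicates are aggregated by
# arithmetic mean; a replicate spread beyond `replicate_tol` cycles flags the
# (sample, assay) triplet but does not exclude it.

#' Construct / validate a Ct table
#'
#' @param sample,assay character vectors (recycled to common length)
#' @param ct numeric cycle-threshold values; NA marks undetermined wells
#' @param replicate integer replicate index (defaults to within-group order)
#' @return data.frame of class `ct_table`
#' @export
ct_table <- function(sample, assay, ct, replicate = NULL) {
  n <- max(length(sample), length(assay), length(ct))
  df <- data.frame(sample = rep_len(as.character(sample), n),
                   assay = rep_len(as.character(assay), n),
                   ct = rep_len(as.numeric(ct), n),
                   stringsAsFactors = FALSE)
  .check(all(is.na(df$ct) | df$ct > 0),
         "Ct values must be positive or NA (undetermined)")
  df$replicate <- if (is.null(replicate))
    stats::ave(df$ct, df$sample, df$assay, FUN = seq_along)
  else rep_len(as.integer(replicate), n)
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table from TSV/CSV
#' @param path file with columns sample, assay, replicate, ct
#' @param sep field separator (tab by default)
#' @return `ct_table`
#' @export
read_ct_table <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  .check(all(c("sample", "assay", "ct") %in% names(df)),
         "Ct file must have columns sample, assay, ct")
  ct_table(df$sample, df$assay, df$ct,
           replicate = if ("replicate" %in% names(df)) df$replicate)
}

# mean Ct per (sample, assay); NA when all replicates undetermined.
# attaches a spread flag when replicates disagree by more than tol cycles.
.ct_means <- function(ct, replicate_tol = 0.5) {
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, 0) else c(mean(v), diff(range(v)))
  }
  sp <- split(ct$ct, paste(ct$sample, ct$assay, sep = "\r"), drop = TRUE)
  res <- t(vapply(sp, agg, numeric(2)))
  key <- do.call(rbind, strsplit(rownames(res), "\r", fixed = TRUE))
  data.frame(sample = key[, 1], assay = key[, 2],
             ct = res[, 1], spread_flag = res[, 2] > replicate_tol,
             stringsAsFactors = FALSE, row.names = NULL)
}

.ct_lookup <- function(means, sample, assay) {
  i <- which(means$sample == sample & means$assay == assay)
  if (!length(i)) NA_real_ else means$ct[i[1]]
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each case sample, delta-Ct = Ct(target) - mean Ct over the reference
#' assay(s), using replicate means. The calibrator delta-Ct is the mean over
#' the calibrator samples, or, in paired mode, the matched calibrator of the
#' same case (supply `pairing` as a named vector case -> calibrator). Fold
#' change is 2^-(delta-delta-Ct) and the twofold retention rule classifies
#' each level (see [retention_classify()]).
#'
#' Samples in which every replicate of a required assay is undetermined are
#' excluded; their ids and reasons are attached as attribute `excluded`.
#'
#' @param ct a [ct_table()]
#' @param target target assay id
#' @param reference reference assay id(s); several ids are combined by
#'   averaging their delta-Ct contribution (e.g. the two small-RNA
#'   references used for miRNA assays)
#' @param cases character vector of case sample ids
#' @param calibrators character vector of calibrator sample ids (ignored
#'   when `pairing` is given)
#' @param pairing optional named character vector mapping each case sample to
#'   its matched calibrator sample
#' @param replicate_tol replicate spread flag threshold, cycles
#' @return data.frame with sample, gene, delta_ct, delta_delta_ct, fold,
#'   classification
#' @export
relative_expression <- function(ct, target, reference, cases, calibrators,
                                pairing = NULL, replicate_tol = 0.5) {
  .check(inherits(ct, "ct_table"), "ct must be a ct_table")
  .check(length(cases) >= 1, "no case samples given")
  if (is.null(pairing))
    .check(length(calibrators) >= 1, "calibrator set must be non-empty")
  means <- .ct_means(ct, replicate_tol)

  dct <- function(s) {
    t_ct <- .ct_lookup(means, s, target)
    r_ct <- mean(vapply(reference, function(r) .ct_lookup(means, s, r),
                        numeric(1)))
    t_ct - r_ct
  }
  excluded <- character(0)
  rows <- lapply(cases, function(s) {
    d_case <- dct(s)
    d_cal <- if (is.null(pairing)) {
      mean(vapply(calibrators, dct, numeric(1)), na.rm = TRUE)
    } else {
      .check(s %in% names(pairing),
             sprintf("no calibrator paired with sample %s", s))
      dct(pairing[[s]])
    }
    if (!is.finite(d_case) || !is.finite(d_cal)) {
      excluded[[length(excluded) + 1L]] <<-
        sprintf("%s: undetermined Ct in a required assay", s)
      return(NULL)
    }
    ddct <- d_case - d_cal
    data.frame(sample = s, gene = target, delta_ct = d_case,
               delta_delta_ct = ddct, fold = 2^(-ddct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(sample = character(0), gene = character(0),
                      delta_ct = numeric(0), delta_delta_ct = numeric(0),
                      fold = numeric(0), stringsAsFactors = FALSE)
  out$classification <- retention_classify(out$delta_delta_ct)
  attr(out, "excluded") <- excluded
  out
}

#' Twofold retention rule for relative expression
#'
#' Changes of less than twofold (|delta-delta-Ct| <= 1, boundary inclusive)
#' are considered retentions; larger delta-delta-Ct is a downregulation
#' (fold < 0.5), smaller than -1 an upregulation.
#'
#' @param ddct numeric vector of delta-delta-Ct values (or a data.frame with
#'   a `delta_delta_ct` column)
#' @return character vector in {"down", "retained", "up"}
#' @export
retention_classify <- function(ddct) {
  if (is.data.frame(ddct)) ddct <- ddct$delta_delta_ct
  ifelse(ddct > 1, "down", ifelse(ddct < -1, "up", "retained"))
}

#' qMSP relative methylation level (PMR)
#'
#' Percent of methylated reference: for each sample,
#' PMR = 100 * 2^-[(Ct(locus) - Ct(ACTB))_sample - (Ct(locus) - Ct(ACTB))_control]
#' against a fully methylated control DNA. Bisulfite conversion is checked
#' per sample with the unconverted-ACTB control assay: amplification below
#' `conversion_ct_floor` cycles marks incomplete conversion, and the sample
#' is flagged (`conversion_ok = FALSE`).
#'
#' An undetermined Ct at the methylated-specific locus with a valid converted
#' ACTB assay yields PMR = 0 (below detection). PMR is capped at `pmr_cap`;
#' capped values are flagged.
#'
#' @param ct a [ct_table()] containing the locus assay, the converted-ACTB
#'   assay and optionally the unconverted-ACTB assay
#' @param locus methylated-specific locus assay id
#' @param samples sample ids to quantify (default: all samples except the
#'   control)
#' @param fully_methylated_control sample id of the 100%-methylated control
#' @param actb_converted,actb_unconverted assay ids of the conversion
#'   controls
#' @param conversion_ct_floor Ct below which unconverted ACTB amplification
#'   marks failed conversion
#' @param pmr_cap cap absorbing amplification-efficiency noise
#' @param replicate_tol replicate spread flag threshold, cycles
#' @return data.frame with sample, locus, pmr, conversion_ok, capped
#' @export
qmsp_level <- function(ct, locus, samples = NULL,
                       fully_methylated_control = "FM_CONTROL",
                       actb_converted = "ACTB_conv",
                       actb_unconverted = "ACTB_unconv",
                       conversion_ct_floor = 35,
                       pmr_cap = 150, replicate_tol = 0.5) {
  .check(inherits(ct, "ct_table"), "ct must be a ct_table")
  means <- .ct_means(ct, replicate_tol)
  .check(fully_methylated_control %in% means$sample,
         sprintf("fully methylated control sample '%s' is missing",
                 fully_methylated_control))
  if (is.null(samples))
    samples <- setdiff(unique(means$sample), fully_methylated_control)

  d_ctrl <- .ct_lookup(means, fully_methylated_control, locus) -
    .ct_lookup(means, fully_methylated_control, actb_converted)
  .check(is.finite(d_ctrl),
         "fully methylated control lacks locus or converted-ACTB Ct")

  rows <- lapply(samples, function(s) {
    actb <- .ct_lookup(means, s, actb_converted)
    locus_ct <- .ct_lookup(means, s, locus)
    unconv <- .ct_lookup(means, s, actb_unconverted)
    conv_ok <- !(is.finite(unconv) && unconv < conversion_ct_floor)
    pmr <- if (!is.finite(actb)) NA_real_
      else if (!is.finite(locus_ct)) 0   # below detection by convention
      else 100 * 2^(-((locus_ct - actb) - d_ctrl))
    capped <- is.finite(pmr) && pmr > pmr_cap
    data.frame(sample = s, locus = locus,
               pmr = if (capped) pmr_cap else pmr,
               conversion_ok = conv_ok, capped = capped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
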