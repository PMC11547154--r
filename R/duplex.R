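#' Scoring scheme for duplex alignment
#'
#' Parameters of the local alignment used to enumerate complementary sites
#' between transcript pairs. Scores are in arbitrary units per nucleotide;
#' the gap penalty is linear (applied per gapped nucleotide). G:U wobble
#' pairing can be given a score of its own; it is disabled by default since
#' the site metrics are defined on strict Watson-Crick identity in DNA space.
#'
#' @param match score for a complementary (or identical, in identity mode)
#'   base pair; must be positive
#' @param mismatch score for a non-complementary pair; must be <= 0
#' @param gap score per gapped nucleotide; must be <= 0
#' @param wobble_gt score for a G:U (G:T in DNA space) wobble pair, or `NULL`
#'   to disable wobble pairing
#' @param min_site_score minimal alignment score for a site to be reported
#' @param min_site_length minimal number of aligned columns in a site (>= 4)
#' @param max_sites maximal number of sites extracted per pair
#' @return object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap = -5,
                           wobble_gt = NULL,
                           min_site_score = 12, min_site_length = 6,
                           max_sites = 25) {
  .check(is.numeric(match) && match > 0, "match score must be positive")
  .check(is.numeric(mismatch) && mismatch <= 0, "mismatch score must be <= 0")
  .check(is.numeric(gap) && gap <= 0, "gap score must be <= 0")
  .check(is.null(wobble_gt) || is.numeric(wobble_gt),
         "wobble_gt must be NULL or numeric")
  .check(min_site_length >= 4, "min_site_length must be >= 4")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 wobble_gt = wobble_gt, min_site_score = min_site_score,
                 min_site_length = min_site_length, max_sites = max_sites),
            class = "scoring_scheme")
}

# Build the 4x4 pair-score and pair-match lookup used by the C++ kernel.
# In complementarity mode the subject is reverse-complemented first, so a
# "match" is simple base identity in the transformed space. Wobble G:U on
# the original strands maps to (G,A) and (T,C) in revcomp space.
.pair_tables <- function(scheme, mode) {
  sc <- matrix(scheme$mismatch, 4, 4, dimnames = list(.BASES, .BASES))
  diag(sc) <- scheme$match
  eq <- diag(4) == 1
  dimnames(eq) <- dimnames(sc)
  if (!is.null(scheme$wobble_gt) && mode == "complementarity") {
    sc["G", "A"] <- scheme$wobble_gt
    sc["T", "C"] <- scheme$wobble_gt
  }
  list(score = sc, ismatch = eq)
}

#' Smith-Waterman local alignment of two transcripts
#'
#' From-scratch local alignment with linear gap penalties. In
#' `complementarity` mode the subject `b` is reverse-complemented before the
#' standard dynamic program, so the reported alignment describes an
#' antiparallel duplex between the two given strands; coordinates are mapped
#' back to the input strand of `b`. Traceback is deterministic (diagonal
#' preferred over up over left; among equal-scoring end cells the smallest
#' coordinates win).
#'
#' @param a query sequence (character string; U accepted)
#' @param b subject sequence
#' @param scheme a [scoring_scheme()]
#' @param mode `"complementarity"` (default) or `"identity"`
#' @param .mask_a,.mask_b optional logical vectors marking positions excluded
#'   from alignment (used internally by [enumerate_sites()])
#' @return list of class `duplex_alignment` with elements `score`,
#'   `a_start`/`a_end` and `b_start`/`b_end` (0-based, half-open, on the
#'   given strands), `matched` (complementary base pairs in the site),
#'   `aligned_a`/`aligned_b` (gapped alignment strings; `aligned_b` is shown
#'   in the orientation actually aligned, i.e. reverse-complemented in
#'   complementarity mode) and `empty` (TRUE when no positive-scoring
#'   alignment exists)
#' @examples
#' sw <- smith_waterman("ACGTACGT", revcomp("ACGTACGT"))
#' sw$score   # 16 with the default match score of 2
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme(),
                           mode = c("complementarity", "identity"),
                           .mask_a = NULL, .mask_b = NULL) {
  mode <- match.arg(mode)
  a <- normalize_seq(a, "query")
  b <- normalize_seq(b, "subject")
  .check(nchar(a) > 0 && nchar(b) > 0, "sequences must be non-empty")
  ea <- .encode(a)
  bt <- if (mode == "complementarity") revcomp(b) else b
  eb <- .encode(bt)
  if (!is.null(.mask_a)) ea[.mask_a] <- 0L
  if (!is.null(.mask_b)) {
    mb <- if (mode == "complementarity") rev(.mask_b) else .mask_b
    eb[mb] <- 0L
  }
  tab <- .pair_tables(scheme, mode)
  r <- sw_align_cpp(ea, eb, tab$score, tab$ismatch, scheme$gap)

  # map subject coordinates back to the input strand of b
  m <- nchar(b)
  if (mode == "complementarity") {
    b_start <- m - r$b_end
    b_end <- m - r$b_start
  } else {
    b_start <- r$b_start
    b_end <- r$b_end
  }
  structure(list(
    score = r$score,
    a_start = r$a_start, a_end = r$a_end,
    b_start = b_start, b_end = b_end,
    matched = r$matched,
    aligned_a = .decode(r$aligned_a),
    aligned_b = .decode(r$aligned_b),
    mode = mode,
    empty = r$score <= 0
  ), class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  if (x$empty) {
    cat("<empty local alignment>\n")
    return(invisible(x))
  }
  cat(sprintf("local alignment (%s mode): score %g, %d matched nt\n",
              x$mode, x$score, x$matched))
  cat(sprintf("  query   [%d,%d)  %s\n", x$a_start, x$a_end, x$aligned_a))
  cat(sprintf("  subject [%d,%d)  %s\n", x$b_start, x$b_end, x$aligned_b))
  invisible(x)
}

#' Enumerate non-overlapping complementary sites between two transcripts
#'
#' Iterative best-site extraction: the maximal local alignment is accepted as
#' a site, its footprint on both sequences is masked, and the alignment is
#' repeated until the best score drops below `min_site_score` (or the site is
#' shorter than `min_site_length`, or `max_sites` is reached). The summary
#' metrics follow the convention of reporting the summed count of
#' complementary nucleotides over all accepted sites and that count divided
#' by the subject (mRNA) length.
#'
#' @inheritParams smith_waterman
#' @param query_id,subject_id identifiers carried into the report
#' @return list of class `duplex_report` with `sites` (data.frame: one row
#'   per site with coordinates, score and matched nucleotide count),
#'   `total_matched`, `proportion` (total matched / subject length),
#'   `query_id`, `subject_id`
#' @export
enumerate_sites <- function(a, b, scheme = scoring_scheme(),
                            mode = c("complementarity", "identity"),
                            query_id = "query", subject_id = "subject") {
  mode <- match.arg(mode)
  a <- normalize_seq(a, "query")
  b <- normalize_seq(b, "subject")
  mask_a <- rep(FALSE, nchar(a))
  mask_b <- rep(FALSE, nchar(b))
  sites <- list()
  repeat {
    if (length(sites) >= scheme$max_sites) break
    al <- smith_waterman(a, b, scheme, mode,
                         .mask_a = mask_a, .mask_b = mask_b)
    if (al$empty || al$score < scheme$min_site_score) break
    ncol_aln <- nchar(al$aligned_a)
    if (ncol_aln < scheme$min_site_length) break
    sites[[length(sites) + 1L]] <- data.frame(
      query_id = query_id, subject_id = subject_id,
      a_start = al$a_start, a_end = al$a_end,
      b_start = al$b_start, b_end = al$b_end,
      score = al$score, matched = al$matched,
      aligned_a = al$aligned_a, aligned_b = al$aligned_b,
      stringsAsFactors = FALSE)
    mask_a[seq.int(al$a_start + 1L, al$a_end)] <- TRUE
    mask_b[seq.int(al$b_start + 1L, al$b_end)] <- TRUE
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(query_id = character(0), subject_id = character(0),
               a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               score = numeric(0), matched = integer(0),
               aligned_a = character(0), aligned_b = character(0),
               stringsAsFactors = FALSE)
  total <- sum(sites$matched)
  structure(list(query_id = query_id, subject_id = subject_id,
                 sites = sites, total_matched = total,
                 proportion = total / nchar(b),
                 subject_length = nchar(b)),
            class = "duplex_report")
}

#' @export
print.duplex_report <- function(x, ...) {
  cat(sprintf("duplex report %s vs %s: %d site(s), %d matched nt, proportion %.3f\n",
              x$query_id, x$subject_id, nrow(x$sites), x$total_matched,
              x$proportion))
  invisible(x)
}

#' Longest exact complementary run between two sequences
#'
#' Length of the longest contiguous stretch of perfect Watson-Crick
#' complementarity between `a` and `b` (antiparallel). Used for null
#' calibration of spurious complementary runs in random sequence.
#'
#' @param a,b sequences (character strings)
#' @return integer run length
#' @export
longest_complementary_run <- function(a, b) {
  longest_common_run_cpp(.encode(normalize_seq(a)),
                         .encode(revcomp(b)))
}

# ---- miRNA seed-site classification ------------------------------------

#' Classify miRNA seed sites on a target transcript
#'
#' Scans the target for Watson-Crick complements of miRNA seed positions
#' (miRNA given 5'->3'; target scanned 5'->3'). Canonical taxonomy:
#' a 6mer pairs miRNA positions 2-7; 7mer-m8 pairs 2-8; 7mer-A1 pairs 2-7
#' with an A in the target opposite miRNA position 1; 8mer pairs 2-8 with
#' that A. The g-bulged 7mer-m8 variant pairs positions 2-8 with exactly one
#' unpaired G bulged on the target side inside the seed span. The strongest
#' type is reported per target position; overlapping weaker sites are
#' suppressed.
#'
#' @param mirna miRNA sequence (>= 8 nt, U accepted)
#' @param target target transcript sequence
#' @param mirna_id,target_id identifiers carried into the result
#' @param priority site types from strongest to weakest; sites of types not
#'   listed are not reported
#' @return data.frame with columns `mirna`, `target`, `position` (0-based
#'   start of the site on the target), `width` and `type`
#' @export
classify_seed <- function(mirna, target, mirna_id = "miRNA",
                          target_id = "target",
                          priority = c("8mer", "7mer-m8", "7mer-A1",
                                       "6mer", "7mer-m8 g-bulged")) {
  mirna <- normalize_seq(mirna, "miRNA")
  target <- normalize_seq(target, "target")
  .check(nchar(mirna) >= 8, "miRNA must be at least 8 nt long")
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  core6 <- revcomp(paste(m[2:7], collapse = ""))            # pairs 2-7
  t7m8 <- revcomp(paste(m[2:8], collapse = ""))             # pairs 2-8
  # all single-G target-side bulge variants of the 2-8 pairing, with the
  # bulged G strictly inside the seed span
  bulged <- unique(vapply(2:7, function(k) {
    paste0(substr(t7m8, 1, k - 1), "G", substr(t7m8, k, 7))
  }, character(1)))
  bulged <- setdiff(bulged, t7m8)

  tl <- nchar(target)
  find_at <- function(pat) {
    w <- nchar(pat)
    if (tl < w) return(integer(0))
    starts <- seq_len(tl - w + 1L)
    starts[vapply(starts, function(i)
      substr(target, i, i + w - 1L) == pat, logical(1))]
  }

  hits <- list()
  add <- function(type, start1, width) {
    hits[[length(hits) + 1L]] <<- data.frame(
      mirna = mirna_id, target = target_id,
      position = start1 - 1L, width = width, type = type,
      stringsAsFactors = FALSE)
  }
  for (i in find_at(t7m8)) {
    if (i + 7L <= tl && substr(target, i + 7L, i + 7L) == "A")
      add("8mer", i, 8L) else add("7mer-m8", i, 7L)
  }
  for (i in find_at(core6)) {
    if (i + 6L <= tl && substr(target, i + 6L, i + 6L) == "A")
      add("7mer-A1", i, 7L) else add("6mer", i, 6L)
  }
  for (pat in bulged) for (i in find_at(pat)) add("7mer-m8 g-bulged", i, 8L)

  empty <- data.frame(mirna = character(0), target = character(0),
                      position = integer(0), width = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  hits <- hits[hits$type %in% priority, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  # strongest first, then left-most; greedily suppress overlapping weaker hits
  hits <- hits[order(match(hits$type, priority), hits$position), , drop = FALSE]
  covered <- rep(FALSE, tl)
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    span <- seq.int(hits$position[r] + 1L, hits$position[r] + hits$width[r])
    if (!any(covered[span])) {
      keep[r] <- TRUE
      covered[span] <- TRUE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$position), , drop = FALSE]
}
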