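# Synthetic sequence generator: uniform-background transcripts with planted
# reverse-complement segments and miRNA seed sites, for exercising the
# alignment and seed-classification stages against known ground truth.

#' Specification of a synthetic sequence set
#'
#' @param n_background number of unplanted background transcripts
#' @param length_range two integers: host/background transcript lengths are
#'   drawn uniformly from this range
#' @param planted_sites data.frame with columns `host`, `guest`, `length`
#'   (site length, used for kind "revcomp"), `kind` (one of "revcomp",
#'   "6mer", "7mer-A1", "7mer-m8", "8mer", "7mer-m8 g-bulged") and
#'   `position` (1-based start of the planted site on the host)
#' @param guest_length length of generated guest sequences that are miRNAs
#'   (site kinds other than "revcomp")
#' @param seed integer seed
#' @return object of class `sequence_spec`
#' @export
sequence_spec <- function(n_background = 0,
                          length_range = c(500, 2000),
                          planted_sites = NULL,
                          guest_length = 22,
                          seed = 1L) {
  if (is.null(planted_sites))
    planted_sites <- data.frame(host = character(0), guest = character(0),
                                length = integer(0), kind = character(0),
                                position = integer(0))
  .check(all(c("host", "guest", "kind", "position") %in%
               names(planted_sites)),
         "planted_sites needs columns host, guest, kind, position")
  kinds <- c("revcomp", "6mer", "7mer-A1", "7mer-m8", "8mer",
             "7mer-m8 g-bulged")
  .check(all(planted_sites$kind %in% kinds),
         sprintf("site kind must be one of: %s",
                 paste(kinds, collapse = ", ")))
  .check(length(length_range) == 2 && length_range[1] >= 30 &&
           length_range[2] >= length_range[1],
         "length_range must be two increasing values >= 30")
  structure(list(n_background = n_background,
                 length_range = as.integer(length_range),
                 planted_sites = planted_sites,
                 guest_length = as.integer(guest_length),
                 seed = as.integer(seed)),
            class = "sequence_spec")
}

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# Target-site insert for a seed of the declared type. The insert controls
# its own flanks: the nucleotide opposite miRNA position 1 where the type
# constrains it, and, for types pairing only positions 2-7, a leading guard
# base that cannot pair miRNA position 8 (otherwise a chance upstream
# complement would upgrade the site). Returns the insert string plus the
# 0-based offset of the classifiable site within it.
.seed_target_site <- function(mirna, kind) {
  m <- strsplit(normalize_seq(mirna), "", fixed = TRUE)[[1]]
  core6 <- revcomp(paste(m[2:7], collapse = ""))
  t7m8 <- revcomp(paste(m[2:8], collapse = ""))
  guard <- setdiff(c("A", "C"), substr(t7m8, 1, 1))[1]
  switch(kind,
    "6mer" = list(insert = paste0(guard, core6, "C"), offset = 1L),
    "7mer-A1" = list(insert = paste0(guard, core6, "A"), offset = 1L),
    "7mer-m8" = list(insert = paste0(t7m8, "C"), offset = 0L),
    "8mer" = list(insert = paste0(t7m8, "A"), offset = 0L),
    "7mer-m8 g-bulged" = list(                 # bulged G inside the core span
      insert = paste0(substr(t7m8, 1, 4), "G", substr(t7m8, 5, 7), "C"),
      offset = 0L),
    stop("unknown seed kind"))
}

#' Simulate transcript sequences with planted sites
#'
#' Background composition is uniform over A/C/G/T. A planted
#' reverse-complement segment copies a seeded random stretch of the guest
#' and implants its reverse complement into the host, so the pair aligns
#' with full-length exact complementarity. A planted seed site implants the
#' exact target-site string of the declared type (constructed from the guest
#' miRNA seed), so the classifier recovers the declared type by
#' construction. Overlapping planted sites within one host are rejected.
#'
#' @param spec a [sequence_spec()]
#' @return named character vector of sequences (DNA alphabet) with attribute
#'   `planted` (the realized site table, including guest segment coordinates
#'   for revcomp sites)
#' @export
simulate_sequences <- function(spec = sequence_spec()) {
  .check(inherits(spec, "sequence_spec"), "spec must be a sequence_spec")
  set.seed(spec$seed)
  ps <- spec$planted_sites

  hosts <- unique(ps$host)
  guests <- setdiff(unique(ps$guest), hosts)
  mirna_guests <- unique(ps$guest[ps$kind != "revcomp"])

  seqs <- list()
  lr <- spec$length_range
  for (h in hosts)
    seqs[[h]] <- .random_seq(sample(lr[1]:lr[2], 1))
  for (g in guests) {
    n <- if (g %in% mirna_guests) spec$guest_length
         else sample(lr[1]:lr[2], 1)
    seqs[[g]] <- .random_seq(n)
  }
  if (spec$n_background > 0)
    for (b in sprintf("BG%04d", seq_len(spec$n_background)))
      seqs[[b]] <- .random_seq(sample(lr[1]:lr[2], 1))

  planted <- NULL
  occupied <- lapply(seqs, function(s) rep(FALSE, nchar(s)))
  for (i in seq_len(nrow(ps))) {
    host <- ps$host[i]; guest <- ps$guest[i]; kind <- ps$kind[i]
    pos <- ps$position[i]
    if (kind == "revcomp") {
      len <- ps$length[i]
      .check(is.finite(len) && len >= 4, "revcomp site length must be >= 4")
      gmax <- nchar(seqs[[guest]]) - len + 1L
      .check(gmax >= 1, sprintf(
        "site %d: guest %s shorter than the site", i, guest))
      gstart <- sample.int(gmax, 1)
      segment <- substr(seqs[[guest]], gstart, gstart + len - 1L)
      insert <- revcomp(segment)
      # break chance extension of the duplex at both flanks so the planted
      # coordinates are recovered exactly: the host base left of the insert
      # pairs the guest base right of the segment (and vice versa)
      non_pairing <- function(guest_pos) {
        if (guest_pos < 1 || guest_pos > nchar(seqs[[guest]]))
          return(NA_character_)
        forb <- .complement_base(substr(seqs[[guest]], guest_pos, guest_pos))
        setdiff(c("A", "C"), forb)[1]
      }
      fix_flank <- function(host_pos, repl) {
        if (!is.na(repl) && host_pos >= 1 && host_pos <= nchar(seqs[[host]]) &&
            !occupied[[host]][host_pos])
          substr(seqs[[host]], host_pos, host_pos) <<- repl
      }
      fix_flank(pos - 1L, non_pairing(gstart + len))
      fix_flank(pos - 2L, non_pairing(gstart + len + 1L))
      fix_flank(pos + len, non_pairing(gstart - 1L))
      fix_flank(pos + len + 1L, non_pairing(gstart - 2L))
    } else {
      st <- .seed_target_site(seqs[[guest]], kind)
      insert <- st$insert
      site_offset <- st$offset
      gstart <- NA_integer_
      len <- nchar(insert)
    }
    hlen <- nchar(seqs[[host]])
    .check(pos >= 1 && pos + nchar(insert) - 1L <= hlen,
           sprintf("site %d does not fit within host %s", i, host))
    span <- seq.int(pos, pos + nchar(insert) - 1L)
    .check(!any(occupied[[host]][span]),
           sprintf("planted sites overlap within host %s", host))
    occupied[[host]][span] <- TRUE
    substr(seqs[[host]], pos, pos + nchar(insert) - 1L) <- insert
    # `position` is the 1-based start of the recoverable site itself
    # (for guarded seed inserts that is one base into the insert)
    site_pos <- if (kind == "revcomp") pos else pos + site_offset
    site_width <- if (kind == "revcomp") nchar(insert)
      else nchar(insert) - site_offset - 1L +
        (kind %in% c("7mer-A1", "8mer"))  # the A1 base is part of the site
    planted <- rbind(planted, data.frame(
      host = host, guest = guest, kind = kind, position = site_pos,
      width = site_width, guest_start = gstart, length = len,
      stringsAsFactors = FALSE))
  }
  out <- unlist(seqs)
  attr(out, "planted") <- planted
  out
}
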