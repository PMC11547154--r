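# Smith-Waterman alignment, site enumeration and seed classification.

test_that("a perfect duplex aligns full length at 2 per base pair", {
  a <- "ACGTACGT"
  al <- smith_waterman(a, revcomp(a))
  expect_equal(al$score, 16)
  expect_equal(al$matched, 8)
  expect_equal(c(al$a_start, al$a_end), c(0, 8))
  expect_equal(c(al$b_start, al$b_end), c(0, 8))
})

test_that("non-pairing sequences give an empty alignment", {
  al <- smith_waterman("AAAA", "AAAA")  # A cannot pair with A
  expect_true(al$empty)
  expect_equal(al$score, 0)
})

test_that("illegal characters are rejected with their position", {
  expect_error(smith_waterman("ACGXACGT", "ACGT"), "position 4")
  expect_error(smith_waterman("ACGT", ""), "single character|non-empty")
})

test_that("U is accepted and mapped to T", {
  al <- smith_waterman("ACGU", revcomp("ACGT"))
  expect_equal(al$score, 8)
})

test_that("scores equal the exhaustive recursion oracle at tiny lengths", {
  set.seed(31)
  for (i in 1:40) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    got <- smith_waterman(a, b, mode = "identity")$score
    expect_equal(got, sw_recursive_oracle(a, b), info = paste(a, b))
  }
})

test_that("scores equal the substring Needleman-Wunsch oracle", {
  set.seed(32)
  for (i in 1:12) {
    a <- random_dna(sample(6:12, 1))
    b <- random_dna(sample(6:12, 1))
    got <- smith_waterman(a, b, mode = "identity")$score
    expect_equal(got, sw_substring_oracle(a, b), info = paste(a, b))
  }
})

test_that("scores equal the Biostrings local-alignment oracle at length <= 30", {
  sub <- matrix(-3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(sub) <- 2
  set.seed(33)
  for (i in 1:200) {
    a <- random_dna(sample(8:30, 1))
    b <- random_dna(sample(8:30, 1))
    got <- smith_waterman(a, b, mode = "identity")$score
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = 5, scoreOnly = TRUE)
    expect_equal(got, max(0, pa), info = paste(a, b))
  }
})

test_that("complementarity mode equals identity mode on the reverse complement", {
  set.seed(34)
  for (i in 1:20) {
    a <- random_dna(40); b <- random_dna(40)
    comp <- smith_waterman(a, b, mode = "complementarity")
    ident <- smith_waterman(a, revcomp(b), mode = "identity")
    expect_equal(comp$score, ident$score)
    expect_equal(comp$matched, ident$matched)
    expect_equal(c(comp$a_start, comp$a_end), c(ident$a_start, ident$a_end))
    # identity coordinates are on the reversed strand
    expect_equal(comp$b_start, 40 - ident$b_end)
    expect_equal(comp$b_end, 40 - ident$b_start)
  }
})

test_that("wobble pairs score only when enabled", {
  # G:U wobble on the given strands: query G opposite subject T
  a <- "GGGGGG"
  b <- "TTTTTT"   # revcomp(b) = AAAAAA; G~A in revcomp space is the wobble
  off <- smith_waterman(a, b, scoring_scheme())
  on <- smith_waterman(a, b, scoring_scheme(wobble_gt = 1,
                                            min_site_length = 4))
  expect_true(off$empty)
  expect_equal(on$score, 6)
  expect_equal(on$matched, 0)  # wobble pairs are not counted as matched
})

test_that("site enumeration masks accepted sites and never overlaps", {
  set.seed(35)
  for (i in 1:10) {
    a <- random_dna(300); b <- random_dna(300)
    rep <- enumerate_sites(a, b, scoring_scheme(max_sites = 10))
    s <- rep$sites
    if (nrow(s) < 2) next
    for (x in list(cbind(s$a_start, s$a_end), cbind(s$b_start, s$b_end))) {
      x <- x[order(x[, 1]), , drop = FALSE]
      expect_true(all(x[-1, 1] >= x[-nrow(x), 2]))
    }
    # scores are non-increasing across extraction rounds
    expect_true(all(diff(s$score) <= 0))
    expect_true(all(s$score >= 12))
  }
})

test_that("raising min_site_score never increases total matched", {
  set.seed(36)
  for (i in 1:8) {
    a <- random_dna(250); b <- random_dna(250)
    lo <- enumerate_sites(a, b, scoring_scheme(min_site_score = 12))
    hi <- enumerate_sites(a, b, scoring_scheme(min_site_score = 20))
    expect_lte(hi$total_matched, lo$total_matched)
  }
})

test_that("the Table-2 style proportion metric is total matched over subject length", {
  # query is the complementary probe itself; subject background cannot pair
  # with it, so the planted site is the only reportable alignment
  set.seed(37)
  segment <- paste(sample(c("A", "C", "G"), 32, replace = TRUE),
                   collapse = "")
  subject <- paste(rep("A", 1231), collapse = "")
  substr(subject, 601, 632) <- revcomp(segment)
  rep <- enumerate_sites(segment, subject, subject_id = "mRNA")
  expect_equal(nrow(rep$sites), 1)
  expect_equal(rep$total_matched, 32)
  expect_equal(signif(rep$proportion, 2), 0.026)
})

test_that("seed sites classify by the canonical taxonomy", {
  mir <- "UGGAGUGUGACAAUGGUGUUUG"  # 22-nt miRNA, 5'->3'
  m <- strsplit(chartr("U", "T", mir), "")[[1]]
  core <- revcomp(paste(m[2:7], collapse = ""))
  t7m8 <- revcomp(paste(m[2:8], collapse = ""))
  pad <- function(site) paste0(strrep("C", 30), site, strrep("C", 30))

  expect_equal(classify_seed(mir, pad(paste0(t7m8, "A")))$type, "8mer")
  expect_equal(classify_seed(mir, pad(paste0(t7m8, "C")))$type, "7mer-m8")
  expect_equal(classify_seed(mir, pad(paste0(core, "A")))$type, "7mer-A1")
  expect_equal(classify_seed(mir, pad(paste0(core, "C")))$type, "6mer")
  bulged <- paste0(substr(t7m8, 1, 3), "G", substr(t7m8, 4, 7), "C")
  expect_equal(classify_seed(mir, pad(bulged))$type, "7mer-m8 g-bulged")
  expect_equal(nrow(classify_seed(mir, strrep("C", 50))), 0)
})

test_that("the strongest seed type is reported per position", {
  mir <- "UGGAGUGUGACAAUGGUGUUUG"
  m8site <- paste0(revcomp(substr(chartr("U", "T", mir), 2, 8)), "A")
  target <- paste0(strrep("C", 20), m8site, strrep("C", 20))
  hits <- classify_seed(mir, target)
  # the embedded 6mer/7mer variants must be subsumed by the 8mer call
  expect_equal(nrow(hits), 1)
  expect_equal(hits$type, "8mer")
  expect_equal(hits$position, 20)
})

test_that("a short miRNA is rejected", {
  expect_error(classify_seed("ACGUACG", strrep("A", 30)), "at least 8")
})
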