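# delta-delta-Ct quantification and qMSP PMR

test_that("relative expression reproduces closed-form folds", {
  ct <- ct_table(
    sample = rep(c("case", "cal"), each = 2),
    assay = rep(c("TGT", "REF"), 2),
    ct = c(24, 20, 22, 20))
  r <- relative_expression(ct, "TGT", "REF", cases = "case",
                           calibrators = "cal")
  expect_equal(r$delta_delta_ct, 2)
  expect_equal(r$fold, 0.25)
  expect_equal(r$classification, "down")

  # target Ct = reference Ct everywhere -> fold exactly 1
  ct1 <- ct_table(sample = rep(c("s", "c"), each = 2),
                  assay = rep(c("TGT", "REF"), 2), ct = c(21, 21, 25, 25))
  expect_equal(relative_expression(ct1, "TGT", "REF", "s", "c")$fold, 1)
})

test_that("triplicates aggregate by arithmetic mean", {
  ct <- ct_table(
    sample = c(rep("case", 4), rep("cal", 2)),
    assay = c("TGT", "TGT", "TGT", "REF", "TGT", "REF"),
    ct = c(24.1, 23.9, 24.0, 20, 22, 20))
  r <- relative_expression(ct, "TGT", "REF", "case", "cal")
  expect_equal(r$delta_delta_ct, 2)
})

test_that("twofold retention rule is boundary-inclusive", {
  expect_equal(retention_classify(2), "down")          # fold 0.25
  expect_equal(retention_classify(log2(1 / 1.8)), "retained")  # fold 1.8
  expect_equal(retention_classify(1), "retained")      # fold exactly 0.5
  expect_equal(retention_classify(-1), "retained")     # fold exactly 2
  expect_equal(retention_classify(-1.2), "up")
})

test_that("reference self-quantification is identically 1", {
  samples <- sprintf("s%d", 1:6)
  ct <- ct_table(sample = samples, assay = "REF", ct = 18 + runif(6, 0, 8))
  r <- relative_expression(ct, "REF", "REF", cases = samples,
                           calibrators = samples[1])
  expect_equal(r$fold, rep(1, 6))
})

test_that("dilution linearity: +c cycles on the target scales folds by 2^-c", {
  set.seed(11)
  samples <- sprintf("s%d", 1:5)
  tgt <- 22 + runif(5); ref <- 20 + runif(5)
  make <- function(shift) ct_table(
    sample = rep(samples, 2), assay = rep(c("TGT", "REF"), each = 5),
    ct = c(tgt + shift, ref))
  base <- relative_expression(make(0), "TGT", "REF", samples[-1], samples[1])
  shifted <- relative_expression(make(1.7), "TGT", "REF",
                                 samples[-1], samples[1])
  # the calibrator shifts too, so folds are unchanged under paired shift;
  # shifting cases only must scale folds by 2^-c
  ct_mix <- ct_table(
    sample = rep(samples, 2), assay = rep(c("TGT", "REF"), each = 5),
    ct = c(tgt + c(0, rep(1.7, 4)), ref))
  mixed <- relative_expression(ct_mix, "TGT", "REF", samples[-1], samples[1])
  expect_equal(shifted$fold, base$fold)
  expect_equal(mixed$fold, base$fold * 2^-1.7)
})

test_that("paired calibrator mode uses the matched sample", {
  ct <- ct_table(
    sample = rep(c("t1", "n1", "t2", "n2"), each = 2),
    assay = rep(c("TGT", "REF"), 4),
    ct = c(25, 20, 23, 20, 24, 20, 24, 20))
  r <- relative_expression(ct, "TGT", "REF", cases = c("t1", "t2"),
                           calibrators = NULL,
                           pairing = c(t1 = "n1", t2 = "n2"))
  expect_equal(r$fold, c(2^-2, 1))
})

test_that("undetermined required assays exclude the sample with a reason", {
  ct <- ct_table(
    sample = c("bad", "bad", "ok", "ok", "cal", "cal"),
    assay = rep(c("TGT", "REF"), 3),
    ct = c(NA, 20, 24, 20, 22, 20))
  r <- relative_expression(ct, "TGT", "REF", c("bad", "ok"), "cal")
  expect_equal(r$sample, "ok")
  expect_match(attr(r, "excluded"), "bad")
})

test_that("miRNA-style multi-reference averages the reference delta-Ct", {
  ct <- ct_table(
    sample = rep(c("s", "c"), each = 3),
    assay = rep(c("MIR", "RNU48", "RNU6"), 2),
    ct = c(26, 20, 22, 24, 20, 22))
  r <- relative_expression(ct, "MIR", c("RNU48", "RNU6"), "s", "c")
  expect_equal(r$delta_ct, 26 - 21)
  expect_equal(r$fold, 2^-2)
})

test_that("qMSP PMR follows the 100%-methylated-control formula", {
  ct <- ct_table(
    sample = rep(c("FM_CONTROL", "same", "plus1"), each = 2),
    assay = rep(c("LOC", "ACTB_conv"), 3),
    ct = c(25, 25, 27, 27, 28, 27))
  q <- qmsp_level(ct, "LOC")
  expect_equal(q$pmr[q$sample == "same"], 100)
  expect_equal(q$pmr[q$sample == "plus1"], 50)
})

test_that("qMSP degenerate inputs: undetermined locus, missing control, cap", {
  ct <- ct_table(
    sample = c("FM_CONTROL", "FM_CONTROL", "unmeth", "unmeth", "hot", "hot"),
    assay = rep(c("LOC", "ACTB_conv"), 3),
    ct = c(25, 25, NA, 27, 24, 27))
  q <- qmsp_level(ct, "LOC")
  expect_equal(q$pmr[q$sample == "unmeth"], 0)   # below detection
  expect_equal(q$pmr[q$sample == "hot"], 150)    # capped from 800
  expect_true(q$capped[q$sample == "hot"])

  expect_error(
    qmsp_level(ct_table("s", "LOC", 25), "LOC"),
    "fully methylated control")
})

test_that("conversion control flags incomplete bisulfite conversion", {
  ct <- ct_table(
    sample = c(rep("FM_CONTROL", 2), rep("fail", 3), rep("pass", 3)),
    assay = c("LOC", "ACTB_conv",
              "LOC", "ACTB_conv", "ACTB_unconv",
              "LOC", "ACTB_conv", "ACTB_unconv"),
    ct = c(25, 25, 27, 27, 30, 27, 27, 39))
  q <- qmsp_level(ct, "LOC")
  expect_false(q$conversion_ok[q$sample == "fail"])
  expect_true(q$conversion_ok[q$sample == "pass"])
})

test_that("Ct tables from the cohort generator round-trip to planted values", {
  co <- simulate_cohort(cohort_spec(n_patients = 12, n_normal = 10,
                                    n_donors = 3, n_pm_samples = 3,
                                    seed = 33))
  for (g in c("GAS5", "MEG3")) {
    q <- qmsp_level(co$ct_methylation, g)
    planted <- co$methylation[g, q$sample]
    expect_lt(max(abs(q$pmr - planted) / pmax(planted, 1e-12)), 1e-9)
  }
  # expression: paired T-vs-N fold equals 2^(log2 level difference)
  cl <- co$clinical
  paired <- intersect(cl$patient[cl$tissue == "T"],
                      cl$patient[cl$tissue == "N"])
  tids <- paste0(paired, "_T"); nids <- paste0(paired, "_N")
  r <- relative_expression(co$ct_expression, "MEG3", "B2M",
                           cases = tids, calibrators = NULL,
                           pairing = setNames(nids, tids))
  planted_fold <- 2^(co$expression["MEG3", tids] - co$expression["MEG3", nids])
  expect_equal(r$fold, unname(planted_fold), tolerance = 1e-12)
})

test_that("ct_table validates and reads from disk", {
  expect_error(ct_table("s", "a", -1), "positive")
  p <- tempfile(fileext = ".tsv")
  df <- data.frame(sample = c("s", "s"), assay = "A",
                   replicate = 1:2, ct = c(24, 24.2))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- read_ct_table(p)
  expect_s3_class(ct, "ct_table")
  expect_equal(nrow(ct), 2)
})
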