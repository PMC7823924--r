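test_that("reading round-trips a well-formed table and honours column maps", {
  tab <- toySummary(6)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(tab, f)
  got <- readSummaryStats(f)
  expect_equal(nrow(got), 6)
  expect_equal(got$beta, tab$beta)
  expect_equal(got$snp, tab$snp)

  # same file with foreign headers, mapped back
  tab2 <- tab
  names(tab2)[names(tab2) == "snp"] <- "rsid"
  names(tab2)[names(tab2) == "beta"] <- "b"
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(tab2, f2)
  expect_error(readSummaryStats(f2), "missing mandatory")
  got2 <- readSummaryStats(f2, columnMap = c(snp = "rsid", beta = "b"))
  expect_equal(got2$beta, got$beta)
})

test_that("malformed records are rejected with row-numbered messages", {
  tab <- toySummary(3)
  tab$se[2] <- 0
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(tab, f)
  expect_error(readSummaryStats(f), "row\\(s\\) 2.*se")

  tab <- toySummary(3)
  tab$oa[3] <- tab$ea[3]               # "A/A"
  writeSummaryStats(tab, f)
  expect_error(readSummaryStats(f), "row\\(s\\) 3.*identical")

  tab <- toySummary(3)
  tab$eaf[1] <- 1.2
  writeSummaryStats(tab, f)
  expect_error(readSummaryStats(f), "eaf")
})

test_that("instrument filtering applies inclusive thresholds with first-fail reasons", {
  tab <- toySummary(6)
  tab$eaf[1] <- 0.10                   # fails MAF >= 0.18
  tab$info <- c(NA, 0.96, 0.80, 1, 1, 1)   # row 3 fails info
  tab$hwe_p <- c(1, 1, 1, 0.001, 1, 1)     # row 4 fails hwe
  res <- filterInstruments(tab, mafMin = 0.18, hwePMin = 0.17,
                           infoMin = 0.96, pvalMax = 1)
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(tab))
  expect_setequal(res$dropped$snp, c("rs1", "rs3", "rs4"))
  expect_equal(res$dropped$reason[res$dropped$snp == "rs1"], "maf")
  expect_equal(res$dropped$reason[res$dropped$snp == "rs3"], "info")
  expect_equal(res$dropped$reason[res$dropped$snp == "rs4"], "hwe")
  # boundary is inclusive: info exactly 0.96 kept; missing info passes
  expect_true(all(c("rs2", "rs5") %in% res$kept$snp))

  allPass <- filterInstruments(toySummary(6), mafMin = 0.18)
  expect_equal(nrow(allPass$kept), 6)
  expect_equal(nrow(allPass$dropped), 0)
})

test_that("harmonization flips swapped alleles and drops ambiguous palindromes", {
  ex <- toySummary(4)
  ou <- toyOutcome(ex, slope = 2)
  # swap alleles of the second outcome record
  ou$ea[2] <- ex$oa[2]; ou$oa[2] <- ex$ea[2]
  ou$beta[2] <- -ou$beta[2]            # stored flipped; harmonizer re-flips
  ou$eaf[2] <- 1 - ou$eaf[2]
  set <- harmonizeInstruments(ex, ou)
  expect_equal(nInstruments(set), 4)
  expect_equal(unname(outcomeBeta(set)), 2 * ex$beta, tolerance = 1e-12)

  # ambiguous palindromic variant: eaf 0.5 on both sides
  exp2 <- toySummary(3, palindromic = TRUE)
  out2 <- toyOutcome(exp2, slope = 1)
  exp2$eaf <- c(0.50, 0.2, 0.2)
  out2$eaf <- c(0.50, 0.2, 0.8)        # third: opposite sides, outside window
  set2 <- harmonizeInstruments(exp2, out2)
  expect_setequal(droppedVariants(set2)$snp, c("rs1", "rs3"))
  expect_true(all(droppedVariants(set2)$reason == "palindromic"))
  expect_equal(variantIds(set2), "rs2")

  # unmatched variants drop with reason "missing"; empty overlap errors
  set3 <- harmonizeInstruments(ex, ou[-1, ])
  expect_equal(droppedVariants(set3)$reason[droppedVariants(set3)$snp == "rs1"],
               "missing")
  expect_error(harmonizeInstruments(ex, toySummary(3, seed = 9)[0, ]),
               "no variants shared")
})

test_that("harmonization is idempotent and strand-flip invariant", {
  ex <- toySummary(6)
  ou <- toyOutcome(ex, slope = 1.5, noiseSd = 0.01)
  ou$ea[3] <- ex$oa[3]; ou$oa[3] <- ex$ea[3]
  ou$beta[3] <- -ou$beta[3]; ou$eaf[3] <- 1 - ou$eaf[3]
  set1 <- harmonizeInstruments(ex, ou)
  tabs <- instrumentTables(set1)
  set2 <- harmonizeInstruments(tabs$exposure, tabs$outcome)
  expect_equal(set2@data[names(set1@data)], set1@data, tolerance = 1e-12)

  # exposure reported on the complementary strand: same harmonized effects
  exFlip <- ex
  exFlip$ea <- chartr("ACGT", "TGCA", ex$ea)
  exFlip$oa <- chartr("ACGT", "TGCA", ex$oa)
  setF <- harmonizeInstruments(exFlip, ou)
  expect_equal(unname(exposureBeta(setF)), unname(exposureBeta(set1)))
  expect_equal(unname(outcomeBeta(setF)), unname(outcomeBeta(set1)))
})

test_that("kept and dropped variants partition the input exactly", {
  ex <- toySummary(8, seed = 5)
  ou <- toyOutcome(ex, slope = 1)[-c(2, 5), ]
  set <- harmonizeInstruments(ex, ou)
  expect_equal(nInstruments(set) + nrow(droppedVariants(set)), nrow(ex))
  expect_length(intersect(variantIds(set), droppedVariants(set)$snp), 0)
})
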