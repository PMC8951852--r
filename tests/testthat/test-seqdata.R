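test_that("FASTA parsing, case normalisation and round-trip are faithful", {
  f <- writeTempFasta(c("s1 popA", "s2 popA", "s3 popB"),
                      c("ACGTACGT", "acgtacgt", "ACGTACGA"))
  a <- readHapAlignment(f, coordStart = 101L)
  expect_equal(nSamples(a), 3L)
  expect_equal(nSites(a), 8L)
  expect_equal(sampleIDs(a), c("s1", "s2", "s3"))
  expect_equal(samplePopulations(a), c("popA", "popA", "popB"))
  # lower-case input yields the same haplotypes as upper-case
  expect_equal(alignmentMatrix(a)[1, ], alignmentMatrix(a)[2, ])
  # round trip
  out <- tempfile(fileext = ".fasta")
  writeHapAlignment(a, out)
  b <- readHapAlignment(out, coordStart = 101L)
  expect_identical(alignmentMatrix(b), alignmentMatrix(a))
  expect_identical(sampleIDs(b), sampleIDs(a))
  expect_identical(samplePopulations(b), samplePopulations(a))
})

test_that("ragged, empty and invalid-character FASTA are rejected by name", {
  f <- writeTempFasta(c("ok popA", "ok2 popA", "short popA"),
                      c("ACGTACGT", "ACGTACGA", "ACGT"))
  expect_error(readHapAlignment(f), "short")
  f2 <- tempfile(fileext = ".fasta")
  writeLines(character(), f2)
  expect_error(readHapAlignment(f2), "empty")
  f3 <- writeTempFasta(c("x popA"), c("ACXT"))
  expect_error(readHapAlignment(f3), "disallowed")
})

test_that("HVS-1 window arithmetic retains 339 columns, 328 after exclusion", {
  a <- hapAlignment(matrix("A", 2, 16400 - 16024 + 1), coordStart = 16024L)
  expect_equal(nSites(applyWindow(a, hvs1Window(), applyExclusions = FALSE)),
               339L)
  expect_equal(nSites(applyWindow(a, hvs1Window())), 328L)
  w <- applyWindow(a, hvs1Window())
  expect_false(any(rcrsPositions(w) >= 16184 & rcrsPositions(w) <= 16194))
  expect_equal(range(rcrsPositions(w)), c(16032L, 16370L))
})

test_that("applyWindow is idempotent and errors on uncovered windows", {
  a <- hapAlignment(matrix(sample(c("A", "C"), 2 * 400, TRUE), 2, 400),
                    coordStart = 16024L)
  w1 <- applyWindow(a, hvs1Window())
  expect_identical(alignmentMatrix(applyWindow(w1, hvs1Window())),
                   alignmentMatrix(w1))
  # full-span identity window, no exclusions
  wfull <- hvs1Window(16024L, 16423L, NULL)
  expect_identical(alignmentMatrix(applyWindow(a, wfull)), alignmentMatrix(a))
  short <- hapAlignment(matrix("A", 2, 100), coordStart = 16300L)
  expect_error(applyWindow(short, hvs1Window()), "16032")
})

test_that("haplotype collapsing counts and conserves samples", {
  a <- hapAlignment(c("AAC", "AAC", "AAT", "GGG"),
                    populations = c("p1", "p1", "p1", "p2"))
  ht <- collapseHaplotypes(a)
  expect_equal(sort(unname(haplotypeCounts(ht$p1))), c(1L, 2L))
  expect_equal(haplotypeCounts(ht$p1)[["AAC"]], 2L)
  expect_equal(sort(unname(haplotypeFreqs(ht$p1))), c(1 / 3, 2 / 3))
  expect_equal(sum(vapply(ht, nSamples, 0)), nSamples(a))
  # identical sequences in one population: single haplotype, p = 1
  b <- hapAlignment(rep("ACGT", 4), populations = "p1")
  expect_equal(haplotypeFreqs(collapseHaplotypes(b)$p1), c(ACGT = 1))
  # unknown population vs. metadata is an error
  expect_error(collapseHaplotypes(a, makeMeta("p1")), "p2")
})

test_that("ambiguity masking removes columns with N or gaps globally", {
  a <- hapAlignment(c("ANC-T", "AACGT", "AACGT"), populations = "p")
  m <- maskAmbiguous(a)
  expect_equal(nSites(m), 3L)
  expect_equal(rcrsPositions(m), c(1L, 3L, 5L))
  expect_false(any(alignmentMatrix(m) %in% c("N", "-")))
})

test_that("metadata validation enforces levels and hierarchy consistency", {
  md <- makeMeta(c("p1", "p2", "p3"))
  expect_silent(validateSampleMetadata(md))
  bad <- md; bad$region1[1] <- "SS"          # contradicts region2 = eNA
  expect_error(validateSampleMetadata(bad), "region2")
  bad2 <- md; bad2$language[1] <- "XX"
  expect_error(validateSampleMetadata(bad2), "language")
  f <- tempfile(fileext = ".tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readSampleMetadata(f)$population_id, md$population_id)
})
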