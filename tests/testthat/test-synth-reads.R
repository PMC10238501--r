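test_that("sampleLibrary draws the configured insertion distribution", {
  t441 <- target441()
  des <- defaultDesign()
  lib <- sampleLibrary(t441, des, 1000, reverseFraction = 0, seed = 5)
  expect_equal(nrow(lib), 1000L)
  expect_true(all(lib$orientation == "forward"))
  expect_true(all(lib$p >= 0 & lib$p <= 441 - 5))
  # positions uniform: chi-square over deciles not rejected at alpha 0.01
  bins <- cut(lib$p, breaks = seq(-0.5, 436.5, length.out = 11))
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)

  # degenerate orientation probability
  libR <- sampleLibrary(t441, des, 200, reverseFraction = 1, seed = 5)
  expect_true(all(libR$orientation == "reverse"))

  # determinism
  expect_identical(lib, sampleLibrary(t441, des, 1000,
                                      reverseFraction = 0, seed = 5))
  expect_error(sampleLibrary(t441, des, 10,
                             positionWeights = rep(0, 437)), "empty")
})

test_that("clones per site sets the expected fold depth", {
  t441 <- target441()
  des <- defaultDesign()
  S <- 441 - 5 + 1
  lib <- sampleLibrary(t441, des, S * 190, seed = 9)
  depth <- table(factor(lib$p, levels = 0:(S - 1)))
  expect_equal(mean(depth), 190, tolerance = 0.02)
  expect_equal(foldCoverage(S * 190, S), 190)
})

test_that("buildAmplicon composes flanks and insert orientation correctly", {
  t441raw <- target441()
  des <- defaultDesign()
  fl <- strrep("ACGT", 13)
  fl <- substr(fl, 1, 50)
  tgt <- TargetConstruct("t", as.character(cdsSeq(t441raw)), fl, fl)
  ev <- InsertionEvent(65, variant = "LOV02")
  amp <- buildAmplicon(tgt, ev, des)
  expect_equal(length(amp), 958L)  # 50 + 858 + 50

  # reverse orientation: same length, insert segment reverse-complemented
  ampR <- buildAmplicon(tgt, InsertionEvent(65, "reverse", "LOV02"), des)
  expect_equal(length(ampR), 958L)
  ins <- dipscreen:::.insertSeq(des, "LOV02")
  insRC <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ins)))
  expect_equal(substr(as.character(ampR), 50 + 70 + 1, 50 + 70 + nchar(ins)),
               insRC)
  expect_equal(substr(as.character(amp), 50 + 70 + 1, 50 + 70 + nchar(ins)),
               ins)

  # empty flanks: amplicon == fusion
  expect_equal(as.character(buildAmplicon(t441raw, ev, des)),
               as.character(buildInsertionCds(t441raw, ev, des)))
})

test_that("shearAndRead emits bounded exact fragments at zero error", {
  toy <- toyTarget()
  des <- defaultDesign()
  pool <- simulatePool(toy, des, nPos = 5, nReads = 300, seed = 2)
  reads <- pool$reads
  amp <- dipscreen:::.ampliconPool(toy, des, pool$events)$amplicons
  prov <- parseReadProvenance(names(reads))
  fragLen <- prov$fragEnd - prov$fragStart + 1
  expect_true(all(fragLen >= 300 & fragLen <= 400))
  expect_true(all(Biostrings::width(reads) <= 300))
  # every zero-noise read is an exact substring of its amplicon (or its rc)
  key <- sub("\\|.*$", "", names(reads))
  for (i in seq_len(50)) {
    a <- as.character(amp[[key[i]]])
    r <- as.character(reads[[i]])
    if (prov$strand[i] == "-")
      r <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r)))
    expect_true(grepl(r, a, fixed = TRUE), info = names(reads)[i])
  }
})

test_that("read simulation is deterministic and conserves read counts", {
  toy <- toyTarget()
  des <- defaultDesign()
  pool <- dipscreen:::.ampliconPool(
    toy, des, data.frame(p = c(50, 200), orientation = "forward",
                         variant = "LOV02"))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeFastq(shearAndRead(pool$amplicons, 400, seed = 42), f1)
  writeFastq(shearAndRead(pool$amplicons, 400, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTQ
  r3 <- shearAndRead(pool$amplicons, 400, seed = 43)
  r1 <- readFastq(f1)
  expect_false(identical(unname(as.character(r1)),
                         unname(as.character(r3))))
  expect_equal(length(readFastq(f1)), 400L)

  # amplicons shorter than the fragment range are skipped with a warning
  shortAmp <- Biostrings::DNAStringSet(c(tiny = strrep("ACGT", 30)))
  expect_warning(
    r <- shearAndRead(c(pool$amplicons, shortAmp), 300,
                      weights = c(1, 1, 2), seed = 1),
    "skipped")
  expect_lt(length(r), 300L)
  expect_error(suppressWarnings(shearAndRead(shortAmp, 50, seed = 1)),
               "all fragment draws")
})

test_that("provenance names round-trip the true insertion identity", {
  toy <- toyTarget()
  des <- defaultDesign()
  pool <- simulatePool(toy, des, nPos = 8, nReads = 200, seed = 4)
  prov <- parseReadProvenance(names(pool$reads))
  expect_true(all(prov$p %in% pool$events$p))
  expect_true(all(prov$orientation %in% pool$events$orientation[
    match(prov$p, pool$events$p)]))
  expect_error(parseReadProvenance("not-a-name"), "unparseable")
})

test_that("FASTQ IO rejects malformed records", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)  # quality shorter than read
  expect_error(readFastq(bad), "malformed")
  expect_error(readFastq("/nonexistent/reads.fastq"), "not found")
})
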