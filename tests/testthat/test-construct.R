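test_that("translateCds follows the standard code and flags bad input", {
  expect_equal(translateCds("ATGAAA"), "MK")
  expect_equal(translateCds("TAA"), "*")
  expect_equal(translateCds("ATGAAAG"), "MK")  # trailing partial ignored
  expect_error(translateCds("ATGNAA"), "non-ACGT")
  expect_error(translateCds("AT"), "shorter")
})

test_that("the packaged Gal4 target has the screen's hit residues", {
  prot <- as.character(proteinSeq(gal4Vp64Target()))
  expect_equal(substr(prot, 22, 22), "S")
  expect_equal(substr(prot, 23, 23), "K")
  expect_equal(substr(prot, 29, 29), "A")
  expect_equal(length(asLOV2Domain()), 408L)
})

test_that("buildInsertionCds duplicates the target site and conserves length", {
  # no duplication, empty scars: plain prepend
  tgt <- TargetConstruct("t", "ATGGGG")
  des0 <- InsertDesign("AAATTT", tsdLen = 0L,
                       variants = list(FrameVariant("V0")))
  expect_equal(as.character(
    buildInsertionCds(tgt, InsertionEvent(0, variant = "V0"), des0)),
    "AAATTTATGGGG")

  # length formula: 441 + 5 + 2 + 408 + 2 = 858
  t441 <- target441()
  des <- defaultDesign()
  fus <- buildInsertionCds(t441, InsertionEvent(3, variant = "LOV02"), des)
  expect_equal(length(fus), 858L)

  # duplicated pentamer flanks the insert (string-search oracle)
  gal <- gal4Vp64Target()
  cds <- as.character(cdsSeq(gal))
  fus <- as.character(
    buildInsertionCds(gal, InsertionEvent(65, variant = "LOV02"), des))
  dup <- substr(cds, 66, 70)
  hits <- gregexpr(dup, fus, fixed = TRUE)[[1]]
  expect_true(70 %in% (hits + 4))          # left copy ends at position 70
  ins <- nchar(dipscreen:::.insertSeq(des, "LOV02"))
  expect_true((70 + ins + 1) %in% hits)    # right copy starts after insert

  # length conservation over random draws
  set.seed(11)
  for (i in 1:25) {
    p <- sample(0:(length(cdsSeq(gal)) - 5L), 1)
    v <- sample(c("LOV01", "LOV02", "LOV03"), 1)
    ori <- sample(c("forward", "reverse"), 1)
    fusL <- length(buildInsertionCds(gal, InsertionEvent(p, ori, v), des))
    vv <- des@variants[[v]]
    expect_equal(fusL, length(cdsSeq(gal)) + 5L + nchar(vv@s5) + 408L +
                   nchar(vv@s3))
  }

  expect_error(buildInsertionCds(gal, InsertionEvent(1e5), des),
               "out of range")
  expect_error(
    buildInsertionCds(gal, InsertionEvent(length(cdsSeq(gal)) - 2L), des),
    "p \\+ d > L")
})

test_that("classifyFrame matches modular arithmetic and direct translation", {
  gal <- gal4Vp64Target()
  des <- defaultDesign()
  # (65 + 5 + 2) %% 3 == 0 -> in frame; 66 shifts out
  expect_true(classifyFrame(gal, InsertionEvent(65, variant = "LOV02"),
                            des)$domain_in_frame)
  expect_false(classifyFrame(gal, InsertionEvent(66, variant = "LOV02"),
                             des)$domain_in_frame)
  # antisense insert can never be functional
  fc <- classifyFrame(gal, InsertionEvent(65, "reverse", "LOV02"), des)
  expect_false(fc$domain_in_frame)
  expect_false(fc$functional)

  # frame call agrees with finding the domain's translation in the fusion
  domAa <- translateCds(asLOV2Domain())
  set.seed(7)
  toy <- toyTarget()
  for (i in 1:60) {
    p <- sample(0:(600 - 5L), 1)
    v <- sample(c("LOV01", "LOV02", "LOV03"), 1)
    ev <- InsertionEvent(p, variant = v)
    fc <- classifyFrame(toy, ev, des)
    aa <- translateCds(buildInsertionCds(toy, ev, des))
    expect_equal(fc$domain_in_frame, grepl(domAa, aa, fixed = TRUE),
                 info = paste("p =", p, v))
  }
})

test_that("assignAaSite names the insertion junction by translation prefix", {
  gal <- gal4Vp64Target()
  des <- defaultDesign()
  prot <- as.character(proteinSeq(gal))
  # identity: no insert -> full protein length
  expect_equal(assignAaSite(cdsSeq(gal), prot), nchar(prot))
  # codon-boundary insertions conserve at least the first k residues and
  # stay within the duplication window
  set.seed(3)
  for (k in sample(5:150, 12)) {
    p <- 3L * k
    ev <- InsertionEvent(p, variant = "LOV01")  # p %% 3 == 0 -> in frame
    fc <- classifyFrame(gal, ev, des)
    if (!fc$functional) next
    site <- assignAaSite(buildInsertionCds(gal, ev, des), prot)
    expect_gte(site, k)
    expect_gte(site, floor(p / 3))
    # duplication and scar codons can extend the conserved prefix by one
    # junction codon, and a coincidental match with the domain's first
    # residue can add one more
    expect_lte(site, floor((p + 5) / 3) + 2)
  }
})

test_that("default frame variants partition insertion positions mod 3", {
  toy <- toyTarget()
  des <- defaultDesign()
  ef <- enumerateInFramePositions(toy, des)
  expect_false(any(is.na(ef$variant)))
  expect_equal(unname(ef$variant[ef$p %% 3 == 0][1]), "LOV01")
  expect_equal(unname(ef$variant[ef$p %% 3 == 1][1]), "LOV03")
  expect_equal(unname(ef$variant[ef$p %% 3 == 2][1]), "LOV02")
  expect_true(all(tapply(ef$variant, ef$p %% 3,
                         function(v) length(unique(v)) == 1L)))
  # a frame-breaking design is a configuration error
  expect_error(InsertDesign(variants = list(FrameVariant("bad", s5 = "A",
                                                         s3 = "A"))),
               "downstream frame")
})

test_that("constructReport tabulates frames and sites per event", {
  gal <- gal4Vp64Target()
  rep_ <- constructReport(gal, defaultDesign(),
                          data.frame(p = c(62, 63, 62),
                                     orientation = c("forward", "forward",
                                                     "reverse"),
                                     variant = c("LOV02", "LOV01", "LOV02")))
  expect_equal(rep_$functional, c(TRUE, TRUE, FALSE))
  expect_equal(rep_$aa_site[1], 22L)
  expect_true(is.na(rep_$aa_site[3]))
})

test_that("TargetConstruct validity enforces the CDS contract", {
  expect_error(TargetConstruct("bad", "ATGAA"), "multiple of 3")
  expect_error(TargetConstruct("bad", "ATGNNN"), "non-ACGT|A/C/G/T")
})
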