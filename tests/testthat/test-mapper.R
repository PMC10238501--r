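test_that("indexTarget preserves uniqueness and repeat ambiguity", {
  toy <- toyTarget()
  cds <- as.character(cdsSeq(toy))
  idx <- indexTarget(cds, k = 20)
  # non-repetitive CDS: every forward k-mer maps to exactly one offset
  set.seed(1)
  for (i in sample(1:(600 - 19), 30)) {
    hit <- lookupKmer(idx, substr(cds, i, i + 19), strand = "+")
    expect_equal(hit$offset, i)
  }
  # an internal 25-nt repeat keeps both offsets (ambiguity preserved)
  block <- substr(cds, 1, 25)
  filler <- substr(cds, 101, 135)
  repCds <- paste0(block, filler, block, filler)
  idx2 <- indexTarget(repCds, k = 20)
  hit2 <- lookupKmer(idx2, substr(block, 1, 20), strand = "+")
  expect_gte(nrow(hit2), 2L)
  expect_error(indexTarget("ACGTACGT", k = 20), "must not exceed")
})

test_that("findJunctions labels junction side and insert orientation", {
  toy <- toyTarget()
  des <- defaultDesign()
  ins <- dipscreen:::.insertSeq(des, "LOV02")
  cds <- as.character(cdsSeq(toy))

  # read wholly inside the domain: no junction hit with flanking target
  inside <- substr(ins, 50, 250)
  expect_equal(nrow(findJunctions(inside, des, "LOV02")), 0L)

  # synthetic left-junction read: target flank then insert start
  left <- paste0(substr(cds, 31, 105), substr(ins, 1, 120))
  h <- findJunctions(left, des, "LOV02")
  h <- h[h$strand == "+", ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$side, "left")
  expect_equal(h$orientation, "forward")
  expect_equal(h$offset, 76L)

  # reverse-complemented domain start implies a reverse-orientation insert
  insRC <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ins)))
  revRead <- paste0(substr(cds, 31, 105), substr(insRC, 1, 120))
  h2 <- findJunctions(revRead, des, "LOV02")
  h2 <- h2[h2$strand == "+" & h2$side == "left", ]
  expect_equal(h2$orientation, "reverse")
})

test_that("callInsertion inverts the construction with mismatch tolerance", {
  toy <- toyTarget()
  des <- defaultDesign()
  idx <- indexTarget(as.character(cdsSeq(toy)), 20)
  fus <- as.character(buildInsertionCds(
    toy, InsertionEvent(65, variant = "LOV02"), des))

  # error-free read over the left junction
  read <- substr(fus, 20, 320)
  call <- callInsertion(read, idx, toy, des, "LOV02")
  expect_equal(call$p, 65L)
  expect_equal(call$orientation, "forward")

  # one substitution inside the flank is tolerated
  mut <- read
  substr(mut, 40, 40) <- if (substr(mut, 40, 40) == "A") "C" else "A"
  call2 <- callInsertion(mut, idx, toy, des, "LOV02")
  expect_equal(call2$p, 65L)
  expect_equal(call2$mismatches, 1L)

  # a 10-nt flank is below minFlank: no call
  short <- substr(fus, 61, 320)
  expect_null(callInsertion(short, idx, toy, des, "LOV02"))

  # a read spanning both junctions yields one consistent call
  span <- substr(fus, 30, 30 + 480)
  call3 <- callInsertion(span, idx, toy, des, "LOV02", anchorLen = 15)
  expect_equal(call3$p, 65L)
})

test_that("left and right junctions of one insert give the same p", {
  toy <- toyTarget()
  des <- defaultDesign()
  idx <- indexTarget(as.character(cdsSeq(toy)), 20)
  ins <- nchar(dipscreen:::.insertSeq(des, "LOV02"))
  for (p in c(40, 301, 500)) {
    fus <- as.character(buildInsertionCds(
      toy, InsertionEvent(p, variant = "LOV02"), des))
    left <- substr(fus, max(1, p - 60), p + 5 + 60)
    right <- substr(fus, p + 5 + ins - 60, min(nchar(fus), p + 5 + ins + 80))
    cl <- callInsertion(left, idx, toy, des, "LOV02")
    cr <- callInsertion(right, idx, toy, des, "LOV02")
    expect_equal(cl$p, p)
    expect_equal(cr$p, p)
    expect_equal(cl$side, "left")
    expect_equal(cr$side, "right")
  }
})

test_that("zero-noise mapping is the exact inverse of simulation", {
  toy <- toyTarget()
  des <- defaultDesign()
  for (seed in c(11, 12)) {
    pool <- simulatePool(toy, des, nPos = 20, nReads = 1200, seed = seed)
    prof <- buildProfile(pool$reads, toy, des)
    rs <- profileStats(prof)
    expect_equal(rs[["total"]],
                 rs[["mapped"]] + rs[["unmapped"]] + rs[["ambiguous"]] +
                   rs[["nonJunction"]])
    cts <- profileCounts(prof)
    called <- which(rowSums(cts) > 0) - 1L
    # no phantom positions; every truth position with junction reads found
    expect_true(all(called %in% pool$events$p))
    # orientation recovered exactly: counts only in the true orientation
    for (p in called) {
      ori <- pool$events$orientation[pool$events$p == p]
      other <- setdiff(c("forward", "reverse"), ori)
      expect_equal(cts[p + 1L, other], 0L,
                   ignore_attr = TRUE)
    }
  }
})

test_that("mapping tolerates sequencing error at the MiSeq rate", {
  toy <- toyTarget()
  des <- defaultDesign()
  pool <- simulatePool(toy, des, nPos = 20, nReads = 1500,
                       perBaseError = 0.001, seed = 21)
  prof <- buildProfile(pool$reads, toy, des)
  cts <- profileCounts(prof)
  mapped <- profileStats(prof)[["mapped"]]
  atTruth <- sum(cts[pool$events$p + 1L, ])
  expect_gte(atTruth / mapped, 0.99)
})

test_that("buildProfile handles empty input and profile IO round-trips", {
  toy <- toyTarget()
  des <- defaultDesign()
  empty <- buildProfile(Biostrings::DNAStringSet(), toy, des)
  expect_equal(sum(profileCounts(empty)), 0)
  expect_equal(profileStats(empty)[["total"]], 0L)

  pool <- simulatePool(toy, des, nPos = 4, nReads = 200, seed = 31)
  prof <- buildProfile(pool$reads, toy, des, roundLabel = "round1")
  tsv <- tempfile(fileext = ".tsv")
  writeProfile(prof, tsv)
  back <- readProfile(tsv)
  expect_equal(profileCounts(back), profileCounts(prof))
  expect_equal(profileStats(back), profileStats(prof))
  expect_equal(back@roundLabel, "round1")
})
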