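test_that("expression model honors mean, noise and symmetry", {
  # same seed, same mean: dark and light draws identical in distribution
  a <- simulateExpression(500, 0.6, 1000, seed = 8)
  b <- simulateExpression(500, 0.6, 1000, seed = 8)
  expect_identical(a, b)
  # vanishing noise collapses onto floor + mean
  x <- simulateExpression(100, 1e-4, 200, floor = 10, seed = 1)
  expect_equal(mean(x), 110, tolerance = 1e-3)
  expect_lt(sd(x), 0.1)
  # photoswitchable phenotype: dark median ~100x light median
  dark <- simulateExpression(1000, 0.6, 1e5, floor = 0, seed = 2)
  light <- simulateExpression(10, 0.6, 1e5, floor = 0, seed = 3)
  expect_equal(median(dark) / median(light), 100, tolerance = 0.05)
})

test_that("sortRound selects the expected variant composition", {
  phen <- phenotypeTable(c("dead", "const", "photo"),
                         gfpDark = c(1, 1000, 1000),
                         gfpLight = c(1, 1000, 1))
  f0 <- setNames(phen$frequency, phen$variant_id)

  # non-selective gate: frequencies unchanged in expectation
  fin <- rowMeans(sapply(1:20, function(s)
    sortRound(f0, phen, gateSpec("dark", "keep-high", threshold = 0),
              2e4, 2e4, seed = s)))
  expect_equal(unname(fin), unname(f0), tolerance = 0.02)

  # dead variant under a GFP-positive dark gate vanishes in one round
  f1 <- sortRound(f0, phen, gateSpec("dark", "keep-high", threshold = 30),
                  2e4, 1e4, seed = 1)
  expect_lt(f1[["dead"]], 0.01)

  # constitutive mass strictly decreases under keep-low light selection
  drops <- sapply(1:20, function(s) {
    f <- sortRound(f0, phen, gateSpec("light", "keep-low", 0.5),
                   2e4, 1e4, seed = s)
    f[["const"]] < f0[["const"]]
  })
  expect_true(all(drops))

  # an impossible gate is reported, not silently emptied
  expect_error(
    sortRound(f0, phen, gateSpec("dark", "keep-high", threshold = 1e9),
              1e3, 1e3, seed = 1),
    "over-stringent")
})

test_that("runScreen conserves frequency mass and tracks the schedule", {
  phen <- screenLibraryPhenotypes(nDead = 100, nConstitutive = 10,
                                  nTruncation = 5, nPhotoswitchable = 1)
  tr <- runScreen(phen, nPopulation = 3e4, nSorted = 1e4, seed = 2)
  f <- trajectoryFrequencies(tr)
  expect_equal(nrow(f), 5L)  # initial + 4 rounds
  expect_true(all(abs(rowSums(f) - 1) < 1e-8))
  expect_true(all(f >= 0))
  expect_identical(
    f, trajectoryFrequencies(runScreen(phen, nPopulation = 3e4,
                                       nSorted = 1e4, seed = 2)))
  expect_equal(nrow(tr@summaries), 5L)
})

test_that("neutral gates drift but do not select", {
  phen <- phenotypeTable(paste0("v", 1:4), gfpDark = 100, gfpLight = 100)
  gates <- rep(list(gateSpec("dark", "keep-high", threshold = 0)), 3)
  finals <- sapply(1:25, function(s)
    finalFrequencies(runScreen(phen, gates, nPopulation = 1e4,
                               nSorted = 5e3, seed = s)))
  expect_equal(unname(rowMeans(finals)), rep(0.25, 4), tolerance = 0.03)
})

test_that("a uniformly advantaged variant is never expected to lose ground", {
  # photoswitchable passes every default gate at least as often as dead
  phen <- phenotypeTable(c("dead", "photo"), gfpDark = c(1, 1000),
                         gfpLight = c(1, 1), frequency = c(0.9, 0.1))
  finals <- sapply(1:25, function(s)
    finalFrequencies(runScreen(phen, nPopulation = 2e4, nSorted = 1e4,
                               seed = s)))
  expect_gte(mean(finals["photo", ]), 0.1)
  expect_gte(min(finals["photo", ]), 0.1)
})
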