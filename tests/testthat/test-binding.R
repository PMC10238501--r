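test_that("boundFraction solves the one-site mass balance exactly", {
  expect_equal(boundFraction(0, T = 2, Kd = 6.4), 0)
  # independent oracle: numeric root of complex = (P - x)(T - x) / Kd
  massBalanceB <- function(P, T, Kd) {
    if (P == 0) return(0)
    x <- stats::uniroot(function(x) x - (P - x) * (T - x) / Kd,
                        c(0, min(P, T)), tol = 1e-12)$root
    x / T
  }
  for (P in c(0.5, 2, 6.2, 25, 400)) {
    expect_equal(boundFraction(P, T = 2, Kd = 6.4),
                 massBalanceB(P, 2, 6.4), tolerance = 1e-8)
  }
  # the assay's own constants: probe 2 nM, Kd 6.4 nM, first point 6.2 nM
  expect_equal(boundFraction(6.2, T = 2, Kd = 6.4), 0.4527,
               tolerance = 1e-3)
  # hyperbolic limit as probe depletion vanishes
  expect_equal(boundFraction(5, T = 1e-6, Kd = 6.4), 5 / (5 + 6.4),
               tolerance = 1e-5)
  Kd <- 6.4
  expect_equal(boundFraction(10, T = Kd / 1e4, Kd = Kd),
               boundFraction(10, T = Kd / 1e4, Kd = Kd,
                             model = "hyperbola"),
               tolerance = 1e-4)
})

test_that("boundFraction is bounded and monotone", {
  P <- seq(0, 500, by = 2.5)
  for (Kd in c(1, 6.4, 40)) {
    b <- boundFraction(P, T = 2, Kd = Kd)
    expect_true(all(b >= 0 & b <= pmin(1, ifelse(P == 0, 0, P / 2) + 1e-12)))
    expect_true(all(diff(b) >= 0))
  }
  # decreasing in Kd
  expect_true(all(diff(sapply(c(2, 6.4, 20, 60),
                              function(k) boundFraction(10, 2, k))) < 0))
})

test_that("model anisotropy interpolates free to bound", {
  expect_equal(modelAnisotropy(0, 6.4, 0.1, 0.25), 0.1)
  expect_equal(modelAnisotropy(1e6, 6.4, 0.1, 0.25), 0.25,
               tolerance = 1e-4)
  r <- modelAnisotropy(seq(0, 800, by = 4), 6.4, 0.1, 0.25)
  expect_true(all(diff(r) >= 0))
})

test_that("titration grid doubles from 6.2 nM until saturation", {
  P <- titrationGrid(6.4)
  expect_equal(P[1:2], c(0, 6.2))
  steps <- P[P > 0]
  expect_equal(steps / steps[1], 2^(seq_along(steps) - 1))
  expect_gt(boundFraction(max(P), 2, 6.4), 0.98)
  expect_lte(boundFraction(steps[length(steps) - 1], 2, 6.4), 0.98)
})

test_that("simulated titrations are exact at zero noise and seeded", {
  cv <- simulateTitration(6.4, noiseSd = 0, nReplicates = 1)
  expect_equal(cv@data$anisotropy,
               modelAnisotropy(cv@data$P_nM, 6.4, 0.1, 0.25))
  c1 <- simulateTitration(6.4, seed = 1)
  expect_identical(c1@data, simulateTitration(6.4, seed = 1)@data)
  c2 <- simulateTitration(6.4, seed = 2)
  expect_false(identical(c1@data$anisotropy, c2@data$anisotropy))
  # noise is centered: two seeds agree in mean over many replicates
  big <- simulateTitration(6.4, nReplicates = 400, seed = 3)
  mu <- tapply(big@data$anisotropy, big@data$P_nM, mean)
  truth <- modelAnisotropy(as.numeric(names(mu)), 6.4, 0.1, 0.25)
  expect_equal(as.vector(mu), truth, tolerance = 0.005)
})

test_that("fitTitration recovers exact parameters from noiseless data", {
  fit <- fitTitration(simulateTitration(6.4, noiseSd = 0, nReplicates = 1))
  expect_true(fit@converged)
  expect_equal(bindingKd(fit), 6.4, tolerance = 1e-4)
  expect_equal(unname(fit@estimates[c("rFree", "rBound")]), c(0.1, 0.25),
               tolerance = 1e-6)
  expect_error(fitTitration(TitrationCurve(c(0, 5, 10), c(.1, .2, .25))),
               ">= 4 distinct")
})

test_that("the fitter is essentially unbiased at the assay noise level", {
  kds <- vapply(1:300, function(s)
    bindingKd(fitTitration(simulateTitration(6.4, seed = 7000 + s))),
    numeric(1))
  expect_lt(abs(mean(kds) - 6.4) / 6.4, 0.05)
})

test_that("titration IO round-trips", {
  cv <- simulateTitration(8.6, seed = 4, condition = "dark",
                          variant = "V416L")
  tsv <- tempfile(fileext = ".tsv")
  writeTitration(cv, tsv)
  back <- readTitration(tsv)
  expect_equal(back@data$anisotropy, cv@data$anisotropy)
  expect_equal(back@probe_nM, 2)
  expect_equal(back@condition, "dark")
  expect_equal(back@variant, "V416L")
})
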