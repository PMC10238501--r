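# Stochastic simulation of iterative dark/light FACS selection reshaping
# variant frequencies.

#' Simulate single-cell GFP expression for one phenotype
#'
#' Single-cell expression is modeled as an autofluorescence floor plus a
#' log-normal component whose arithmetic mean is the phenotype's mean for
#' the assay condition and whose coefficient of variation is `noiseCv`
#' (the synthetic stand-in for flow-cytometry histograms).
#'
#' @param mean Mean reporter expression above background (AU, > 0; values
#'   <= 0 give pure autofluorescence).
#' @param noiseCv Coefficient of variation of the log-normal component.
#' @param n Number of cells.
#' @param floor Autofluorescence floor (AU, added to every cell).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` expression values.
#' @examples
#' summary(simulateExpression(1000, 0.6, 1e4, seed = 1))
#' @export
simulateExpression <- function(mean, noiseCv, n, floor = 10, seed = NULL) {
  stopifnot(n >= 1, noiseCv > 0)
  .withSeed(seed, floor + .rlnormMean(n, mean, noiseCv))
}

.rlnormMean <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Specify a FACS gate
#'
#' A gate keeps cells above (`keep-high`) or below (`keep-low`) a cutoff on
#' reporter expression measured under the stated illumination condition.
#' The cutoff is either an absolute `threshold` (AU) or a `quantile` of the
#' current population (the screen's gates were set relative to each round's
#' population).
#'
#' @param condition `"dark"` or `"light"`.
#' @param direction `"keep-high"` or `"keep-low"`.
#' @param quantile Population quantile in (0, 1) defining the cutoff.
#' @param threshold Absolute cutoff (AU); overrides `quantile`.
#' @return A list of class `"GateSpec"`.
#' @examples
#' gateSpec("dark", "keep-high", quantile = 0.5)
#' @export
gateSpec <- function(condition = c("dark", "light"),
                     direction = c("keep-high", "keep-low"),
                     quantile = 0.5, threshold = NULL) {
  condition <- match.arg(condition)
  direction <- match.arg(direction)
  if (is.null(threshold) && (quantile <= 0 || quantile >= 1))
    stop("quantile must be in (0, 1)")
  structure(list(condition = condition, direction = direction,
                 quantile = quantile, threshold = threshold),
            class = "GateSpec")
}

#' Default selection schedule
#'
#' One dark round recovering GFP-positive cells, followed by three light
#' keep-low rounds -- the screen's initial recovery of the GFP-positive
#' population and its "three rounds of dark/light selection". The dark
#' gate is an absolute GFP-positive threshold (default 3x the
#' autofluorescence floor): a population-median gate cannot represent a
#' GFP-positive sort when most of the initial library is GFP-negative,
#' since the median then sits inside the dead peak. The light rounds use
#' population-quantile keep-low gates; all gates are configuration.
#'
#' @param quantile Quantile of the light keep-low gates.
#' @param gfpPositiveThreshold Absolute cutoff (AU) of the dark keep-high
#'   gate.
#' @param nLightRounds Number of light keep-low rounds.
#' @return List of [gateSpec()] objects.
#' @export
defaultGateSchedule <- function(quantile = 0.5, gfpPositiveThreshold = 30,
                                nLightRounds = 3) {
  c(list(gateSpec("dark", "keep-high", threshold = gfpPositiveThreshold)),
    rep(list(gateSpec("light", "keep-low", quantile)), nLightRounds))
}

#' Phenotype table for a screen simulation
#'
#' @param variantId Variant labels.
#' @param gfpDark,gfpLight Mean reporter expression above background in the
#'   dark and under blue light (AU).
#' @param noiseCv Single-cell coefficient of variation (default 0.6).
#' @param frequency Initial frequencies (normalized internally; default
#'   equal).
#' @return Data frame with columns `variant_id`, `gfp_dark`, `gfp_light`,
#'   `noise_cv`, `frequency`.
#' @seealso [screenLibraryPhenotypes()] for the canonical screen mixture.
#' @export
phenotypeTable <- function(variantId, gfpDark, gfpLight, noiseCv = 0.6,
                           frequency = NULL) {
  n <- length(variantId)
  if (is.null(frequency)) frequency <- rep(1 / n, n)
  stopifnot(length(gfpDark) %in% c(1L, n), length(gfpLight) %in% c(1L, n),
            all(frequency >= 0), sum(frequency) > 0, all(noiseCv > 0))
  data.frame(variant_id = as.character(variantId),
             gfp_dark = rep(gfpDark, length.out = n),
             gfp_light = rep(gfpLight, length.out = n),
             noise_cv = rep(noiseCv, length.out = n),
             frequency = frequency / sum(frequency))
}

#' Canonical phenotype mixture of the insertion library
#'
#' The four phenotype classes seen in the screen's initial library:
#' dead (out-of-frame / non-functional insertions, background GFP),
#' constitutive (insertions with no deleterious effect, full GFP in dark
#' and light), truncation-like (intermediate GFP from insertions sparing
#' some VP16 repeats), and photoswitchable (full GFP in dark, background
#' under blue light).
#'
#' @param nDead,nConstitutive,nTruncation,nPhotoswitchable Number of
#'   variants per class.
#' @param levels Named numeric: mean above-background GFP (AU) of the
#'   classes (`dead`, `intermediate`, `full`, `photoLight`).
#' @param noiseCv Single-cell CV.
#' @return A phenotype data frame (see [phenotypeTable()]).
#' @export
screenLibraryPhenotypes <- function(nDead = 1000, nConstitutive = 50,
                                    nTruncation = 20, nPhotoswitchable = 1,
                                    levels = c(dead = 1, intermediate = 100,
                                               full = 1000, photoLight = 1),
                                    noiseCv = 0.6) {
  ids <- c(sprintf("dead%04d", seq_len(nDead)),
           sprintf("const%03d", seq_len(nConstitutive)),
           sprintf("trunc%03d", seq_len(nTruncation)),
           sprintf("photo%02d", seq_len(nPhotoswitchable)))
  dark <- c(rep(levels[["dead"]], nDead),
            rep(levels[["full"]], nConstitutive),
            rep(levels[["intermediate"]], nTruncation),
            rep(levels[["full"]], nPhotoswitchable))
  light <- c(rep(levels[["dead"]], nDead),
             rep(levels[["full"]], nConstitutive),
             rep(levels[["intermediate"]], nTruncation),
             rep(levels[["photoLight"]], nPhotoswitchable))
  phenotypeTable(ids, dark, light, noiseCv)
}

#' Apply one sorting round
#'
#' `nPopulation` cells are assigned to variants multinomially from the
#' current frequencies; each cell draws an expression value under the
#' gate's illumination condition; cells passing the gate are sampled
#' without replacement down to `nSorted` (or all passers if fewer); the new
#' frequencies are the variant composition of the sorted cells.
#'
#' @param frequencies Named numeric vector of current variant frequencies.
#' @param phenotypes Phenotype data frame (see [phenotypeTable()]).
#' @param gate A [gateSpec()].
#' @param nPopulation Cells assayed before sorting.
#' @param nSorted Cells kept (default 100000, the screen's sort size).
#' @param floor Autofluorescence floor (AU).
#' @param seed Optional integer seed.
#' @return Updated named frequency vector (sums to 1).
#' @export
sortRound <- function(frequencies, phenotypes, gate, nPopulation,
                      nSorted = 1e5, floor = 10, seed = NULL) {
  stopifnot(inherits(gate, "GateSpec"), nSorted <= nPopulation)
  .withSeed(seed, {
    counts <- as.vector(stats::rmultinom(1, nPopulation, frequencies))
    mu <- if (gate$condition == "dark") phenotypes$gfp_dark else
      phenotypes$gfp_light
    vidx <- rep.int(seq_along(counts), counts)
    expr <- floor + unlist(lapply(which(counts > 0), function(i)
      .rlnormMean(counts[i], mu[i], phenotypes$noise_cv[i])), use.names = FALSE)
    cut <- if (!is.null(gate$threshold)) gate$threshold else
      stats::quantile(expr, gate$quantile, names = FALSE)
    pass <- if (gate$direction == "keep-high") expr >= cut else expr <= cut
    if (!any(pass)) stop("no cells pass the gate; gate is over-stringent")
    passers <- vidx[pass]
    if (length(passers) > nSorted)
      passers <- passers[sample.int(length(passers), nSorted)]
    newCounts <- tabulate(passers, nbins = length(counts))
    stats::setNames(newCounts / sum(newCounts), names(frequencies))
  })
}

#' Run a multi-round selection screen
#'
#' Applies the gate schedule sequentially with neutral multinomial regrowth
#' to `nPopulation` cells between rounds; records the variant frequency
#' trajectory and per-round population GFP medians under both dark and
#' light assay conditions. Deterministic given `seed` (per-round seeds are
#' derived from it).
#'
#' @param phenotypes Phenotype data frame with initial `frequency` column.
#' @param gates List of [gateSpec()] objects (default
#'   [defaultGateSchedule()]).
#' @param nPopulation Cells assayed per round.
#' @param nSorted Cells kept per sort (default 100000).
#' @param floor Autofluorescence floor (AU).
#' @param seed Optional integer seed.
#' @param summaryCells Cells drawn per condition for the GFP summaries.
#' @return A [ScreenTrajectory-class].
#' @examples
#' phen <- screenLibraryPhenotypes(nDead = 50, nConstitutive = 5,
#'                                 nTruncation = 2, nPhotoswitchable = 1)
#' tr <- runScreen(phen, nPopulation = 2e4, nSorted = 1e4, seed = 1)
#' head(sort(finalFrequencies(tr), decreasing = TRUE))
#' @export
runScreen <- function(phenotypes, gates = defaultGateSchedule(),
                      nPopulation = 2e5, nSorted = 1e5, floor = 10,
                      seed = NULL, summaryCells = 2e4) {
  freq <- stats::setNames(phenotypes$frequency, phenotypes$variant_id)
  freq <- freq / sum(freq)
  traj <- matrix(freq, nrow = 1,
                 dimnames = list("initial", names(freq)))
  # derived per-round seeds, kept within the 32-bit range set.seed needs
  derive <- function(i) (as.numeric(seed) * 131 + i) %% 2147483647
  summ <- .gfpSummary(freq, phenotypes, floor, summaryCells,
                      if (is.null(seed)) NULL else derive(0))
  for (i in seq_along(gates)) {
    rseed <- if (is.null(seed)) NULL else derive(i)
    freq <- sortRound(freq, phenotypes, gates[[i]], nPopulation, nSorted,
                      floor, seed = rseed)
    traj <- rbind(traj, freq)
    rownames(traj)[nrow(traj)] <- paste0("round", i)
    summ <- rbind(summ, .gfpSummary(freq, phenotypes, floor, summaryCells,
                                    if (is.null(rseed)) NULL else rseed + 7919L))
  }
  summ$state <- rownames(traj)
  new("ScreenTrajectory", frequencies = traj, gates = gates,
      summaries = summ[, c("state", "median_dark", "median_light")],
      seed = if (is.null(seed)) NA_real_ else seed)
}

.gfpSummary <- function(freq, phenotypes, floor, n, seed) {
  .withSeed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, freq))
    med <- vapply(c("gfp_dark", "gfp_light"), function(col) {
      expr <- floor + unlist(lapply(which(counts > 0), function(i)
        .rlnormMean(counts[i], phenotypes[[col]][i],
                    phenotypes$noise_cv[i])), use.names = FALSE)
      stats::median(expr)
    }, numeric(1))
    data.frame(median_dark = med[[1]], median_light = med[[2]])
  })
}

#' @describeIn ScreenTrajectory-class Frequency matrix accessor.
#' @param x,object A `ScreenTrajectory`.
#' @export
setGeneric("trajectoryFrequencies",
           function(x) standardGeneric("trajectoryFrequencies"))

#' @rdname ScreenTrajectory-class
#' @export
setMethod("trajectoryFrequencies", "ScreenTrajectory",
          function(x) x@frequencies)

#' @describeIn ScreenTrajectory-class Final-round frequencies.
#' @export
setGeneric("finalFrequencies",
           function(x) standardGeneric("finalFrequencies"))

#' @rdname ScreenTrajectory-class
#' @export
setMethod("finalFrequencies", "ScreenTrajectory",
          function(x) x@frequencies[nrow(x@frequencies), ])

setMethod("show", "ScreenTrajectory", function(object) {
  f <- object@frequencies
  cat("ScreenTrajectory: ", nrow(f) - 1L, " selection round(s), ",
      ncol(f), " variants\n", sep = "")
  top <- sort(f[nrow(f), ], decreasing = TRUE)
  cat("  top final variants:",
      paste(sprintf("%s (%.3g)", names(top)[1:min(3, length(top))],
                    top[1:min(3, length(top))]), collapse = ", "), "\n")
})
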