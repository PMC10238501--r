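# Coverage, diversity, enrichment and hit-clustering statistics over
# insertion profiles, plus library-design calculators.

.countVector <- function(x, orientation = "forward") {
  if (is(x, "InsertionProfile")) {
    if (orientation == "both") rowSums(x@counts) else x@counts[, orientation]
  } else as.numeric(x)
}

#' Fraction of insertion sites observed at least once
#'
#' The library-diversity statistic reported for the screen: the fraction
#' of the `nSites` possible insertion positions carrying at least one
#' mapped count (80.3% for the integrated LOV02 library against
#' Gal4-VP64).
#'
#' @param x An [InsertionProfile-class] or a numeric count vector.
#' @param nSites Number of possible sites (denominator). Defaults to the
#'   number of counts supplied; for a profile, to the number of valid
#'   positions `L - d + 1`.
#' @param orientation For profiles: `"forward"`, `"reverse"` or `"both"`
#'   (default `"forward"`: a site counts as covered when seen in the
#'   orientation that can encode the domain).
#' @return Fraction in `[0, 1]`.
#' @examples
#' coverageFraction(c(3, 0, 1, 2))  # 0.75
#' @export
coverageFraction <- function(x, nSites = NULL, orientation = "forward") {
  cts <- .countVector(x, orientation)
  if (is.null(nSites)) {
    nSites <- if (is(x, "InsertionProfile"))
      length(cts) - x@tsdLen else length(cts)
  }
  stopifnot(nSites >= 1)
  if (is(x, "InsertionProfile")) cts <- cts[seq_len(nSites)]
  sum(cts >= 1) / nSites
}

#' Probability a site is covered in at least one of k libraries
#'
#' `1 - (1 - p)^k` for `k` independent libraries with per-library coverage
#' probability `p`. With the screen's measured per-library coverage of
#' 0.803 and the three frame-shifted libraries this exceeds 0.99.
#'
#' @param pSingle Per-library coverage probability in `[0, 1]`.
#' @param k Number of independent libraries (>= 1).
#' @return Probability in `[0, 1]`.
#' @examples
#' unionCoverage(0.803, 3)
#' @export
unionCoverage <- function(pSingle, k) {
  stopifnot(all(pSingle >= 0), all(pSingle <= 1), all(k >= 1))
  1 - (1 - pSingle)^k
}

#' Fold coverage of a clone library
#'
#' `foldCoverage` is clones per possible insertion site (the screen's
#' colony counts gave approximately 190-fold);
#' `expectedFractionObserved` is the Poisson-sampling expectation
#' `1 - exp(-fold)` for the fraction of sites seen at least once at that
#' depth.
#'
#' @param nClones Number of clones.
#' @param nSites Number of possible insertion sites (>= 1).
#' @return Fold coverage (clones per site).
#' @examples
#' foldCoverage(190 * 600, 600)        # 190
#' expectedFractionObserved(log(2))    # 0.5
#' @export
foldCoverage <- function(nClones, nSites) {
  stopifnot(nSites >= 1)
  nClones / nSites
}

#' @rdname foldCoverage
#' @param fold Fold coverage (>= 0).
#' @export
expectedFractionObserved <- function(fold) {
  stopifnot(all(fold >= 0))
  1 - exp(-fold)
}

#' Display transform for count tracks
#'
#' `log10(count + 1)`, the transform used for plotting coverage profiles
#' so positions with zero counts remain on a logarithmic axis.
#'
#' @param counts Non-negative counts.
#' @return Transformed values (0 maps to 0, 9 to 1, 999 to 3).
#' @export
displayTransform <- function(counts) {
  counts <- .countVector(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log10(counts + 1)
}

#' Per-position log2 enrichment between two profiles
#'
#' For each position, `log2((f_b + eps) / (f_a + eps))` where `f` are
#' within-profile frequencies (counts over total mapped counts) and
#' `eps = pseudocount / nPositions` is a frequency-scale pseudocount, so
#' profiles of different sequencing depth are directly comparable and the
#' table negates exactly under swapping the two profiles.
#'
#' @param profileA,profileB [InsertionProfile-class] objects on the same
#'   target (A earlier round, B later round), or equal-length count
#'   vectors.
#' @param pseudocount Pseudocount in per-site frequency units (default 1,
#'   i.e. `eps = 1/nPositions`).
#' @param orientation Orientation aggregated for profiles (default
#'   `"forward"`).
#' @return Data frame with columns `p`, `log2_enrichment`, plus the
#'   attribute `pseudocount`.
#' @examples
#' a <- insertionProfile(c(1, 5), c(10, 10), L = 20)
#' b <- insertionProfile(c(1, 5), c(10, 90), L = 20)
#' subset(enrichment(a, b), log2_enrichment != 0)
#' @export
enrichment <- function(profileA, profileB, pseudocount = 1,
                       orientation = "forward") {
  stopifnot(pseudocount > 0)
  if (is(profileA, "InsertionProfile") && is(profileB, "InsertionProfile")) {
    if (!identical(profileA@targetName, profileB@targetName) ||
        nrow(profileA@counts) != nrow(profileB@counts))
      stop("profiles are not on the same target/coordinates")
  }
  a <- .countVector(profileA, orientation)
  b <- .countVector(profileB, orientation)
  if (length(a) != length(b)) stop("count vectors differ in length")
  eps <- pseudocount / length(a)
  fa <- if (sum(a) > 0) a / sum(a) else a
  fb <- if (sum(b) > 0) b / sum(b) else b
  out <- data.frame(p = seq_along(a) - 1L,
                    log2_enrichment = log2((fb + eps) / (fa + eps)))
  attr(out, "pseudocount") <- eps
  out
}

#' Single-linkage clustering of amino-acid hit sites
#'
#' 1-D single-linkage clusters: sites within `gap` residues of a neighbor
#' join the same cluster. The screen's final selected library forms a
#' single cluster (sites 22, 23, 29) with the Ser22/Lys23 junction as the
#' top site.
#'
#' @param sites Integer amino-acid sites.
#' @param counts Count per site (default 1 each).
#' @param gap Maximum residue gap joining neighbors (default 5).
#' @return Data frame with one row per cluster: `cluster`, `n_sites`,
#'   `top_site` (maximum count, ties to the lower site), `total_count`,
#'   and a list column `members`.
#' @examples
#' clusterHits(c(22, 23, 29), c(120, 30, 8), gap = 6)
#' @export
clusterHits <- function(sites, counts = NULL, gap = 5L) {
  stopifnot(gap >= 1)
  if (length(sites) == 0L)
    return(data.frame(cluster = integer(0), n_sites = integer(0),
                      top_site = integer(0), total_count = numeric(0)))
  if (is.null(counts)) counts <- rep(1, length(sites))
  ord <- order(sites)
  s <- sites[ord]; ct <- counts[ord]
  cl <- cumsum(c(1L, as.integer(diff(s) > gap)))
  out <- do.call(rbind, lapply(split(seq_along(s), cl), function(ix) {
    top <- ix[which.max(ct[ix])]
    data.frame(cluster = cl[ix[1]], n_sites = length(ix),
               top_site = s[top], total_count = sum(ct[ix]))
  }))
  out$members <- unname(split(s, cl))
  rownames(out) <- NULL
  out
}

#' Plot a coverage or enrichment track
#'
#' Base-graphics track of an insertion profile in the `log10(x + 1)`
#' display scale, or of a per-position enrichment table.
#'
#' @param x An [InsertionProfile-class] or the output of [enrichment()].
#' @param orientation For profiles, which orientation to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted values.
#' @importFrom graphics plot abline
#' @export
plotProfileTrack <- function(x, orientation = "forward", ...) {
  if (is(x, "InsertionProfile")) {
    y <- displayTransform(.countVector(x, orientation))
    graphics::plot(seq_along(y) - 1L, y, type = "h",
                   xlab = "insertion position p (nt)",
                   ylab = "log10(count + 1)", ...)
  } else {
    graphics::plot(x$p, x$log2_enrichment, type = "h",
                   xlab = "insertion position p (nt)",
                   ylab = "log2 enrichment", ...)
    graphics::abline(h = 0, col = "grey60")
  }
  invisible(x)
}
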