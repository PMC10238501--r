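#' @import methods
#' @import Biostrings
#' @importFrom stats quantile rbinom rlnorm rmultinom rnorm runif median sd
#'   setNames coef residuals
#' @importFrom utils write.table read.delim
NULL

.validDna <- function(x) {
  !grepl("[^ACGT]", x)
}

#' Target construct: a coding sequence accepting domain insertions
#'
#' A `TargetConstruct` bundles the coding sequence (CDS) of the protein to be
#' made photoswitchable (for example Gal4(1-147)-VP64), optional plasmid
#' flanks used when amplicons are simulated, and the derived protein
#' translation. The CDS length must be a multiple of 3 and the alphabet is
#' restricted to A/C/G/T.
#'
#' @slot name Construct label.
#' @slot cds [Biostrings::DNAString] coding sequence, length a multiple of 3.
#' @slot upstreamFlank,downstreamFlank [Biostrings::DNAString] plasmid
#'   context flanking the CDS in sequencing amplicons (may be empty).
#' @slot protein [Biostrings::AAString] translation of the CDS up to (not
#'   including) any terminal stop.
#'
#' @seealso [TargetConstruct()], [gal4Vp64Target()]
#' @export
setClass("TargetConstruct",
  representation(
    name = "character",
    cds = "DNAString",
    upstreamFlank = "DNAString",
    downstreamFlank = "DNAString",
    protein = "AAString"
  )
)

setValidity("TargetConstruct", function(object) {
  msg <- NULL
  cds <- as.character(object@cds)
  if (nchar(cds) %% 3L != 0L)
    msg <- c(msg, "CDS length must be a multiple of 3")
  if (!.validDna(cds))
    msg <- c(msg, "CDS must contain only A/C/G/T")
  for (fl in c("upstreamFlank", "downstreamFlank")) {
    s <- as.character(slot(object, fl))
    if (nchar(s) > 0L && !.validDna(s))
      msg <- c(msg, paste(fl, "must contain only A/C/G/T"))
  }
  if (nchar(cds) >= 3L) {
    expected <- .proteinFromCds(cds)
    if (!identical(as.character(object@protein), expected))
      msg <- c(msg, "protein slot does not match the CDS translation")
  }
  if (is.null(msg)) TRUE else msg
})

#' Frame variant of the domain insert
#'
#' A frame variant carries the extra scar bases added 5' (`s5`) and 3' (`s3`)
#' of the inserted domain. The three default variants LOV01/LOV02/LOV03 add
#' 1+0, 2+2 and 0+1 bases respectively, so that for any insertion position
#' exactly one variant places the domain in the target's reading frame.
#'
#' @slot name Variant label ("LOV01", "LOV02", "LOV03", or custom).
#' @slot s5,s3 Scar bases added 5' and 3' of the domain (character,
#'   possibly empty).
#'
#' @seealso [FrameVariant()], [defaultFrameVariants()]
#' @export
setClass("FrameVariant",
  representation(name = "character", s5 = "character", s3 = "character")
)

setValidity("FrameVariant", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  for (sl in c("s5", "s3")) {
    s <- slot(object, sl)
    if (length(s) != 1L) msg <- c(msg, paste(sl, "must be length 1"))
    else if (nchar(s) > 0L && !.validDna(s))
      msg <- c(msg, paste(sl, "must contain only A/C/G/T"))
  }
  if (is.null(msg)) TRUE else msg
})

#' Domain insert design
#'
#' The insert design holds the domain coding sequence (by default the 408-nt
#' AsLOV2 sequence covering residues 408-543 of Avena sativa phototropin 1),
#' the transposase target-site duplication length `d` (5 nt for Mu), and the
#' set of frame variants. Every variant must preserve the downstream reading
#' frame: `(d + nchar(s5) + length(domain) + nchar(s3)) %% 3 == 0`.
#'
#' @slot domainSeq [Biostrings::DNAString] domain coding sequence.
#' @slot tsdLen Target-site duplication length in nucleotides.
#' @slot variants Named list of [FrameVariant-class] objects.
#'
#' @seealso [InsertDesign()], [asLOV2Domain()]
#' @export
setClass("InsertDesign",
  representation(domainSeq = "DNAString", tsdLen = "integer",
                 variants = "list")
)

setValidity("InsertDesign", function(object) {
  msg <- NULL
  dom <- as.character(object@domainSeq)
  if (!.validDna(dom)) msg <- c(msg, "domain must contain only A/C/G/T")
  if (length(object@tsdLen) != 1L || is.na(object@tsdLen) ||
      object@tsdLen < 0L)
    msg <- c(msg, "tsdLen must be a single non-negative integer")
  if (length(object@variants) == 0L)
    msg <- c(msg, "at least one frame variant is required")
  for (v in object@variants) {
    if (!is(v, "FrameVariant")) {
      msg <- c(msg, "variants must be FrameVariant objects")
      next
    }
    tot <- object@tsdLen + nchar(v@s5) + nchar(dom) + nchar(v@s3)
    if (tot %% 3L != 0L)
      msg <- c(msg, sprintf(
        "variant '%s' breaks the downstream frame (inserted length %d)",
        v@name, tot))
  }
  if (!is.null(names(object@variants)) &&
      anyDuplicated(names(object@variants)))
    msg <- c(msg, "variant names must be unique")
  if (is.null(msg)) TRUE else msg
})

#' A single domain-insertion event
#'
#' An insertion event is the position, orientation and frame variant of one
#' transposition outcome. The position `p` is a 0-based gap coordinate: the
#' number of target-CDS nucleotides 5' of the insertion point, with the
#' duplicated `d`-mer attributed to the left junction (leftmost consistent
#' position).
#'
#' @slot p Integer gap coordinate in `[0, L]`.
#' @slot orientation `"forward"` or `"reverse"` (antisense) insertion.
#' @slot variant Frame-variant name.
#'
#' @seealso [InsertionEvent()], [buildInsertionCds()]
#' @export
setClass("InsertionEvent",
  representation(p = "integer", orientation = "character",
                 variant = "character")
)

setValidity("InsertionEvent", function(object) {
  msg <- NULL
  if (length(object@p) != 1L || is.na(object@p) || object@p < 0L)
    msg <- c(msg, "p must be a single non-negative integer")
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(object@variant) != 1L || !nzchar(object@variant))
    msg <- c(msg, "variant must be a single non-empty string")
  if (is.null(msg)) TRUE else msg
})

#' Per-position insertion count profile
#'
#' Counts of mapped insertion calls indexed by gap coordinate `p` (rows
#' `p0` ... `pL`) and orientation (columns `forward`, `reverse`), together
#' with read-accounting metadata. The accounting identity
#' `total == mapped + unmapped + ambiguous + nonJunction` is enforced.
#'
#' @slot counts Integer matrix `(L+1) x 2` of per-position call counts.
#' @slot targetName,variant Labels of the mapped target and frame variant.
#' @slot tsdLen Duplication length used for coordinate arithmetic.
#' @slot roundLabel Selection-round (or library) label.
#' @slot readStats Named integer vector with elements `total`, `mapped`,
#'   `unmapped`, `ambiguous`, `nonJunction`.
#'
#' @seealso [buildProfile()], [coverageFraction()], [enrichment()]
#' @export
setClass("InsertionProfile",
  representation(
    counts = "matrix",
    targetName = "character",
    variant = "character",
    tsdLen = "integer",
    roundLabel = "character",
    readStats = "integer"
  )
)

setValidity("InsertionProfile", function(object) {
  msg <- NULL
  cts <- object@counts
  if (ncol(cts) != 2L || !identical(colnames(cts), c("forward", "reverse")))
    msg <- c(msg, "counts must have columns 'forward' and 'reverse'")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  need <- c("total", "mapped", "unmapped", "ambiguous", "nonJunction")
  if (!all(need %in% names(object@readStats)))
    msg <- c(msg, "readStats must contain total/mapped/unmapped/ambiguous/nonJunction")
  else {
    rs <- object@readStats
    if (rs[["total"]] != rs[["mapped"]] + rs[["unmapped"]] +
          rs[["ambiguous"]] + rs[["nonJunction"]])
      msg <- c(msg, "read categories must sum to total")
  }
  if (is.null(msg)) TRUE else msg
})

#' Trajectory of a simulated selection screen
#'
#' Variant frequencies before selection and after each sorting round,
#' together with population GFP summaries evaluated under both dark and
#' light assay conditions.
#'
#' @slot frequencies Numeric matrix, one row per state (`initial`,
#'   `round1`, ...), one column per variant; rows sum to 1.
#' @slot gates List of gate specifications applied, in order.
#' @slot summaries Data frame of per-state population GFP medians under
#'   dark and light conditions.
#' @slot seed Seed used for the simulation (NA if none supplied).
#'
#' @seealso [runScreen()]
#' @export
setClass("ScreenTrajectory",
  representation(frequencies = "matrix", gates = "list",
                 summaries = "data.frame", seed = "numeric")
)

setValidity("ScreenTrajectory", function(object) {
  f <- object@frequencies
  if (any(f < 0)) return("frequencies must be non-negative")
  s <- rowSums(f)
  if (any(abs(s - 1) > 1e-8)) return("each round's frequencies must sum to 1")
  TRUE
})

#' Fluorescence-anisotropy titration curve
#'
#' Concentration-anisotropy measurements for a fixed probe (labeled DNA)
#' concentration titrated with protein. Replicated measurements share a
#' `replicate` label and are fitted jointly.
#'
#' @slot data Data frame with columns `P_nM` (titrant concentration,
#'   ascending within replicate), `anisotropy`, `replicate`.
#' @slot probe_nM Probe concentration T in nM.
#' @slot condition `"dark"`, `"light"` or other pass-through label.
#' @slot variant Protein variant label.
#'
#' @seealso [simulateTitration()], [fitTitration()]
#' @export
setClass("TitrationCurve",
  representation(data = "data.frame", probe_nM = "numeric",
                 condition = "character", variant = "character")
)

setValidity("TitrationCurve", function(object) {
  msg <- NULL
  d <- object@data
  if (!all(c("P_nM", "anisotropy", "replicate") %in% names(d)))
    msg <- c(msg, "data must have columns P_nM, anisotropy, replicate")
  else if (any(d$P_nM < 0)) msg <- c(msg, "P_nM must be non-negative")
  if (length(object@probe_nM) != 1L || object@probe_nM <= 0)
    msg <- c(msg, "probe_nM must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' One-site binding fit
#'
#' Result of fitting a titration curve to the one-site binding model:
#' point estimates and standard errors for the dissociation constant `Kd`
#' (nM) and the free/bound anisotropies, plus convergence diagnostics.
#'
#' @slot estimates Named numeric: `Kd`, `rFree`, `rBound`.
#' @slot se Named numeric standard errors (same names).
#' @slot converged Logical: optimizer converged and `Kd` is interior.
#' @slot model `"depletion"` (exact quadratic) or `"hyperbola"`.
#' @slot residSd Residual standard deviation of the fit.
#' @slot nObs Number of observations fitted.
#'
#' @seealso [fitTitration()]
#' @export
setClass("BindingFit",
  representation(estimates = "numeric", se = "numeric",
                 converged = "logical", model = "character",
                 residSd = "numeric", nObs = "integer")
)

setValidity("BindingFit", function(object) {
  need <- c("Kd", "rFree", "rBound")
  if (!all(need %in% names(object@estimates)))
    return("estimates must be named Kd, rFree, rBound")
  if (object@estimates[["Kd"]] <= 0) return("Kd must be positive")
  TRUE
})
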