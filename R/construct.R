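# Construct arithmetic: fusion CDS assembly with target-site duplication,
# reading-frame classification, and amino-acid site naming.

.proteinFromCds <- function(cds) {
  aa <- .translateChar(cds)
  sub("\\*.*$", "", aa)
}

.translateChar <- function(seq) {
  s <- toupper(as.character(seq))
  if (grepl("[^ACGT]", s)) stop("non-ACGT character in sequence")
  n <- (nchar(s) %/% 3L) * 3L
  if (n < 3L) stop("sequence shorter than one codon")
  # no.init.codon: sequences are translated literally (a leading CTG/TTG
  # is Leu/Leu, not an initiator Met) -- required for domain fragments
  as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                                     no.init.codon = TRUE))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Stop codons are rendered as `"*"`; a trailing partial codon is ignored.
#'
#' @param seq Nucleotide sequence (character or [Biostrings::DNAString]),
#'   A/C/G/T only.
#' @return Amino-acid sequence as a character string.
#' @examples
#' translateCds("ATGAAA")  # "MK"
#' translateCds("TAA")     # "*"
#' @export
translateCds <- function(seq) .translateChar(seq)

#' @describeIn TargetConstruct-class Constructor; the protein slot is
#'   derived by translating the CDS up to any terminal stop.
#' @param name Construct label.
#' @param cds Coding sequence (character or [Biostrings::DNAString]).
#' @param upstreamFlank,downstreamFlank Optional flanking sequence.
#' @export
TargetConstruct <- function(name, cds, upstreamFlank = "",
                            downstreamFlank = "") {
  cds <- Biostrings::DNAString(toupper(as.character(cds)))
  new("TargetConstruct",
    name = name,
    cds = cds,
    upstreamFlank = Biostrings::DNAString(toupper(as.character(upstreamFlank))),
    downstreamFlank = Biostrings::DNAString(toupper(as.character(downstreamFlank))),
    protein = Biostrings::AAString(.proteinFromCds(as.character(cds)))
  )
}

#' @describeIn FrameVariant-class Constructor.
#' @param name Variant label.
#' @param s5,s3 Scar bases added 5' and 3' of the domain.
#' @export
FrameVariant <- function(name, s5 = "", s3 = "") {
  new("FrameVariant", name = name, s5 = toupper(s5), s3 = toupper(s3))
}

#' Default frame variants LOV01/LOV02/LOV03
#'
#' The three frame-shifted insert designs: LOV01 adds one base 5' of the
#' domain, LOV02 adds two bases at each end, and LOV03 adds one base 3'.
#' With a 5-nt target-site duplication they partition insertion positions
#' by residue class mod 3 (LOV01: p = 0, LOV03: p = 1, LOV02: p = 2).
#' Scar content is all-C (configurable): frame arithmetic depends only on
#' scar lengths, and C-containing codons can never be stops.
#'
#' @return Named list of three [FrameVariant-class] objects.
#' @examples
#' defaultFrameVariants()
#' @export
defaultFrameVariants <- function() {
  list(
    LOV01 = FrameVariant("LOV01", s5 = "C", s3 = ""),
    LOV02 = FrameVariant("LOV02", s5 = "CC", s3 = "CC"),
    LOV03 = FrameVariant("LOV03", s5 = "", s3 = "C")
  )
}

#' @describeIn InsertDesign-class Constructor.
#' @param domainSeq Domain coding sequence (default: the 408-nt AsLOV2
#'   sequence from [asLOV2Domain()]).
#' @param tsdLen Target-site duplication length `d` in nt (default 5, the
#'   Mu transposase duplication).
#' @param variants List of [FrameVariant-class] objects (default
#'   [defaultFrameVariants()]).
#' @export
InsertDesign <- function(domainSeq = asLOV2Domain(), tsdLen = 5L,
                         variants = defaultFrameVariants()) {
  if (is.null(names(variants)))
    names(variants) <- vapply(variants, function(v) v@name, character(1))
  new("InsertDesign",
    domainSeq = Biostrings::DNAString(toupper(as.character(domainSeq))),
    tsdLen = as.integer(tsdLen), variants = variants)
}

#' @describeIn InsertionEvent-class Constructor.
#' @param p 0-based gap coordinate (CDS nucleotides 5' of the insertion).
#' @param orientation `"forward"` or `"reverse"`.
#' @param variant Frame-variant name.
#' @export
InsertionEvent <- function(p, orientation = "forward", variant = "LOV02") {
  new("InsertionEvent", p = as.integer(p), orientation = orientation,
      variant = variant)
}

.getVariant <- function(design, variant) {
  if (is(variant, "FrameVariant")) return(variant)
  v <- design@variants[[variant]]
  if (is.null(v)) stop("unknown frame variant: ", variant)
  v
}

# Full inserted cassette (scar + domain + scar) on the forward strand.
.insertSeq <- function(design, variant) {
  v <- .getVariant(design, variant)
  paste0(v@s5, as.character(design@domainSeq), v@s3)
}

#' Build the fusion CDS for one insertion event
#'
#' Models the sequence outcome of Mu transposition followed by domain
#' replacement: for a forward insertion at gap coordinate `p` with
#' duplication length `d`, the fusion is
#' `cds[1..p+d] + s5 + domain + s3 + cds[p+1..L]`, so the `d`-mer
#' `cds[p+1..p+d]` appears twice, flanking the insert (the target-site
#' duplication). Reverse-orientation events insert the reverse complement
#' of `s5 + domain + s3` between the same duplicated bases.
#'
#' @param target A [TargetConstruct-class].
#' @param event An [InsertionEvent-class].
#' @param design An [InsertDesign-class].
#' @return The fusion CDS as a [Biostrings::DNAString] of length
#'   `L + d + nchar(s5) + length(domain) + nchar(s3)`.
#' @examples
#' tgt <- TargetConstruct("toy", "ATGGGGAAACCC")
#' des <- InsertDesign("AAATTT", tsdLen = 0L,
#'                     variants = list(FrameVariant("V0")))
#' buildInsertionCds(tgt, InsertionEvent(0, variant = "V0"), des)
#' @export
buildInsertionCds <- function(target, event, design) {
  stopifnot(is(target, "TargetConstruct"), is(event, "InsertionEvent"),
            is(design, "InsertDesign"))
  cds <- as.character(target@cds)
  L <- nchar(cds)
  d <- design@tsdLen
  p <- event@p
  if (p < 0L || p > L) stop("insertion position p out of range [0, ", L, "]")
  if (p + d > L) stop("duplication does not fit: p + d > L")
  ins <- .insertSeq(design, event@variant)
  if (event@orientation == "reverse")
    ins <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
  Biostrings::DNAString(paste0(
    substr(cds, 1L, p + d), ins, substr(cds, p + 1L, L)))
}

# Fusion-coordinate ranges of the bases not present in the wild-type CDS
# frame: both copies of the duplicated d-mer's second copy region and the
# scar bases (for reverse orientation, the whole inserted cassette).
.linkerRanges <- function(L, d, p, n5, ndom, n3, orientation) {
  ni <- n5 + ndom + n3
  if (orientation == "forward") {
    # left: duplicated d-mer + s5; right: s3 + the downstream copy's d-mer
    list(c(p + 1L, p + d + n5),
         c(p + d + n5 + ndom + 1L, p + d + ni + d))
  } else {
    list(c(p + 1L, p + d + ni + d))
  }
}

#' Classify the reading frames of an insertion event
#'
#' Determines whether the inserted domain is in frame with the upstream
#' target (`(p + d + nchar(s5)) %% 3 == 0`, forward orientation only),
#' whether the downstream target frame is preserved (total inserted length
#' divisible by 3), and whether a stop codon occurs in the translated
#' duplication/scar codons of the constructed fusion. An event is
#' `functional` when it is forward, both frames hold and no linker stop
#' occurs.
#'
#' @inheritParams buildInsertionCds
#' @return A list with elements `domain_in_frame`, `downstream_in_frame`,
#'   `stop_in_linker`, `functional`.
#' @examples
#' tgt <- gal4Vp64Target()
#' des <- InsertDesign()
#' classifyFrame(tgt, InsertionEvent(65, variant = "LOV02"), des)
#' @export
classifyFrame <- function(target, event, design) {
  stopifnot(is(target, "TargetConstruct"), is(event, "InsertionEvent"),
            is(design, "InsertDesign"))
  d <- design@tsdLen
  p <- event@p
  v <- .getVariant(design, event@variant)
  n5 <- nchar(v@s5); n3 <- nchar(v@s3)
  ndom <- length(design@domainSeq)
  ni <- n5 + ndom + n3
  domain_in_frame <- event@orientation == "forward" &&
    (p + d + n5) %% 3L == 0L
  downstream_in_frame <- (d + ni) %% 3L == 0L
  fusion <- as.character(buildInsertionCds(target, event, design))
  aa <- .translateChar(fusion)
  L <- length(target@cds)
  stop_in_linker <- FALSE
  for (rg in .linkerRanges(L, d, p, n5, ndom, n3, event@orientation)) {
    ci <- ((rg[1] - 1L) %/% 3L + 1L):((rg[2] - 1L) %/% 3L + 1L)
    ci <- ci[ci <= nchar(aa)]
    if (any(strsplit(substr(aa, min(ci), max(ci)), "")[[1]] == "*"))
      stop_in_linker <- TRUE
  }
  list(
    domain_in_frame = domain_in_frame,
    downstream_in_frame = downstream_in_frame,
    stop_in_linker = stop_in_linker,
    functional = event@orientation == "forward" && domain_in_frame &&
      downstream_in_frame && !stop_in_linker
  )
}

#' Amino-acid insertion-site label of a fusion construct
#'
#' The site is the length of the longest common prefix of the fusion's
#' translation and the target protein: a construct with site 22 is labeled
#' "after residue 22", i.e. inserted between residue 22 and residue 23.
#' Because the target-site duplication and scar codons can extend or
#' truncate the conserved prefix, the site is computed by translation
#' rather than closed-form arithmetic.
#'
#' @param fusionCds Fusion coding sequence (character or
#'   [Biostrings::DNAString]).
#' @param targetProtein Target protein sequence (character or
#'   [Biostrings::AAString]).
#' @return Integer site (0 allowed for insertions at/near the start).
#' @examples
#' assignAaSite("ATGAAATTT", "MK")  # identical prefix: 2
#' @export
assignAaSite <- function(fusionCds, targetProtein) {
  aaF <- strsplit(.translateChar(fusionCds), "")[[1]]
  aaT <- strsplit(toupper(as.character(targetProtein)), "")[[1]]
  n <- min(length(aaF), length(aaT))
  if (n == 0L) return(0L)
  neq <- aaF[seq_len(n)] != aaT[seq_len(n)]
  if (any(neq)) which(neq)[1] - 1L else n
}

#' Which frame variant is in frame at each insertion position
#'
#' For every gap coordinate `p` in `[0, L - d]`, reports the frame variant
#' (if any) for which a forward insertion has both the domain and the
#' downstream target in frame. With the default LOV01/LOV02/LOV03 scars and
#' `d = 5`, the three variants partition positions by `p %% 3`
#' (LOV01: 0, LOV03: 1, LOV02: 2), realizing in-frame insertion at every
#' nucleotide position across the three libraries.
#'
#' @inheritParams buildInsertionCds
#' @return Data frame with columns `p` and `variant` (`NA` when no variant
#'   is in frame).
#' @examples
#' tgt <- gal4Vp64Target()
#' head(enumerateInFramePositions(tgt, InsertDesign()))
#' @export
enumerateInFramePositions <- function(target, design) {
  d <- design@tsdLen
  L <- length(target@cds)
  ndom <- length(design@domainSeq)
  p <- 0:(L - d)
  variant <- rep(NA_character_, length(p))
  for (v in design@variants) {
    n5 <- nchar(v@s5); n3 <- nchar(v@s3)
    if ((d + n5 + ndom + n3) %% 3L != 0L)
      stop("variant '", v@name, "' violates the downstream-frame invariant")
    hit <- (p + d + n5) %% 3L == 0L
    clash <- hit & !is.na(variant)
    if (any(clash))
      stop("positions claimed by more than one variant (first: p=",
           p[which(clash)[1]], ")")
    variant[hit] <- v@name
  }
  data.frame(p = p, variant = variant)
}

#' Tabulate construction outcomes for a set of insertion events
#'
#' @param target A [TargetConstruct-class].
#' @param design An [InsertDesign-class].
#' @param events Data frame with columns `p`, `orientation`, `variant`
#'   (as produced by [sampleLibrary()]), or a list of
#'   [InsertionEvent-class] objects.
#' @return Data frame with columns `p`, `variant`, `orientation`,
#'   `domain_in_frame`, `downstream_in_frame`, `stop_in_linker`,
#'   `functional` and `aa_site` (NA unless functional).
#' @examples
#' tgt <- gal4Vp64Target()
#' constructReport(tgt, InsertDesign(),
#'                 data.frame(p = c(62, 63), orientation = "forward",
#'                            variant = c("LOV02", "LOV01")))
#' @export
constructReport <- function(target, design, events) {
  events <- .asEventFrame(events)
  prot <- as.character(target@protein)
  out <- lapply(seq_len(nrow(events)), function(i) {
    ev <- InsertionEvent(events$p[i], events$orientation[i],
                         events$variant[i])
    fc <- classifyFrame(target, ev, design)
    aa <- if (fc$functional)
      assignAaSite(buildInsertionCds(target, ev, design), prot)
    else NA_integer_
    data.frame(p = ev@p, variant = ev@variant, orientation = ev@orientation,
               domain_in_frame = fc$domain_in_frame,
               downstream_in_frame = fc$downstream_in_frame,
               stop_in_linker = fc$stop_in_linker,
               functional = fc$functional, aa_site = aa)
  })
  do.call(rbind, out)
}

.asEventFrame <- function(events) {
  if (is.data.frame(events)) {
    stopifnot(all(c("p", "orientation", "variant") %in% names(events)))
    return(events)
  }
  do.call(rbind, lapply(events, function(e)
    data.frame(p = e@p, orientation = e@orientation, variant = e@variant)))
}

## Accessors ------------------------------------------------------------

#' @describeIn TargetConstruct-class CDS accessor.
#' @param x,object A `TargetConstruct`.
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @rdname TargetConstruct-class
#' @export
setMethod("cdsSeq", "TargetConstruct", function(x) x@cds)

#' @describeIn TargetConstruct-class Protein accessor.
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))

#' @rdname TargetConstruct-class
#' @export
setMethod("proteinSeq", "TargetConstruct", function(x) x@protein)

setMethod("show", "TargetConstruct", function(object) {
  cat("TargetConstruct '", object@name, "': ", length(object@cds),
      " nt CDS (", length(object@protein), " aa), flanks ",
      length(object@upstreamFlank), "/", length(object@downstreamFlank),
      " nt\n", sep = "")
})

setMethod("show", "InsertDesign", function(object) {
  cat("InsertDesign: ", length(object@domainSeq), " nt domain, d = ",
      object@tsdLen, " nt TSD, variants: ",
      paste(names(object@variants), collapse = ", "), "\n", sep = "")
})

setMethod("show", "InsertionEvent", function(object) {
  cat("InsertionEvent p=", object@p, " (", object@orientation, ", ",
      object@variant, ")\n", sep = "")
})
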