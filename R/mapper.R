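# FASTQ analysis: detect domain/target junction reads, call insertion
# position + orientation, aggregate per-position count profiles.

#' Exact k-mer index of a target CDS
#'
#' Hash from every k-mer of the CDS (both strands) to its 1-based offsets.
#' Target CDSs here are short (~0.6-1 kb), so exact lookup is robust and
#' fast; ambiguity from internal repeats is preserved as multi-offset hits.
#'
#' @param cds Nucleotide sequence (character or [Biostrings::DNAString]).
#' @param k k-mer length (default 20; must be <= the CDS length).
#' @return An object of class `"KmerIndex"` with fields `k`, `L` and a
#'   lookup environment.
#' @seealso [lookupKmer()]
#' @export
indexTarget <- function(cds, k = 20L) {
  s <- toupper(as.character(cds))
  L <- nchar(s)
  if (k > L) stop("k must not exceed the CDS length (k=", k, ", L=", L, ")")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  structure(list(k = as.integer(k), L = L, seq = s,
                 dna = Biostrings::DNAString(s),
                 fwd = .fillIndex(s, k), rev = .fillIndex(rc, k)),
            class = "KmerIndex")
}

# kmer -> integer offsets (1-based starts on the given strand's sequence)
.fillIndex <- function(s, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  n <- nchar(s) - k + 1L
  km <- substring(s, 1:n, k:(k + n - 1L))
  for (i in seq_len(n)) env[[km[i]]] <- c(env[[km[i]]], i)
  env
}

#' Look up a k-mer in a target index
#'
#' @param index A `"KmerIndex"` from [indexTarget()].
#' @param kmer Query of length `k`.
#' @param strand Restrict to `"+"`, `"-"`, or `"both"`.
#' @return Data frame with columns `offset` (1-based, on the queried
#'   strand's coordinates: `"+"` offsets are CDS positions) and `strand`;
#'   zero rows for no hit.
#' @export
lookupKmer <- function(index, kmer, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  kmer <- toupper(kmer)
  f <- if (strand %in% c("both", "+")) index$fwd[[kmer]] else NULL
  r <- if (strand %in% c("both", "-")) index$rev[[kmer]] else NULL
  data.frame(offset = c(f, r, integer(0)),
             strand = c(rep("+", length(f)), rep("-", length(r))))
}

# Anchor set for one frame variant: the first/last anchorLen nt of the
# inserted cassette (s5+domain+s3) and their reverse complements. Each
# anchor implies which junction side and insert orientation it marks when
# found on the target's forward strand.
.anchorSet <- function(design, variant, anchorLen) {
  ins <- .insertSeq(design, variant)
  if (anchorLen < 12L) stop("anchorLen must be >= 12")
  if (anchorLen > nchar(ins)) stop("anchorLen exceeds the insert length")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  A5 <- substr(ins, 1L, anchorLen)
  A3 <- substr(ins, nchar(ins) - anchorLen + 1L, nchar(ins))
  list(
    list(seq = A5,     side = "left",  orientation = "forward"),
    list(seq = A3,     side = "right", orientation = "forward"),
    list(seq = rc(A3), side = "left",  orientation = "reverse"),
    list(seq = rc(A5), side = "right", orientation = "reverse"))
}

#' Find domain/target junction anchors in a read
#'
#' Scans a read (and its reverse complement) for the terminal `anchorLen`
#' nucleotides of the inserted cassette and their reverse complements,
#' allowing up to `maxMismatch` substitutions. Each hit is labeled with the
#' junction side it represents (`left` = target then insert, `right` =
#' insert then target, in target-forward coordinates), the implied insert
#' orientation, and the read strand on which it was found.
#'
#' @param read A single read (character or [Biostrings::DNAString]).
#' @param design An [InsertDesign-class].
#' @param variant Frame-variant name of the sequenced library.
#' @param anchorLen Anchor length (default 15, minimum 12).
#' @param maxMismatch Substitutions tolerated in the anchor (default 1).
#' @return Data frame with columns `side`, `offset` (1-based anchor start
#'   within the reported strand), `orientation`, `strand` (`"+"` read
#'   as-is, `"-"` reverse complement); zero rows when no anchor matches.
#' @export
findJunctions <- function(read, design, variant = "LOV02", anchorLen = 15L,
                          maxMismatch = 1L) {
  anchors <- .anchorSet(design, variant, anchorLen)
  rs <- toupper(as.character(read))
  strands <- c("+" = rs,
               "-" = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(rs))))
  out <- list()
  for (st in names(strands)) {
    subj <- Biostrings::DNAString(strands[[st]])
    for (a in anchors) {
      m <- Biostrings::matchPattern(a$seq, subj, max.mismatch = maxMismatch)
      if (length(m))
        out[[length(out) + 1L]] <- data.frame(
          side = a$side, offset = Biostrings::start(m),
          orientation = a$orientation, strand = st)
    }
  }
  if (!length(out)) return(data.frame(side = character(0),
                                      offset = integer(0),
                                      orientation = character(0),
                                      strand = character(0)))
  do.call(rbind, out)
}

# Map p to the leftmost position yielding an identical fusion sequence
# (duplication-induced equivalence). One map per orientation.
.canonicalPMap <- function(target, design, variant) {
  cds <- as.character(target@cds)
  L <- nchar(cds)
  d <- design@tsdLen
  ps <- 0:(L - d)
  ins <- .insertSeq(design, variant)
  insRev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ins)))
  lapply(list(forward = ins, reverse = insRev), function(insert) {
    seqs <- paste0(substr(rep(cds, length(ps)), 1L, ps + d), insert,
                   substring(cds, ps + 1L))
    ps[match(seqs, seqs)]
  })
}

#' Call the insertion position from one junction-spanning read
#'
#' For each anchor hit the target-derived flank adjacent to the insert is
#' looked up in the k-mer index (exact lookup, with a mismatch-tolerant
#' fallback scan of up to `flankMismatch` substitutions). Left junctions
#' give `p = offset + k - 1 - d`, right junctions `p = offset - 1`; both
#' are normalized to the leftmost position consistent with the target-site
#' duplication. Calls from multiple junctions of the same read must agree,
#' otherwise the read is ambiguous; flanks shorter than `minFlank` or
#' flanks mapping to multiple loci do not produce calls.
#'
#' @param read A single read (character or [Biostrings::DNAString]).
#' @param index A `"KmerIndex"` of the target CDS ([indexTarget()]).
#' @param target A [TargetConstruct-class].
#' @param design An [InsertDesign-class].
#' @param variant Frame-variant name of the sequenced library.
#' @param minFlank Minimum target flank used for lookup (default the
#'   index's `k`; must be >= `k`).
#' @param anchorLen,maxMismatch Anchor search parameters
#'   (see [findJunctions()]).
#' @param flankMismatch Substitutions tolerated in the flank lookup
#'   (default 1).
#' @return A list with elements `p`, `orientation`, `side`
#'   (`left`/`right`/`both`), `mismatches`; or `NULL` for no callable
#'   junction; or the string `"ambiguous"` for conflicting/multi-locus
#'   evidence.
#' @export
callInsertion <- function(read, index, target, design, variant = "LOV02",
                          minFlank = index$k, anchorLen = 15L,
                          maxMismatch = 1L, flankMismatch = 1L) {
  if (minFlank < index$k) stop("minFlank must be >= the index k")
  pmap <- .canonicalPMap(target, design, variant)
  res <- .callOne(toupper(as.character(read)), index, design, variant,
                  length(target@cds), design@tsdLen, pmap,
                  minFlank, anchorLen, maxMismatch, flankMismatch)
  if (res$category == "mapped")
    list(p = res$p, orientation = res$orientation, side = res$side,
         mismatches = res$mismatches)
  else if (res$category == "ambiguous") "ambiguous"
  else NULL
}

# Core single-read caller over a prepared environment; returns a category
# plus call fields. `hits` may be precomputed (vectorized path), and the
# read's reverse complement may be supplied to avoid recomputation.
.callOne <- function(rs, index, design, variant, L, d, pmap,
                     minFlank, anchorLen, maxMismatch, flankMismatch,
                     hits = NULL, rsRC = NULL) {
  if (is.null(hits))
    hits <- findJunctions(rs, design, variant, anchorLen, maxMismatch)
  if (nrow(hits) == 0L)
    return(list(category = "nonJunction"))
  strands <- list("+" = rs)
  if (any(hits$strand == "-"))
    strands[["-"]] <- if (!is.null(rsRC)) rsRC else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(rs)))
  k <- index$k
  calls <- list()
  sawShort <- FALSE
  ambiguous <- FALSE
  for (i in seq_len(nrow(hits))) {
    s <- strands[[hits$strand[i]]]
    a0 <- hits$offset[i]
    if (hits$side[i] == "left") {
      flank <- substr(s, 1L, a0 - 1L)
      if (nchar(flank) == 0L) next
      if (nchar(flank) < minFlank) { sawShort <- TRUE; next }
      kmer <- substr(flank, nchar(flank) - k + 1L, nchar(flank))
    } else {
      fstart <- a0 + anchorLen
      flank <- substr(s, fstart, nchar(s))
      if (nchar(flank) == 0L) next
      if (nchar(flank) < minFlank) { sawShort <- TRUE; next }
      kmer <- substr(flank, 1L, k)
    }
    offs <- index$fwd[[kmer]]
    mm <- 0L
    if (is.null(offs) && flankMismatch > 0L) {
      m <- Biostrings::matchPattern(kmer, index$dna,
                                    max.mismatch = flankMismatch)
      if (length(m)) {
        offs <- Biostrings::start(m)
        mm <- 1L
      }
    }
    if (is.null(offs) || length(offs) == 0L) { sawShort <- TRUE; next }
    if (length(offs) > 1L) { ambiguous <- TRUE; next }
    o <- offs[1]
    p <- if (hits$side[i] == "left") o + k - 1L - d else o - 1L
    if (p < 0L || p > L - d) { sawShort <- TRUE; next }
    p <- pmap[[hits$orientation[i]]][p + 1L]
    calls[[length(calls) + 1L]] <- list(
      p = p, orientation = hits$orientation[i], side = hits$side[i],
      mismatches = mm)
  }
  if (!length(calls)) {
    if (ambiguous) return(list(category = "ambiguous"))
    if (sawShort) return(list(category = "unmapped"))
    return(list(category = "nonJunction"))
  }
  ps <- vapply(calls, `[[`, integer(1), "p")
  oris <- vapply(calls, `[[`, character(1), "orientation")
  if (length(unique(ps)) > 1L || length(unique(oris)) > 1L || ambiguous)
    return(list(category = "ambiguous"))
  sides <- unique(vapply(calls, `[[`, character(1), "side"))
  list(category = "mapped", p = ps[1], orientation = oris[1],
       side = if (length(sides) > 1L) "both" else sides,
       mismatches = max(vapply(calls, `[[`, integer(1), "mismatches")))
}

# Vectorized anchor search over a read set: one vmatchPattern call per
# (anchor, strand), then per-read hit tables assembled in one split().
.findJunctionsSet <- function(reads, design, variant, anchorLen,
                              maxMismatch,
                              readsRC = Biostrings::reverseComplement(reads)) {
  anchors <- .anchorSet(design, variant, anchorLen)
  n <- length(reads)
  subjects <- list("+" = reads, "-" = readsRC)
  ri <- integer(0); side <- character(0); off <- integer(0)
  ori <- character(0); strand <- character(0)
  for (st in names(subjects)) {
    for (a in anchors) {
      m <- Biostrings::vmatchPattern(a$seq, subjects[[st]],
                                     max.mismatch = maxMismatch)
      starts <- Biostrings::startIndex(m)
      nh <- lengths(starts)
      if (!any(nh > 0L)) next
      ri <- c(ri, rep.int(seq_len(n), nh))
      off <- c(off, unlist(starts, use.names = FALSE))
      tot <- sum(nh)
      side <- c(side, rep.int(a$side, tot))
      ori <- c(ori, rep.int(a$orientation, tot))
      strand <- c(strand, rep.int(st, tot))
    }
  }
  hits <- vector("list", n)
  if (length(ri)) {
    df <- data.frame(side = side, offset = off, orientation = ori,
                     strand = strand)
    for (grp in split(seq_along(ri), ri)) {
      hits[[ri[grp[1]]]] <- df[grp, , drop = FALSE]
    }
  }
  hits
}

#' Map a read pool into a per-position insertion profile
#'
#' Runs the junction caller over every read and aggregates the calls into
#' per-position counts by orientation, with full read accounting
#' (`total == mapped + unmapped + ambiguous + nonJunction`).
#'
#' @param reads FASTQ file path(s) or a [Biostrings::DNAStringSet].
#' @param target A [TargetConstruct-class].
#' @param design An [InsertDesign-class].
#' @param variant Frame-variant name of the sequenced library (libraries
#'   are sequenced separately, so variant identity is configuration).
#' @param k Index k-mer length and minimum flank (default 20).
#' @param anchorLen,maxMismatch,flankMismatch See [callInsertion()].
#' @param roundLabel Metadata label for the profile.
#' @return An [InsertionProfile-class].
#' @examples
#' tgt <- gal4Vp64Target()
#' des <- InsertDesign()
#' amp <- Biostrings::DNAStringSet(setNames(
#'   as.character(buildAmplicon(tgt, InsertionEvent(65), des)),
#'   "p65_for_LOV02"))
#' reads <- shearAndRead(amp, nReads = 50, perBaseError = 0, seed = 1)
#' prof <- buildProfile(reads, tgt, des)
#' profileStats(prof)
#' @export
buildProfile <- function(reads, target, design, variant = "LOV02",
                         k = 20L, anchorLen = 15L, maxMismatch = 1L,
                         flankMismatch = 1L, roundLabel = "") {
  if (is.character(reads)) {
    reads <- do.call(c, lapply(reads, readFastq))
  }
  reads <- Biostrings::DNAStringSet(reads)
  L <- length(target@cds)
  d <- design@tsdLen
  index <- indexTarget(as.character(target@cds), k)
  pmap <- .canonicalPMap(target, design, variant)
  counts <- matrix(0L, nrow = L + 1L, ncol = 2L,
                   dimnames = list(paste0("p", 0:L),
                                   c("forward", "reverse")))
  stats <- c(total = length(reads), mapped = 0L, unmapped = 0L,
             ambiguous = 0L, nonJunction = 0L)
  if (length(reads)) {
    readsRC <- Biostrings::reverseComplement(reads)
    hitList <- .findJunctionsSet(reads, design, variant, anchorLen,
                                 maxMismatch, readsRC)
    readChar <- as.character(reads)
    rcChar <- as.character(readsRC)
    for (i in seq_along(readChar)) {
      if (is.null(hitList[[i]])) {
        stats[["nonJunction"]] <- stats[["nonJunction"]] + 1L
        next
      }
      res <- .callOne(readChar[i], index, design, variant, L, d, pmap,
                      minFlank = k, anchorLen, maxMismatch, flankMismatch,
                      hits = hitList[[i]], rsRC = rcChar[i])
      stats[[res$category]] <- stats[[res$category]] + 1L
      if (res$category == "mapped")
        counts[res$p + 1L, res$orientation] <-
          counts[res$p + 1L, res$orientation] + 1L
    }
  }
  new("InsertionProfile", counts = counts, targetName = target@name,
      variant = variant, tsdLen = d, roundLabel = roundLabel,
      readStats = stats)
}

#' Build an InsertionProfile from known counts
#'
#' Constructor used for truth profiles and tabular input: supply counts at
#' chosen positions directly.
#'
#' @param p Integer vector of gap coordinates.
#' @param counts Integer vector of counts (recycled).
#' @param L Target CDS length.
#' @param orientation Orientation per position (recycled).
#' @param targetName,variant,roundLabel Metadata labels.
#' @param tsdLen Duplication length (default 5).
#' @return An [InsertionProfile-class] whose read accounting treats every
#'   count as a mapped read.
#' @export
insertionProfile <- function(p, counts, L, orientation = "forward",
                             targetName = "", variant = "LOV02",
                             roundLabel = "", tsdLen = 5L) {
  mat <- matrix(0L, nrow = L + 1L, ncol = 2L,
                dimnames = list(paste0("p", 0:L), c("forward", "reverse")))
  orientation <- rep(orientation, length.out = length(p))
  counts <- as.integer(rep(counts, length.out = length(p)))
  for (i in seq_along(p))
    mat[p[i] + 1L, orientation[i]] <- mat[p[i] + 1L, orientation[i]] +
      counts[i]
  tot <- sum(mat)
  new("InsertionProfile", counts = mat, targetName = targetName,
      variant = variant, tsdLen = as.integer(tsdLen),
      roundLabel = roundLabel,
      readStats = c(total = tot, mapped = tot, unmapped = 0L,
                    ambiguous = 0L, nonJunction = 0L))
}

#' @describeIn InsertionProfile-class Count-matrix accessor.
#' @param x,object An `InsertionProfile`.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname InsertionProfile-class
#' @export
setMethod("profileCounts", "InsertionProfile", function(x) x@counts)

#' @describeIn InsertionProfile-class Read-accounting accessor.
#' @export
setGeneric("profileStats", function(x) standardGeneric("profileStats"))

#' @rdname InsertionProfile-class
#' @export
setMethod("profileStats", "InsertionProfile", function(x) x@readStats)

setMethod("show", "InsertionProfile", function(object) {
  rs <- object@readStats
  nz <- sum(rowSums(object@counts) > 0)
  cat("InsertionProfile on '", object@targetName, "' (", object@variant,
      if (nzchar(object@roundLabel)) paste0(", ", object@roundLabel), "): ",
      nz, " occupied positions; reads: ", rs[["mapped"]], " mapped / ",
      rs[["total"]], " total (", rs[["ambiguous"]], " ambiguous, ",
      rs[["unmapped"]], " unmapped, ", rs[["nonJunction"]],
      " non-junction)\n", sep = "")
})

#' Write / read an insertion profile as tabular text
#'
#' TSV with `#`-prefixed header metadata lines followed by columns
#' `p`, `forward`, `reverse`.
#'
#' @param profile An [InsertionProfile-class].
#' @param path Output path.
#' @return `path` invisibly (`writeProfile`); an `InsertionProfile`
#'   (`readProfile`).
#' @export
writeProfile <- function(profile, path) {
  rs <- profile@readStats
  hdr <- c(
    paste0("# target=", profile@targetName),
    paste0("# variant=", profile@variant),
    paste0("# round=", profile@roundLabel),
    paste0("# tsdLen=", profile@tsdLen),
    paste0("# reads total=", rs[["total"]], " mapped=", rs[["mapped"]],
           " unmapped=", rs[["unmapped"]], " ambiguous=", rs[["ambiguous"]],
           " nonJunction=", rs[["nonJunction"]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(p = 0:(nrow(profile@counts) - 1L),
                   forward = profile@counts[, "forward"],
                   reverse = profile@counts[, "reverse"])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @param path Profile TSV path.
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = "") {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  mat <- as.matrix(df[, c("forward", "reverse")])
  rownames(mat) <- paste0("p", df$p)
  mode(mat) <- "integer"
  rstat <- grep("^# reads ", hdr, value = TRUE)[1]
  nums <- regmatches(rstat, gregexpr("[0-9]+", rstat))[[1]]
  stats <- stats::setNames(as.integer(nums[1:5]),
                           c("total", "mapped", "unmapped", "ambiguous",
                             "nonJunction"))
  new("InsertionProfile", counts = mat, targetName = meta("target"),
      variant = meta("variant"), roundLabel = meta("round"),
      tsdLen = as.integer(meta("tsdLen", "5")), readStats = stats)
}
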