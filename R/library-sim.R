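# Synthetic sequencing: sample an insertion library, build amplicons,
# shear to MiSeq-sized fragments and emit error-bearing FASTQ reads.

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL leaves the caller's RNG stream untouched.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Sample a library of insertion events
#'
#' Draws `nClones` independent transposition outcomes: positions from
#' `positionWeights` (uniform over `[0, L - d]` by default) and orientation
#' from a Bernoulli with probability `reverseFraction` (Mu transposition
#' inserts in both orientations; default 0.5). One library carries a single
#' frame variant, mirroring the separately cloned and sequenced
#' LOV01/LOV02/LOV03 libraries.
#'
#' @param target A [TargetConstruct-class].
#' @param design An [InsertDesign-class].
#' @param nClones Number of clones to draw (>= 1).
#' @param variant Frame-variant name carried by this library.
#' @param positionWeights Optional numeric vector of weights over positions
#'   `0 ... L - d` (normalized internally).
#' @param reverseFraction Probability of a reverse-orientation insertion.
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return Data frame with columns `p`, `orientation`, `variant`.
#' @examples
#' lib <- sampleLibrary(gal4Vp64Target(), InsertDesign(), 100, seed = 1)
#' table(lib$orientation)
#' @export
sampleLibrary <- function(target, design, nClones, variant = "LOV02",
                          positionWeights = NULL, reverseFraction = 0.5,
                          seed = NULL) {
  stopifnot(nClones >= 1, reverseFraction >= 0, reverseFraction <= 1)
  L <- length(target@cds)
  d <- design@tsdLen
  pos <- 0:(L - d)
  if (is.null(positionWeights)) {
    positionWeights <- rep(1, length(pos))
  } else {
    if (length(positionWeights) != length(pos))
      stop("positionWeights must have one weight per position 0..", L - d)
    if (all(positionWeights == 0)) stop("empty position distribution")
  }
  .getVariant(design, variant)  # validate
  .withSeed(seed, {
    p <- sample(pos, nClones, replace = TRUE,
                prob = positionWeights / sum(positionWeights))
    rev <- stats::runif(nClones) < reverseFraction
    data.frame(p = p,
               orientation = ifelse(rev, "reverse", "forward"),
               variant = variant)
  })
}

#' Build the sequencing amplicon for one insertion event
#'
#' The amplicon is the PCR product spanning the fusion: upstream flank +
#' fusion CDS + downstream flank.
#'
#' @inheritParams buildInsertionCds
#' @return A [Biostrings::DNAString].
#' @examples
#' tgt <- gal4Vp64Target()
#' length(buildAmplicon(tgt, InsertionEvent(65), InsertDesign()))
#' @export
buildAmplicon <- function(target, event, design) {
  fusion <- buildInsertionCds(target, event, design)
  Biostrings::DNAString(paste0(
    as.character(target@upstreamFlank), as.character(fusion),
    as.character(target@downstreamFlank)))
}

# Amplicon pool for a multiset of events: unique events -> one amplicon
# each, weighted by multiplicity (times optional per-event weights).
.ampliconPool <- function(target, design, events, weights = NULL) {
  key <- paste0("p", events$p, "_",
                substr(events$orientation, 1, 3), "_", events$variant)
  if (is.null(weights)) weights <- rep(1, nrow(events))
  w <- tapply(weights, key, sum)
  uniq <- events[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  seqs <- vapply(seq_len(nrow(uniq)), function(i) {
    as.character(buildAmplicon(
      target,
      InsertionEvent(uniq$p[i], uniq$orientation[i], uniq$variant[i]),
      design))
  }, character(1))
  amp <- Biostrings::DNAStringSet(seqs)
  names(amp) <- ukey
  list(amplicons = amp, weights = as.numeric(w[ukey]))
}

#' Shear amplicons and emit error-bearing reads
#'
#' Emulates Covaris shearing to 300-400 bp fragments followed by
#' single-end MiSeq sequencing: each read draws an amplicon (by weight), a
#' fragment with uniform start and length uniform in `fragmentLenRange`, a
#' uniformly chosen end/strand, truncation to `readLen`, and i.i.d.
#' substitution errors at `perBaseError`. Qualities are the constant Phred
#' encoding of the error rate. Read names encode provenance
#' (`<amplicon>|frag:<start>-<end>|strand:<+/->|read:<i>`) so zero-noise
#' round-trips can recover the truth.
#'
#' Attempts whose fragment length exceeds the chosen amplicon are skipped
#' with a warning, so the emitted read count is `nReads` minus skips.
#'
#' @param amplicons Named [Biostrings::DNAStringSet] (names carry event
#'   provenance).
#' @param nReads Number of read attempts.
#' @param weights Sampling weight per amplicon (default equal).
#' @param fragmentLenRange Integer pair, fragment length bounds (default
#'   `c(300, 400)`).
#' @param readLen Read length in nt (default 300).
#' @param perBaseError Substitution probability per base (default 0.001).
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   FASTQ output.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @examples
#' tgt <- gal4Vp64Target()
#' amp <- Biostrings::DNAStringSet(setNames(
#'   as.character(buildAmplicon(tgt, InsertionEvent(65), InsertDesign())),
#'   "p65_for_LOV02"))
#' reads <- shearAndRead(amp, nReads = 10, seed = 1)
#' @export
shearAndRead <- function(amplicons, nReads, weights = NULL,
                         fragmentLenRange = c(300L, 400L), readLen = 300L,
                         perBaseError = 0.001, seed = NULL) {
  stopifnot(length(amplicons) > 0, nReads >= 1,
            perBaseError >= 0, perBaseError <= 1,
            fragmentLenRange[1] <= fragmentLenRange[2])
  if (is.null(weights)) weights <- rep(1, length(amplicons))
  ampChar <- as.character(amplicons)
  ampLen <- nchar(ampChar)
  .withSeed(seed, {
    idx <- sample.int(length(amplicons), nReads, replace = TRUE,
                      prob = weights / sum(weights))
    fl <- sample(fragmentLenRange[1]:fragmentLenRange[2], nReads,
                 replace = TRUE)
    keep <- fl <= ampLen[idx]
    nskip <- sum(!keep)
    if (nskip > 0)
      warning(nskip, " fragment draw(s) exceeded the amplicon length; skipped")
    idx <- idx[keep]; fl <- fl[keep]
    n <- length(idx)
    if (n == 0L) stop("all fragment draws were skipped; shorten the fragment range")
    start <- floor(stats::runif(n) * (ampLen[idx] - fl + 1)) + 1L
    minus <- stats::runif(n) < 0.5
    frags <- substr(ampChar[idx], start, start + fl - 1L)
    frags[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(frags[minus])))
    reads <- substr(frags, 1L, readLen)
    if (perBaseError > 0) reads <- .addSubstitutions(reads, perBaseError)
    nm <- sprintf("%s|frag:%d-%d|strand:%s|read:%d",
                  names(amplicons)[idx], start, start + fl - 1L,
                  ifelse(minus, "-", "+"), seq_len(n))
    qchar <- rawToChar(as.raw(33L + .phredFromError(perBaseError)))
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- nm
    quals <- Biostrings::PhredQuality(
      vapply(nchar(reads), function(w) strrep(qchar, w), character(1)))
    names(quals) <- nm
    Biostrings::QualityScaledDNAStringSet(dna, quals)
  })
}

.phredFromError <- function(e) {
  as.integer(min(40L, round(-10 * log10(max(e, 1e-4)))))
}

# i.i.d. substitutions; each errored base is replaced by one of the three
# other bases uniformly.
.addSubstitutions <- function(reads, rate) {
  nc <- nchar(reads)
  tot <- sum(nc)
  nerr <- stats::rbinom(1L, tot, rate)
  if (nerr == 0L) return(reads)
  at <- sort(sample.int(tot, nerr))
  ends <- cumsum(nc)
  ri <- findInterval(at - 1L, ends) + 1L
  pos <- at - c(0L, ends)[ri]
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(at)) {
    cur <- substr(reads[ri[j]], pos[j], pos[j])
    substr(reads[ri[j]], pos[j], pos[j]) <-
      sample(setdiff(bases, cur), 1L)
  }
  reads
}

#' Write reads to a FASTQ file
#'
#' Four-line records, Phred+33 qualities.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (from
#'   [shearAndRead()]) or [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  if (is(reads, "QualityScaledDNAStringSet")) {
    Biostrings::writeQualityScaledXStringSet(reads, path)
  } else {
    Biostrings::writeXStringSet(reads, path, format = "fastq")
  }
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ file path (gzip allowed).
#' @return A [Biostrings::DNAStringSet] with read names.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': truncated at record ",
         length(lines) %/% 4L + 1L)
  rec <- seq_len(length(lines) / 4L)
  bad <- which(!startsWith(lines[4L * rec - 3L], "@") |
                 !startsWith(lines[4L * rec - 1L], "+") |
                 nchar(lines[4L * rec - 2L]) != nchar(lines[4L * rec]))
  if (length(bad))
    stop("malformed FASTQ in '", path, "': record ", bad[1])
  tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e)
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e)))
}

#' Parse provenance from simulated read names
#'
#' Inverts the naming scheme of [shearAndRead()] to recover the true
#' insertion position, orientation and variant of each read's source
#' amplicon (used for round-trip testing).
#'
#' @param names Character vector of read names.
#' @return Data frame with columns `p`, `orientation`, `variant`,
#'   `fragStart`, `fragEnd`, `strand`.
#' @export
parseReadProvenance <- function(names) {
  m <- regmatches(names, regexec(
    "^p(\\d+)_(for|rev)_([^|]+)\\|frag:(\\d+)-(\\d+)\\|strand:([+-])", names))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable read name(s), e.g.: ", names[which(bad)[1]])
  g <- do.call(rbind, m)
  data.frame(
    p = as.integer(g[, 2]),
    orientation = ifelse(g[, 3] == "for", "forward", "reverse"),
    variant = g[, 4],
    fragStart = as.integer(g[, 5]),
    fragEnd = as.integer(g[, 6]),
    strand = g[, 7])
}
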