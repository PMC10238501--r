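# Built-in protein sequences and a fixed-codon back-translation used to
# generate the packaged coding sequences in code (no binary fixtures).

# Gal4 DNA-binding domain + linker region, residues 1-147 (UniProt P04386).
.GAL4_1_147 <- paste0(
  "MKLLSSIEQACDICRLKKLKCSKEKPKCAKCLKNNWECRYSPKTKRSPLT",
  "RAHLTEVESRLERLEQLFLLIFPREDLDMILKMDSLQDIKALLTGLFVQD",
  "NVNKDAVTDRLASVETDMPLTLRQHRISATSSSEESSNKGQRQLTVS"
)

# Tetrameric VP16-derived activation domain (4x DALDDFDLDML, GS-linked).
.VP64 <- paste0(
  "DALDDFDLDML", "GS", "DALDDFDLDML", "GS",
  "DALDDFDLDML", "GS", "DALDDFDLDML"
)

# AsLOV2, Avena sativa phototropin 1 residues 408-543 (136 aa; the
# screen's shortened insert, trimmed from the canonical 404-546 domain).
.ASLOV2_408_543 <- paste0(
  "LERIEKNFVITDPRLPDNPIIFASDSFLQLTEYSREEILGRNCRFLQGPE",
  "TDRATVRKIRDAIDNQTEVTVQLINYTKSGKKFWNLFHLQPMRDQKGDVQ",
  "YFIGVQLDGTEHVRDAAEREGVMLIKKTAENIDEAA"
)

# One fixed codon per amino acid (human-preferred); deterministic so that
# all packaged sequences are reproducible synthetic back-translations.
.CODON <- c(
  A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG", `*` = "TAA"
)

#' Back-translate a protein with a fixed codon table
#'
#' Deterministic back-translation using one (human-preferred) codon per
#' amino acid. Used to generate the packaged synthetic coding sequences for
#' Gal4-VP64 and AsLOV2; codon choice is arbitrary and does not affect any
#' frame arithmetic, which depends only on sequence lengths and the encoded
#' protein.
#'
#' @param protein Amino-acid sequence (character or [Biostrings::AAString]).
#' @return A [Biostrings::DNAString] of length `3 * nchar(protein)`.
#' @examples
#' backTranslate("MK")
#' @export
backTranslate <- function(protein) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  bad <- setdiff(aa, names(.CODON))
  if (length(bad))
    stop("no codon for residue(s): ", paste(unique(bad), collapse = ", "))
  Biostrings::DNAString(paste(.CODON[aa], collapse = ""))
}

#' The AsLOV2 domain coding sequence used for insertion
#'
#' Synthetic back-translation of residues 408-543 of *Avena sativa*
#' phototropin 1 (136 aa, 408 nt) -- the shortened AsLOV2 photoswitch used
#' as the inserted domain.
#'
#' @return A 408-nt [Biostrings::DNAString].
#' @examples
#' length(asLOV2Domain())
#' @export
asLOV2Domain <- function() backTranslate(.ASLOV2_408_543)

#' The packaged Gal4(1-147)-VP64 target construct
#'
#' The model target of the screen: residues 1-147 of the Gal4 DNA-binding
#' domain fused to the VP64 activation domain. The coding sequence is a
#' synthetic back-translation of the canonical protein sequence; the
#' protein-level facts used throughout (Ser22/Lys23 at the hit junction,
#' the zinc-finger cysteines) are codon-independent.
#'
#' @param upstreamFlank,downstreamFlank Optional plasmid flanks included in
#'   simulated amplicons (character; default 60 nt of fixed synthetic
#'   vector context on each side).
#' @return A [TargetConstruct-class].
#' @examples
#' gal4Vp64Target()
#' @export
gal4Vp64Target <- function(
    upstreamFlank = .defaultFlank("up"),
    downstreamFlank = .defaultFlank("down")) {
  TargetConstruct(
    name = "Gal4(1-147)-VP64",
    cds = backTranslate(paste0(.GAL4_1_147, .VP64)),
    upstreamFlank = upstreamFlank,
    downstreamFlank = downstreamFlank
  )
}

# Fixed synthetic vector context so amplicon reads can start outside the CDS.
.defaultFlank <- function(which) {
  if (which == "up")
    "GCTAGCGTTTAAACTTAAGCTTGGTACCGAGCTCGGATCCACTAGTCCAGTGTGGTGGAA"
  else
    "TCTAGAGGGCCCGTTTAAACCCGCTGATCAGCCTCGACTGTGCCTTCTAGTTGCCAGCCA"
}
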