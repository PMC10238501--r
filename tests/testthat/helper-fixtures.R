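# Shared fixtures, all generated in code.

# small stop-free CDS with distinct codons, for fast construct tests
smallTarget <- function(L = 60L) {
  codons <- c("ATG", "GCC", "GAA", "CTG", "AAG", "GAC", "TTC", "CAT",
              "ATC", "GTG", "AAC", "CAG", "CGT", "ACC", "TGG", "TAC",
              "CCA", "AGT", "GGA", "CTT")
  TargetConstruct("small",
                  paste(rep(codons, length.out = L / 3L), collapse = ""))
}

# 441-nt CDS used by the length-formula examples
target441 <- function() {
  t <- toyTarget(L = 441L, flank = 0L)
  TargetConstruct("t441", as.character(cdsSeq(t)))
}

defaultDesign <- function() InsertDesign()

# draw a sparse truth profile and the matching error-bearing read pool
simulatePool <- function(target, design, nPos = 20L, nReads = 2000L,
                         perBaseError = 0, seed = 1L,
                         orientation = c("forward", "reverse")) {
  L <- length(cdsSeq(target))
  d <- design@tsdLen
  set.seed(seed)
  p <- sort(sample(0:(L - d), nPos))
  ev <- data.frame(p = p,
                   orientation = sample(orientation, nPos, replace = TRUE),
                   variant = "LOV02")
  pool <- dipscreen:::.ampliconPool(target, design, ev)
  reads <- shearAndRead(pool$amplicons, nReads = nReads,
                        weights = pool$weights,
                        perBaseError = perBaseError, seed = seed + 1L)
  list(events = ev, reads = reads)
}
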