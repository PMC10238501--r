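# End-to-end orchestration: simulate library -> screen -> reads -> map ->
# statistics, with a machine-readable run manifest.

#' Built-in demonstration targets
#'
#' `toyTarget()` is a deterministic 600-nt toy CDS (plus 40-nt flanks)
#' used by examples and the bundled demo configuration; it is generated in
#' code, stop-free, and non-repetitive at k = 20.
#'
#' @param L CDS length in nt (multiple of 3).
#' @param flank Flank length in nt.
#' @return A [TargetConstruct-class].
#' @export
toyTarget <- function(L = 600L, flank = 40L) {
  stopifnot(L %% 3L == 0L)
  # linear-congruential stream so the toy sequence is seed-independent
  x <- numeric(L + 2L * flank)
  s <- 104729
  for (i in seq_along(x)) {
    s <- (s * 16807) %% 2147483647
    x[i] <- s %% 4L
  }
  base <- c("A", "C", "G", "T")[x + 1L]
  cds <- base[(flank + 1L):(flank + L)]
  # stop-free: recode the middle base of any in-frame stop codon to C
  for (i in seq(1L, L - 2L, by = 3L)) {
    cod <- paste(cds[i:(i + 2L)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) cds[i + 1L] <- "C"
  }
  up <- if (flank > 0L) paste(base[seq_len(flank)], collapse = "") else ""
  down <- if (flank > 0L)
    paste(base[(flank + L + 1L):length(base)], collapse = "") else ""
  TargetConstruct("toy600", paste(cds, collapse = ""), up, down)
}

#' Demonstration pipeline configuration
#'
#' A small end-to-end configuration on the toy target: one LOV02 library,
#' the default dark-high / light-low x3 gate schedule, and read pools
#' sized to finish in seconds.
#'
#' @return A named list accepted by [runEndToEnd()].
#' @export
demoPipelineConfig <- function() {
  list(
    target = "toy600",
    variant = "LOV02",
    tsdLen = 5,
    nClones = 400,
    reverseFraction = 0.5,
    photoswitchSite = 120,
    nPopulation = 20000,
    nSorted = 10000,
    gateQuantile = 0.5,
    nRounds = 2,
    nReads = 2000,
    fragmentLenRange = c(300, 400),
    readLen = 300,
    perBaseError = 0.001,
    seed = 1
  )
}

.configDefaults <- function(config) {
  def <- demoPipelineConfig()
  for (nm in names(def))
    if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
  config
}

.resolveTarget <- function(config) {
  if (!is.null(config$targetFasta)) {
    if (!file.exists(config$targetFasta))
      stop("target FASTA not found: ", config$targetFasta)
    seqs <- Biostrings::readDNAStringSet(config$targetFasta)
    return(TargetConstruct(names(seqs)[1], as.character(seqs[[1]])))
  }
  switch(as.character(config$target),
         toy600 = toyTarget(),
         gal4_vp64 = gal4Vp64Target(),
         stop("unknown built-in target: ", config$target))
}

.resolveDesign <- function(config) {
  dom <- if (!is.null(config$domainFasta)) {
    if (!file.exists(config$domainFasta))
      stop("domain FASTA not found: ", config$domainFasta)
    as.character(Biostrings::readDNAStringSet(config$domainFasta)[[1]])
  } else asLOV2Domain()
  InsertDesign(domainSeq = dom, tsdLen = config$tsdLen)
}

# Phenotype assignment mirroring the screen's biology: reverse or
# out-of-frame insertions are dead; in-frame insertions are constitutive
# except the photoswitchable member, the sampled functional insertion
# nearest to the configured site (the screen can only recover variants the
# library actually contains).
.eventPhenotypes <- function(events, target, design, photoswitchSite,
                             levels = c(dead = 1, full = 1000,
                                        photoLight = 1)) {
  rep_ <- constructReport(target, design, events[!duplicated(
    paste(events$p, events$orientation, events$variant)), , drop = FALSE])
  key <- paste0("p", rep_$p, "_", substr(rep_$orientation, 1, 3), "_",
                rep_$variant)
  mult <- table(paste0("p", events$p, "_",
                       substr(events$orientation, 1, 3), "_",
                       events$variant))
  funP <- rep_$p[rep_$functional]
  if (!length(funP))
    stop("library contains no functional in-frame insertion")
  pPhoto <- funP[which.min(abs(funP - photoswitchSite))]
  isPhoto <- rep_$functional & rep_$p == pPhoto
  dark <- ifelse(rep_$functional, levels[["full"]], levels[["dead"]])
  light <- ifelse(isPhoto, levels[["photoLight"]], dark)
  phenotypeTable(key, dark, light,
                 frequency = as.numeric(mult[key]))
}

#' Run the full simulate-screen-sequence-map-summarize pipeline
#'
#' Samples an insertion library, assigns phenotypes (in-frame insertions
#' are active, one configurable site is photoswitchable, everything else
#' is dead), simulates the FACS selection rounds, generates a sheared read
#' pool per round weighted by the round's variant frequencies, maps every
#' pool back into insertion profiles, and writes coverage, enrichment and
#' hit-cluster tables plus a JSON run manifest. Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config Named list (see [demoPipelineConfig()] for the keys and
#'   defaults) or path to a YAML file with the same fields.
#' @param outDir Output directory (created if missing).
#' @return `outDir`, invisibly; outputs are `library.tsv`,
#'   `trajectory.tsv`, `round<i>.fastq`, `profile_round<i>.tsv`,
#'   `coverage.tsv`, `enrichment.tsv`, `clusters.tsv`, `manifest.json`.
#' @examples
#' \donttest{
#' dir <- runEndToEnd(demoPipelineConfig(), tempfile("demo"))
#' list.files(dir)
#' }
#' @export
runEndToEnd <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config <- .configDefaults(config)
  seed <- as.integer(config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  target <- .resolveTarget(config)
  design <- .resolveDesign(config)

  # stage seeds derived from the single global seed (32-bit safe)
  sseed <- function(i) (as.numeric(seed) * 1000 + i) %% 2147483647

  events <- sampleLibrary(target, design, config$nClones,
                          variant = config$variant,
                          reverseFraction = config$reverseFraction,
                          seed = sseed(1L))
  utils::write.table(events, file.path(outDir, "library.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  phen <- .eventPhenotypes(events, target, design, config$photoswitchSite)
  gates <- defaultGateSchedule(quantile = config$gateQuantile,
                               nLightRounds = config$nRounds - 1L)
  traj <- runScreen(phen, gates, nPopulation = config$nPopulation,
                    nSorted = config$nSorted, seed = sseed(2L))
  freqs <- trajectoryFrequencies(traj)
  utils::write.table(
    data.frame(state = rownames(freqs), freqs, check.names = FALSE),
    file.path(outDir, "trajectory.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # per-round read pools weighted by the trajectory, mapped back
  uniqEvents <- .eventsFromKeys(colnames(freqs))
  pool <- .ampliconPool(target, design, uniqEvents)
  profiles <- list()
  for (ri in seq_len(nrow(freqs))) {
    state <- rownames(freqs)[ri]
    w <- freqs[ri, names(pool$amplicons)]
    keep <- w > 0
    reads <- shearAndRead(pool$amplicons[keep], config$nReads,
                          weights = w[keep],
                          fragmentLenRange = config$fragmentLenRange,
                          readLen = config$readLen,
                          perBaseError = config$perBaseError,
                          seed = sseed(10L + ri))
    fq <- file.path(outDir, paste0(state, ".fastq"))
    writeFastq(reads, fq)
    prof <- buildProfile(fq, target, design, variant = config$variant,
                         roundLabel = state)
    writeProfile(prof, file.path(outDir,
                                 paste0("profile_", state, ".tsv")))
    profiles[[state]] <- prof
  }

  cov <- data.frame(
    state = names(profiles),
    coverage = vapply(profiles, coverageFraction, numeric(1)),
    mapped = vapply(profiles, function(p) profileStats(p)[["mapped"]],
                    integer(1)))
  utils::write.table(cov, file.path(outDir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  enr <- enrichment(profiles[[1L]], profiles[[length(profiles)]])
  utils::write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  finalProf <- profiles[[length(profiles)]]
  rep_ <- constructReport(target, design, uniqEvents)
  cts <- profileCounts(finalProf)[, "forward"]
  called <- which(cts > 0) - 1L
  sites <- vapply(called, function(p) {
    row <- rep_[rep_$p == p & rep_$orientation == "forward", , drop = FALSE]
    if (nrow(row) && !is.na(row$aa_site[1])) row$aa_site[1] else NA_integer_
  }, integer(1))
  ok <- !is.na(sites)
  cl <- clusterHits(sites[ok], cts[called[ok] + 1L])
  utils::write.table(cl[, c("cluster", "n_sites", "top_site",
                            "total_count")],
                     file.path(outDir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "dipscreen",
    version = as.character(utils::packageVersion("dipscreen")),
    seed = seed,
    config = config[order(names(config))],
    target = list(name = target@name, L = length(target@cds)),
    outputs = sort(setdiff(list.files(outDir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

.eventsFromKeys <- function(keys) {
  m <- regmatches(keys, regexec("^p(\\d+)_(for|rev)_(.+)$", keys))
  data.frame(
    p = as.integer(vapply(m, `[`, character(1), 2)),
    orientation = ifelse(vapply(m, `[`, character(1), 3) == "for",
                         "forward", "reverse"),
    variant = vapply(m, `[`, character(1), 4))
}
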