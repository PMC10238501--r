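---
title: "Models and methods: simulating and analysing AsLOV2 domain-insertion screens"
author: "dipscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing AsLOV2 domain-insertion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipscreen)
```

# The problem

Domain-insertion profiling (DIP-seq) builds optogenetic protein variants by
inserting a photoswitchable domain — here AsLOV2, the light–oxygen–voltage
domain of *Avena sativa* phototropin 1 — at essentially every nucleotide
position of a target coding sequence, expressing one library member per
mammalian cell, and enriching photoswitchable variants by iterated
dark/light FACS selection. `dipscreen` implements the computational core of
such a screen end to end: the construct arithmetic of transposon-mediated
insertion, a synthetic sequencing-read generator, a junction-read mapper, a
stochastic selection simulator, library coverage and enrichment statistics,
and a one-site binding-model fitter for the downstream fluorescence
anisotropy characterization of hits.

The model target shipped with the package is the Gal4(1-147)-VP64
transcription factor: the Gal4 Zn~2~Cys~6~ DNA-binding domain fused to a
tetrameric VP16-derived activator. Its coding sequence is a *synthetic
back-translation* of the canonical protein sequence with one fixed codon
per residue (`backTranslate()`): the published screen's plasmid codons are
not public, and nothing in the package depends on codon identity — frame
arithmetic depends only on lengths, and amino-acid site naming depends only
on the encoded protein.

# Construct arithmetic

## Target-site duplication and frame variants

Mu transposition duplicates `d` target nucleotides at the insertion point
(`d = 5` for MuA; the duplication length is exposed as configuration
because the construction chemistry only fixes it through the choice of
transposase). An insertion at 0-based gap coordinate `p` (number of CDS
nucleotides 5′ of the insertion point) with insert cassette
`s5 + domain + s3` yields the fusion

```
cds[1..p+d] + s5 + domain + s3 + cds[p+1..L]
```

so the pentamer `cds[p+1..p+d]` flanks the insert on both sides. Because
the duplication can make several `p` values describe the same molecule, all
coordinates in the package are normalized to the *leftmost* consistent
position; the mapper applies the same normalization, which is what makes
simulation and mapping exact inverses of each other.

The domain is in frame with the upstream target iff
`(p + d + nchar(s5)) %% 3 == 0`, and the downstream target frame survives
iff the total inserted length `d + nchar(s5) + nchar(domain) + nchar(s3)`
is divisible by 3. The three shipped frame variants (LOV01: one extra base
5′; LOV02: two extra bases at each end; LOV03: one extra base 3′) all
satisfy the downstream condition, and with `d = 5` they claim residue
classes `p %% 3 == 0, 2, 1` respectively — a partition, so across the
three libraries every nucleotide position admits exactly one fully
in-frame insertion:

```{r partition}
head(enumerateInFramePositions(toyTarget(), InsertDesign()))
```

Scar *content* is configuration with an all-C default: no codon containing
a C is a stop codon, so the default scars can never themselves introduce a
linker stop; frame logic is independent of this choice.

## Naming hits by amino-acid site

A construct is labeled by the length of the longest common prefix of its
translation and the target protein (`assignAaSite()`), i.e. "after residue
`site`". Closed-form arithmetic would misname constructs because the
duplicated bases and scar codons can coincidentally extend (or truncate)
the conserved prefix; translation-prefix matching is exact by construction.
For the screen's predominant hit — AsLOV2 between Ser22 and Lys23 of Gal4 —
the LOV02 insertion whose duplicated pentamer covers Ser22's codon is
`p = 62`:

```{r sk22}
gal <- gal4Vp64Target()
ev <- InsertionEvent(62, variant = "LOV02")
classifyFrame(gal, ev, InsertDesign())$functional
assignAaSite(buildInsertionCds(gal, ev, InsertDesign()),
             proteinSeq(gal))
```

# Synthetic sequencing reads

`sampleLibrary()` draws insertion positions i.i.d. (uniform by default,
arbitrary weights allowed) and orientations as a Bernoulli draw — Mu
inserts in both orientations, so the default reverse fraction is 0.5;
antisense insertions are always non-functional. `shearAndRead()` emulates
the screen's readout: amplicons (plasmid flank + fusion CDS + flank) are
sheared to fragments uniform in 300–400 bp, one single-end read of up to
300 nt is taken from a uniformly chosen end, and substitutions are applied
i.i.d. at a configurable rate (default 0.001, a MiSeq-scale figure).
Indels, PCR/GC bias and duplicates are deliberately out of scope: the
mapper consumes junction structure, and none of the downstream statistics
read base qualities. Qualities are therefore constant (the Phred encoding
of the error rate). Read names carry full provenance
(`p65_for_LOV02|frag:211-542|strand:+|read:17`), which is what the
round-trip tests and the no-phantom checks key on. Everything is
deterministic given a seed, down to byte-identical FASTQ.

What the generator does *not* emulate of real data: quality-score decay
along the read, indels, chimeric fragments, unequal per-library depth, and
cross-contamination between frame-variant libraries. Tests passing on this
generator therefore certify the *logic* of mapping and enrichment, not
robustness to every MiSeq artifact.

# Junction mapping

The mapper is aligner-free by design: target CDSs in this setting are
0.6–1 kb, so an exact k-mer index (`indexTarget()`, default `k = 20`, both
strands) plus anchor search is both faster and easier to verify than a
general aligner. A read is screened (in both of its own orientations) for
the terminal 15 nt of the insert cassette and their reverse complements,
with up to one mismatch. Each anchor hit implies a junction side and
insert orientation; the target-derived flank adjacent to the insert is
then looked up exactly in the index, with a one-mismatch
`matchPattern` fallback. Left junctions give `p = offset + k - 1 - d`,
right junctions `p = offset - 1`; both are normalized to the leftmost
duplication-consistent position, so the two junctions of one insert always
agree. Reads are accounted into exactly one of four categories —
`mapped`, `ambiguous` (conflicting junctions or multi-locus flanks),
`unmapped` (junction seen, flank shorter than `k` or unmatchable), and
`nonJunction` — and the accounting identity is enforced by the
`InsertionProfile` validity method.

Numerical edge cases: insertions closer than `k` to a CDS end are callable
from one junction only; flanks of length zero are treated as no junction
(the read lies wholly inside the domain). There is no read deduplication —
shearing makes fragment starts near-unique — and frame-variant identity is
per-library configuration, as the libraries are sequenced separately.

# Selection-screen model

Single-cell reporter expression is an autofluorescence floor (10 AU) plus
a log-normal with the phenotype's condition mean and a CV of 0.6 — a
deliberately simple stand-in for flow histograms, for which no parametric
form is available. The canonical library mixture
(`screenLibraryPhenotypes()`) has four classes matching the initial
library's histogram: dead (background GFP; out-of-frame or disruptive
insertions), constitutive (full GFP both conditions), truncation-like
(intermediate GFP; insertions sparing some VP16 repeats), and
photoswitchable (full GFP dark, background under light — the class of the
winning SK22 variant, which is >150-fold switchable, i.e. indistinguishable
from background when lit).

A sorting round assigns cells multinomially to variants, draws expression
under the gate's illumination condition, keeps cells passing the gate,
and subsamples without replacement to the sort size (default 100,000, the
screen's figure). Regrowth between rounds is neutral multinomial
resampling — no variant fitness differences.

**Gate defaults.** The default schedule is one dark round keeping
GFP-positive cells followed by three light keep-low rounds. The dark gate
is an *absolute* threshold at 3× the autofluorescence floor rather than a
population quantile: when >90 % of the initial library is GFP-negative, a
population-median gate falls inside the dead peak and removes only half of
it, which cannot represent "recovering the GFP-positive population" — the
defining property of the first selection (a median dark gate leaves the
dead class at ~88 % frequency after round one; the absolute gate removes
it essentially completely, which is also what makes the photoswitchable
variant the reproducible top hit of the simulated screen). The light
rounds use population-quantile keep-low gates (default 0.5), matching the
screen's progressively refined relative gates; every gate is configurable
per round, including a pure quantile schedule.

# Coverage and enrichment statistics

* `coverageFraction()`: fraction of possible insertion positions with at
  least one mapped count (the screen's measured value for the integrated
  LOV02 library is 80.3 %). Both nucleotide-level and residue-level
  denominators are legitimate readings of "possible sites"; the function
  takes the denominator explicitly, with the nucleotide-level count
  (`L - d + 1`) as default.
* `unionCoverage(p, k) = 1 - (1 - p)^k`: the chance a site is covered in
  at least one of `k` independent libraries; at `p = 0.803, k = 3` this is
  0.9924, the ">99 %" union claim.
* `foldCoverage()` and `expectedFractionObserved(fold) = 1 - exp(-fold)`
  connect colony counts to expected coverage under Poisson sampling (the
  screen's colony counts correspond to ~190-fold coverage).
* `displayTransform()` is `log10(x + 1)`. Coverage tracks in this field
  are often annotated "log(x) + 1", which is ambiguous between
  `log10(x + 1)` and `log10(x) + 1` (the latter is undefined at zero
  counts); `log10(x + 1)` is the reading that accommodates zeros. The
  choice is display-only.
* `enrichment()` is per-position `log2((f_b + eps)/(f_a + eps))` on
  within-profile *frequencies* with `eps = pseudocount / nPositions`. The
  frequency-scale pseudocount makes the table exactly antisymmetric under
  profile swap and exactly invariant to sequencing depth — a count-scale
  pseudocount would be neither.
* `clusterHits()` is 1-D single-linkage with a residue gap (default 5):
  hit reporting aggregates forward in-frame insertions, and the screen's
  final library forms a single cluster {22, 23, 29} topped by site 22.

# One-site anisotropy fits

With a 2 nM labeled-DNA probe and dissociation constants near 6 nM, the
assay is in the ligand-depletion regime, so the default binding model is
the exact quadratic mass-balance solution

$$ b = \frac{(P + T + K_D) - \sqrt{(P + T + K_D)^2 - 4PT}}{2T}, \qquad
   r = r_\mathrm{free} + (r_\mathrm{bound} - r_\mathrm{free})\, b $$

with the hyperbola `P/(P + K_D)` available for comparison (the two agree
to <10⁻⁴ relative error once `T < K_D/10⁴`). Fitting is pooled nonlinear
least squares over replicates in `(log K_D, r_free, r_bound)` — the log
parameterization enforces positivity — with data-driven starts (endpoints
for the anisotropies, half-rise concentration for `K_D`) and
curvature-based standard errors; non-convergence or a boundary `K_D` is
flagged, never silently returned.

The titration simulator uses the assay's published protocol: probe 2 nM
and a doubling series from 6.2 nM continued until the bound fraction
exceeds 0.98 ("until saturated"). The simulated grid additionally includes
the probe-only `P = 0` baseline: a real titration always measures the free
probe before protein is added, and without that point `r_free` is poorly
identified because the first titrant concentration already sits near 50 %
saturation. Default anisotropies (`r_free = 0.10`, `r_bound = 0.25`) are
typical of a rhodamine-labeled ~27-bp duplex; noise is i.i.d. Gaussian
with sd 0.005, a realistic fluorimeter repeatability. At these settings
the fitter recovers a 6.4 nM ground truth with essentially no bias
(<5 %), and noiseless data is recovered to four significant figures.

```{r binding}
fit <- fitTitration(simulateTitration(6.4, seed = 1))
fit
```

# Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from code:
the toy 600-nt target, read pools of 2,000–2,500 reads, screens of
2×10⁵ cells per round over 1,071 variants across 100 seeds, and 200-seed
titration refits. These sizes were chosen so each property is measured
with comfortable statistical margin while the whole suite remains quick to
run; all are parameters, and scaling them up changes nothing but
tightness. Every stochastic function takes an explicit seed and restores
the caller's RNG state, so identical seeds give byte-identical outputs
(including FASTQ files and the pipeline's JSON manifest).

# Known limitations

* The screen simulator has no mCherry/BFP co-selection, no growth-rate or
  cell-cycle structure, and neutral regrowth; it reproduces selection
  logic, not culture dynamics.
* The mapper targets single-domain insertions in short CDSs; it is not a
  general aligner and emits no SAM/BAM.
* The read generator is substitution-only and single-end.
* Binding fits treat condition labels (dark/light) as metadata: photocycle
  kinetics during the measurement are out of scope, so slow-photocycle
  mutants are modeled only through their per-condition `K_D` values.
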