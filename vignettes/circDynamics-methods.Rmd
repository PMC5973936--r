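---
title: "circDynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circDynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

circDynamics is a desk-scale reimplementation of a circRNA
discovery-and-dynamics analysis for stranded total-RNA sequencing. The
experimental design it models is a 2 x 3 grid: two library types — an
RNase R-untreated Ribo-minus library (`rminus`) and an RNase R-treated
one (`rnaser`) — at three timepoints (`t0`, `t24`, `t48`) of a
differentiation time course. Circular RNAs are identified from
back-spliced junction reads (reads whose 5' part aligns downstream of
their 3' part, the head-to-tail signature of a circular template),
quantified by junction-read counts normalized to sequencing depth,
screened for dynamic regulation with a fold-change consensus rule, and
characterized genomically; candidate miRNA sponge interactions are
predicted from seed matches, a duplex pairing score and CLIP support.

Everything operates at toy-genome scale by design: the aligner, the
simulator and the oracles in the test suite are all built for genomes of
tens of kilobases to a few megabases, not for a human genome. Real-scale
alignment is explicitly out of scope; on real data one would substitute
a spliced aligner for the internal one and feed its junction evidence
into the same downstream machinery.

# Coordinates

All genomic coordinates inside the package are 0-based half-open
(`[start, end)`), the BED convention. A circRNA's `start` is the first
base of the circle and `end` is one past the last. GTF (1-based
inclusive) converts at the I/O boundary only. The GT-AG invariant for an
accepted circle on the plus strand is `genome[end, end+2) == "GT"`
(donor) and `genome[start-2, start) == "AG"` (acceptor); on the minus
strand the reverse-complement rule applies (`CT`/`AC` read on the
forward strand). The identity of a circRNA is the tuple
(contig, start, end, strand); the string id `circ_<contig>_<start>_<end>`
is derived for reporting and never parsed.

# The synthetic-data generator

`simConfig()` fixes the simulated study conditions; `buildToyGenome()`,
`chooseCircTemplates()`, `assignAbundances()` and `simulateReads()`
realize them. The defaults are the package's statement of "realistic at
desk scale":

* **Genome**: 20 multi-exon genes (4–8 exons of 120–300 bp, introns
  400–900 bp) on one ~100 kb contig, alternating strands, plus one
  multi-exon lncRNA and one single-exon antisense gene nested in an
  intron. Every intron carries canonical GT..AG flanks in transcript
  orientation, so both linear splice borders and the back-splice borders
  of exon-run circles satisfy the GT-AG rule by construction.
* **circRNAs**: 30 templates, each a contiguous run of interior exons of
  one transcript (terminal exons have no outer splice flank and cannot
  form a canonical circle). The exon-count distribution peaks at 2–3
  exons, the typical size of exon-derived circRNAs.
* **Abundance**: host-gene linear abundance is log-normal
  (meanlog `log(10)`, sdlog 1) and constant over time; circular
  abundance is `fraction x linear`. Three fraction models are available:
  `constant` (the splicing by-product null — the ratio does not depend
  on expression), `saturating` (the ratio falls with host expression,
  the observed alternative), and `independent`. Planted differential
  regulation multiplies circular abundance at t24 and t48 in both
  libraries; up effects are 2.5-fold and down effects 0.4-fold by
  default, clear of the 1.5 / 0.67 screen thresholds so planted truths
  are detectable.
* **RNase R** is modeled as independent Bernoulli survival per molecule:
  circular molecules survive with probability 0.9, linear with 0.05.
  This captures the enrichment logic (treated libraries are dominated by
  circles; linear flanking signal collapses ~20-fold) without modeling
  sequence-dependent exonucleolysis. Digestion efficiency in any real
  experiment is unknown; these are free parameters.
* **Sequencing depth**: by default every sample sequences exactly
  `depth_per_sample` pairs (`depth_model = "fixed"`), the equal-depth
  protocol of real library preparations; under it the treated library's
  surviving pool is renormalized, so circular junction counts are
  strongly enriched relative to the untreated library, as observed in
  real RNase R data. The alternative `"proportional"` model sequences
  treated samples at the untreated library's per-molecule rate (pairs
  scale with surviving material); it isolates the per-molecule survival
  picture — linear read counts drop by `1/p_survive_linear` (20-fold at
  the default) and circular junction counts by `p_survive_circ`. The
  survival-model validation uses both views: enrichment against the
  package's own expectation under the fixed model, and the linear
  flanking collapse under the proportional one.
* **Reads**: 2 x 125 bp paired-end, strand-specific with mate 1 on the
  transcript sense strand; fragment length truncated normal (250, 30)
  with lower bound the read length; fragments are sampled in proportion
  to molecule count x template length; circle fragments start uniformly
  on the circumference and wrap (rolling circle), so fragments can span
  the back-splice; 5% of linear molecules are sampled from unspliced
  pre-mRNA so exon–intron boundary reads exist; substitution errors at
  0.1%, no indels; 1e4 pairs per sample.

The generator is deterministic given `seed`: each stage derives its own
sub-seed, so identical configurations give byte-identical FASTA/GTF and
reads.

What the simulation does *not* emulate: quality-score error profiles,
PCR duplicates, GC bias, intron lariats, fusion transcripts, isoform
diversity (one transcript per gene), expression-dependent RNase R
escape, and repeat structure beyond what tests plant deliberately. Tests
passing on these simulations therefore validate the pipeline's logic and
calibration under its own generative assumptions — not performance on
real libraries.

Two count-level entry points complement the read-level path.
`simulateJunctionCounts()` draws Poisson junction counts around the
enumeration-based expectations of `expectedJunctionReads()`; it is the
generator's view for experiments that consume junction counts only.
`simulateScreenCounts()` uses it in spirit for screen-scale planted-DE
studies (500 circRNAs at junction coverage 10–50), where read-level
simulation would add nothing but volume: the screen never sees reads,
only junction counts and library depths.

# Detection

Reads are first aligned end-to-end to the genome and to the annotated
spliced transcripts by an internal seed-and-extend aligner: exact 20-mer
seeds at `max_mm + 1` evenly spaced offsets guarantee (pigeonhole) that
every placement with at most `max_mm = 2` mismatches is found.
`total_mapped_reads` counts mapped mates individually and is the
normalization denominator.

Unmapped reads enter the junction stage. The terminal 20-nt anchors of
the read (and of its reverse complement) are looked up exactly in the
genome; an anchor with more than one genomic locus sends the read to the
`repetitive` bin immediately — candidates from repetitive or homologous
regions are discarded, not rescued. A head-to-tail anchor pair implies a
circle span of `left_pos - right_pos + read_len - anchor_len`
independent of the breakpoint offset, so the `max_circ_len` ceiling
(100 kb) is checked before scoring. `resolveBreakpoint()` then extends
both anchors toward the read interior and enumerates breakpoint offsets;
an offset is admissible only when the genomic flanks read
`AG | circle | GT` (plus strand; mirrored on minus — GC-AG and other
non-canonical borders are never accepted). The unique best-scoring
admissible offset (total mismatches <= 2) is accepted; ties are
discarded as `ambiguous` rather than resolved left-most. The strand
implied by the flank rule is cross-checked against library strandedness
(mate 1 sense); conflicts are rejected.

A junction read's mate must be consistent with a circular template: it
maps inside `[start, end)` on the expected orientation (directly on the
genome, or via a transcript placement projected to genomic
coordinates), or it spans the same back-splice itself. Fragments, not
mates, are the unit of evidence: a pair in which both mates span the
junction counts once. Candidates are merged by coordinate tuple across
samples; a candidate is *detected* in a sample when it has at least 2
junction reads there, but the raw counts are retained for all samples.
Finally, a candidate whose 40-nt junction sequence occurs anywhere in
the genome as an exact match (either strand) is discarded — a genuine
back-splice sequence is absent from the linear genome.

Anchor length (20 nt), the mismatch allowance (2), and the span ceiling
(100 kb) are package decisions at toy-genome scale, exposed as
parameters.

# Quantification

* Circular abundance: junction reads / total mapped reads x 1e8.
* Linear abundance at a circle: the flanking-exon estimate. At the
  circle's first exon, fragments spanning the linear splice from the
  upstream neighboring exon into it, plus fragments crossing its
  upstream exon–intron boundary; symmetric counts at the last exon; the
  two per-flank totals are averaged. "Close to the junction" is
  operationalized as exactly the two boundary events adjacent to the
  circle's terminal exons — the minimal reading. Terminal-exon circles
  use the available flank only; circles whose breakpoints match no
  annotated exon border fall back to exon–intron counting and are
  flagged. The boundary-crossing overhang defaults to the detector's
  anchor length (20 nt) so that circular and linear fragment counts
  share the same effective crossing window; with matched windows the
  measured circ:linear ratio is directly comparable to the molecular
  proportion (the constant-fraction simulation recovers the planted
  fraction to within ~30%, dominated by the unspliced-read contribution
  and counting noise).
* Host-gene FPKM: exonic fragments / (exonic kb x mapped fragments in
  millions), with fragments overlapping several genes' exon models split
  1/n. Fragments (pairs), not mates, are the counting unit for all
  linear quantities; the normalization denominator for junction reads
  remains mapped mates, following the depth definition above.
* Ratios and fold changes use a symmetric pseudocount equal to one raw
  read normalized in the same sample. It is deliberately depth-aware:
  deeper libraries get a smaller pseudocount. Zero-denominator ratios
  without a pseudocount are returned as NA, never silently dropped.

The linear estimate is computed for every sample, but it is only
meaningful for the untreated library — RNase R destroys the linear
molecules the estimate measures — and all downstream linear fold changes
use `rminus` samples only.

# The screen

The high-confidence set requires detection (>= 2 junction reads) in
*both* library types at the *same* timepoint, for at least one of the
three timepoints — the timepoint binds to both experiments. Known/novel
annotation is an exact coordinate-tuple match against a user-supplied
catalog.

The differential rule is deterministic, with the literal constants: over
the four fold changes (rminus t24/t0, rminus t48/t0, rnaser t24/t0,
rnaser t48/t0), a circRNA is up when at least three values exceed 1.5
and any remaining value exceeds 1.0; down when at least three are below
0.67 and any remaining value is below 1.0. Values equal to a threshold
do not pass. An up call additionally needs >= 3 junction reads in the
24 h or 48 h sample of both libraries; a down call needs >= 3 junction
reads in both untreated (t0) samples; failing support demotes the call
to unchanged (the audit trail keeps the raw direction). Because 0.67 is
not exactly 1/1.5, fold-change vectors in the sliver (1.4925, 1.5]
classify asymmetrically under reciprocal inversion; the tests record
this edge explicitly. There are no p-values and no multiple-testing
correction — the screen is a rule, not a test, and the package preserves
that.

# Characterization

Genomic origin uses a fixed precedence: a circle whose breakpoints both
coincide with exon borders of a sense-strand protein-coding transcript
is CDS if any constituent exon overlaps the CDS span, else 5'UTR/3'UTR
by strand-aware position; otherwise lncRNA if contained in a sense
lncRNA's exons; otherwise antisense if overlapping any opposite-strand
gene; otherwise unannotated. CDS dominates UTR within exonic circles.
Exon counts and circRNAs-per-gene use the border-matched transcript;
circles matching no transcript are excluded and logged. For
ratio-vs-expression analyses each gene is represented by its most
expressed circle (summed rminus normalized expression; ties resolve to
the lexicographically smallest id). Host-linear relationship classes
partition (circle direction x linear direction): changed circle with
unchanged host = independent; same directions = concordant; opposite =
reciprocal; unchanged circle = both_unchanged. The linear direction uses
the two-timepoint analog of the circular rule (both FCs > 1.5 = up,
both < 0.67 = down) on rminus flanking counts with a one-fragment
pseudocount.

Cross-cell-type specificity compares circRNA sets re-detected from reads
trimmed to a common length (3' truncation, e.g. 125 to 80 nt) — the
comparison operates on re-detected calls, not on trimmed call lists —
and reports all Venn region cardinalities plus per-set specific
fractions. Trimming shortens the junction-crossing window, so trimmed
recall is never above full-length recall; the acceptance suite asserts
exactly that monotonicity.

# Sponge prediction

Circle sequences are the concatenated constituent exons in transcript
orientation. Seed matching scans the circularized sequence (first 7
bases appended) so back-splice-spanning sites are found once, at
positions modulo the circle length; classes are the canonical 6mer
(complement of miRNA 2–7), 7mer-m8 (2–8), 7mer-A1 (2–7 plus target A
opposite position 1) and 8mer, with the maximal class reported per site
start. Overlapping registers at different starts are distinct sites.

The pairing score is a deliberately simplified miRanda-like duplex
score, not a reimplementation of miRanda: best local alignment of the
miRNA (3' to 5') against the site plus 30 nt of upstream circular
context, with Watson–Crick +5, G:U wobble +1, mismatch −3, gap open −8
(first gapped base) and extension −2, computed by affine-gap (Gotoh)
dynamic programming with the seed (miRNA positions 2–8) forced
gap-free. Thermodynamic energies and conservation scores are out of
scope. A prediction is final only when all three evidence lines agree:
a 7mer-or-better seed site, a pairing score >= 80, and presence in the
CLIP support table. The thresholds are explicit configuration defaults,
not literature constants.

# Numerical and procedural choices

* Sub-seeds: every stochastic stage derives `(seed * 7919 + offset) mod
  (2^31 - 61)`, keeping all seeds in 32-bit integer range.
* Degenerate inputs: reads shorter than two anchors are skipped with a
  log record; empty BED catalogs annotate everything novel; an empty
  CLIP table warns and fails all `passes_clip`; correlation analyses
  refuse fewer than 10 gene pairs; NaN fold changes are errors.
* Tie-breaks are always deterministic and documented: ambiguous
  breakpoints are discarded; representative circles and best alignments
  order lexicographically.
* N bases: index k-mers containing N are never built, so anchors or
  junctions overlapping N cannot match and the reads fall into the
  ambiguous/no-anchor bins.
* Problem sizes in the shipped tests were chosen to make each claim
  measurable with margin at interactive runtimes: oracle equivalence on
  a <= 20 kb genome with error-free reads at 1e3 pairs/sample (exact
  seed matching and exact equality are only meaningful without
  sequencing errors; the error-tolerant behaviour is exercised by the
  recovery tests); default-condition recovery at the full 1e4
  pairs/sample grid; the RNase R study at 1.5e4 pairs/sample; the
  by-product correlation at 800 single-circle genes using count-level
  simulation at junction coverage far above the Poisson discreteness
  regime (counting zeros and ties otherwise distort the rank
  correlation of a null).

# Known limitations

* The aligner is exact-seeded and substitution-only; indels, soft
  clipping and quality-aware scoring are absent. This matches the
  simulator's error model, not real sequencers.
* The flanking-exon linear estimate depends on annotated exon borders;
  unannotated alternative borders degrade it to exon–intron counting.
* Internal circle structure (alternative splicing within circles) is
  not resolved; circles are distinct only by junction coordinates.
* The screen inherits the fold-change rule's discreteness: near-threshold
  regulation at shallow depth is classified unstably, which is faithful
  to the method rather than a defect of the implementation.
* The sponge module's pairing score is rank-useful but not calibrated to
  binding energy; its threshold (80) interacts with miRNA length.
* Nested or overlapping circles contaminate the flanking-exon linear
  estimate: internal splice-crossing fragments of a larger circle are
  indistinguishable from linear splice fragments at a smaller circle's
  flank. `circ_max_per_gene = 1` in the generator produces
  contamination-free designs for calibration studies.
* Representative-circle selection by maximal measured expression is a
  winner's curse at finite coverage: it inflates the selected ratio more
  for noisier (lower-expressed) hosts and thereby fakes a weak inverse
  ratio-vs-expression correlation even under the constant-fraction null.
  The package's null-calibration experiment therefore uses one circle
  per gene; on real data this bias should be kept in mind when reading
  the inverse-correlation argument.
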