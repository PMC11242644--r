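---
title: "Methods: repeat-mediated recombination analysis for multipartite mitogenomes"
author: "mitorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated recombination analysis for multipartite mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorec)
```

## The problem

Plant mitochondrial genomes are structurally dynamic. Large repeats
(especially those above ~1 kb) mediate homologous recombination, so a
"reference" assembly of one or two circles coexists in vivo with minor
alternative conformations: direct repeat pairs can split a circle into
two smaller circles (fission), inverted pairs can reverse the segment
between them (inversion). Long reads that span a repeat together with
enough unique flanking sequence on both sides are the only direct
evidence for which arrangements are present, and in what proportions.
The same genomes routinely carry stretches of chloroplast DNA (MTPTs),
microsatellites, and a small conserved set of protein-coding genes whose
codon usage and substitution rates carry evolutionary signal.

`mitorec` implements this analysis stack as composable, individually
tested operations: exact repeat detection on circles, repeat-family
decomposition, conformation enumeration, junction-spanning read support
with frequency estimation, plastid-transfer detection, SSR scanning,
RSCU/Ka-Ks/protein statistics, and a ground-truthed simulator that makes
every stage testable without any external data.

## Coordinates and sequence model

All internal coordinates are 0-based, half-open and strand-explicit;
GFF3 and GenBank 1-based inclusive coordinates are converted only at the
I/O boundary. A single convention everywhere prevents off-by-one drift
between stages that exchange intervals. Circular molecules interpret
positions modulo the length; an interval with `end <= start` crosses the
origin. IUPAC ambiguity codes other than N are normalized to N (with a
warning) because exact-repeat semantics need a fixed alphabet, and N is
defined to match nothing — including another N — so masked regions can
never seed repeats.

## Maximal exact repeats on circles

A maximal exact repeat pair is two equal (or reverse-complement-equal)
substrings that cannot be extended on either side. The detector seeds
candidate *diagonals* with shared k-mers (k = min(min_len, 31)) and then
scans each candidate diagonal of the doubled sequence for maximal match
runs; on one diagonal a run flanked by mismatches is exactly one maximal
pair. Inverted pairs are the same computation between the sequence and
its reverse complement. This gives well-defined, oracle-checkable
semantics; the test suite compares it against an exhaustive
all-diagonals enumeration on hundreds of random circles.

Choices that matter:

* Only exact repeats (identity 1) are reported. Mismatch-tolerant
  repeats are a different problem with tool-specific semantics.
* Tandem-like output is excluded: copies must be disjoint, and direct
  copies must not abut (those belong to a tandem-repeat finder).
* No cap is placed on the number of reported repeats; callers truncate
  if they want tool-compatible counts. Published counts obtained under
  a tool-side cap (e.g. a "maximum computed repeats" setting) are
  therefore not directly comparable.
* Degenerate periodic circles (a sequence equal to a rotation of
  itself) are skipped rather than reported as infinitely many pairs.

## Repeat families: core and extensions

Overlapping copies from different pairs are clustered into loci, loci
linked by pairs into families, and each family is summarized as a
*core* (the block contained in every copy) plus per-copy left/right
*extensions*. The core is computed by projecting every locus onto the
widest locus through the exact pair alignments; because the repeat
finder reports *all* maximal pairs, any two copies sharing the core are
directly paired, making the projection a single intersection. Copies
crossing the origin are not supported here — rotate the molecule first
(`seq_rotate()`); this keeps the interval arithmetic linear and is no
loss of generality on a circle. With three copies (the classic
left/core/right arrangement) the three pairwise maximal matches are
exactly the left+core, core+right and core blocks, and the decomposition
recovers the planted arm lengths in the tests.

## Conformation enumeration

Events are recombinations at repeat pairs of at least `min_len` bases
(default 1000, the size class empirically associated with frequent
recombination). The enumerator tracks each molecule as a circular
sequence of oriented *elementary segments* (the reference circle cut at
every event boundary). This representation makes two invariants
structural rather than aspirational: every reference base belongs to
exactly one segment occurrence (so total length is conserved by
construction), and repeat copies are never split (events cut only at
copy boundaries). The outcome of an event is decided by the orientation
the two copies actually have in the *current* molecule — fission if the
repeat sequences read in the same direction, inversion otherwise — so
composed events behave correctly after earlier inversions.

Inversion convention: the arc strictly between the two copies (from the
end of the lower-coordinate copy to the start of the higher one) is
reverse-complemented; both repeat copies are left untouched. Inverting
the complementary arc instead yields the same molecule up to rotation
and reflection, which the deduplication recognizes: conformations are
identified by a canonical signature that is invariant to rotation,
strand flip, and content-equal segments (segments equal up to reverse
complement share a token). Ids are content-derived, so enumeration order
never changes them. Enumeration is breadth-first up to `max_depth`
events with a configurable state budget; the depth is exposed rather
than fixed because how many successive recombinations are biologically
plausible is a question for the data, not the software.

Note on "base conservation": an inversion reverse-complements a segment
on the recorded strand, so the conserved quantity is the double-stranded
content — the A:T and G:C pair counts and the total length — not the
single-strand base multiset. The tests assert exactly that.

## Junction assays and the spanning-read rule

For a repeat of interest, every copy occurrence in every conformation is
extracted with 1 kb flanks (junction references of length repeat +
2 x flank). Junctions from the reference conformation are labeled `ref`,
all others `alt`; junction strings identical up to reverse complement
across the two labels cannot discriminate and are dropped. A read
supports a junction iff its alignment covers the *entire* repeat copy
and at least 100 bp of *both* flanks (defaults; both tunable). Partial
repeat coverage never counts, because only full-repeat-spanning reads
disambiguate conformations.

Two ingestion paths fill the counts:

* **Internal matcher** — exact k-mer anchors (k = 15) sampled at a
  stride along both read strands are matched to the junction k-mer
  index; anchors are clustered into diagonal bands (band 100 bp, which
  absorbs indel drift), the best band per read/junction supplies an
  anchor-count score, and the read extent projected along the band's
  median diagonal is used for the coverage rule. This replaces a banded
  semi-global alignment: at the error rates of corrected long reads the
  projection decides the 100 bp rule correctly with kilobase-scale
  margins, and it keeps the matcher fast and dependency-free. Boundary
  decisions within roughly the read's net indel drift (tens of bases)
  are approximate; reads that barely graze the rule can be missed,
  which costs sensitivity, not bias.
* **PAF alignments** from any long-read aligner targeting the junction
  FASTA; the same coverage rule is applied to the reported target span.

A read matching several junctions is assigned to the best score; exact
ties are discarded (they are uninformative by symmetry). Counts are
pooled over strands and junction copies into `ref` and `alt`, the
recombination frequency is `alt / (alt + ref)`, and the 95% interval is
Wilson's score interval — chosen over the Wald interval for its sane
behavior at 0 and 1 with small counts. Zero informative reads yield a
flagged undefined frequency, never 0/0 arithmetic.

## Synthetic data: what it emulates, and what it does not

The simulator is first-class, tested code, and its defaults are the
study conditions the rest of the package is validated under: two
circular molecules (~545 kb + ~167 kb) of i.i.d. background at 45.2%
GC; planted exact repeats, plain or with the three-copy left/core/right
family structure; plastid fragments copied from a donor circle, mutated
at a configurable per-base divergence (substitutions only) and inserted
at random positions away from planted features, growing the genome by
exactly the summed fragment lengths; long reads drawn from a mixture of
conformations with truncated-normal lengths (mean ~4.9 kb by default,
matching typical corrected nanopore runs), substitutions applied before
indels, constant placeholder qualities (no stage consumes qualities).
The default read error rates (1% substitutions, 0.2% indels) are a
modeling choice for *corrected* long reads; the upstream study does not
report a post-correction error rate.

A targeted variant, `simulate_spanning_reads()`, emits only informative
reads — conformation chosen by weight, then one of its repeat-copy
loci, then a start position guaranteeing coverage of the repeat plus
`min_flank_cov + margin` bases of both flanks (margin 50 bp, so indel
jitter cannot push a read below the tally rule). With equally many
junction loci per conformation, the expected alt fraction among
informative reads equals the mixture weight, which is what the
parameter-recovery study exploits; whole-genome simulation would spend
~99% of reads away from any junction.

Deliberately not emulated: realistic nanopore error profiles
(homopolymer bias), chimeric reads, nuclear background sequence, and
repeat-free background guarantees (planted ≥1 kb repeats make spurious
same-length competitors vanishingly unlikely; tests use the planted
truth, not uniqueness assumptions). Passing tests therefore demonstrate
correctness of the computations under a clean error model, not
robustness to every artifact of real sequencing runs.

## Plastid-transfer detection

Exact 15-mer seeds between mitochondrion and plastome (both strands)
are grouped by diagonal, chained along each diagonal with a 200 bp gap
bound, extended at both ends by an X-drop walk (+1 match, -2 mismatch,
drop 10) and reported with Hamming identity over the final span.
Mitochondrial intervals overlapping by at least half are merged.
Defaults: minimum length 80 bp (the conventional reporting threshold
for chloroplast insertions) and minimum identity 85%, spanning the
identity range typically observed for recent transfers with margin.
The scanner targets substitution-divergence; a large indel inside a
transferred fragment splits it into adjacent reported segments, so
fragment *counts* are not comparable across tools — the genome
*fraction* (interval union over genome length, reported as a percent to
one decimal) is the robust summary. The plastome's two inverted-repeat
copies can make the source interval ambiguous; the mitochondrial
interval, which drives the fraction, is unaffected.

## Codon statistics

RSCU follows the family-normalized definition: observed codon count
times family size over the family total, under the standard genetic
code (plant mitochondria use the universal code). The three stop codons
form one family, fed by the terminal codon of each CDS, so stop-usage
bias is reported like any other family; both stop inclusion and
plastid-derived gene inclusion are caller choices.

Ka/Ks implements the classical site-counting method: per-position
synonymous-site fractions averaged over both sequences; differences per
codon pair averaged over all minimal mutational pathways, excluding
pathways through stop codons (when every pathway is blocked, the
differing positions are classified independently by single-site swaps
and the pair is flagged); substitutions that create a stop codon count
as nonsynonymous in site counting. Proportions are corrected with the
one-parameter (Jukes-Cantor-style) formula d = -(3/4) ln(1 - (4/3) p),
undefined (flagged, not NaN) at p >= 3/4; the ratio is undefined when
Ks = 0. Codon pairs containing gaps, N, or a stop are skipped and
tallied. Alignment is the caller's job — codon-aware alignment is out
of scope. The whole computation is validated against an independent
recursive pathway-enumeration oracle over all sense-codon pairs.

Protein mass uses average residue masses plus one water; the
isoelectric point solves net charge = 0 by bisection with
Henderson-Hasselbalch terms for the termini and D/E/C/Y/H/K/R side
chains. The shipped pKa table is the EMBOSS default set; pI is
table-dependent, so the table is an argument — reproducing another
tool's pI to the second decimal generally requires that tool's table.

## Problem sizes and numerical choices

The validation suite runs at the scales the analyses are designed for:
the frequency study uses a 200 kb circle with one 5 kb direct repeat,
200 informative reads per replicate and 50 replicates per mixture
fraction (0.1/0.3/0.5/0.7); the transfer study plants 24 fragments
totaling 55 kb into a genome of 711,578 bp (7.7% planted fraction) and
rescans it from scratch; oracle comparisons use hundreds of random
sequences up to 5 kb. Fixed seeds drive every stochastic step; with a
fixed seed every emitted byte is reproducible. Mean-absolute-error and
interval-coverage targets (MAE < 0.05, Wilson coverage >= 90%) are what
a binomial estimator with n = 200 should achieve with room to spare
(sd ~ 0.035 at p = 0.5).

## Known limitations

* Repeat-family decomposition and conformation enumeration require
  non-origin-crossing copies (rotate first); the repeat *finder* itself
  is fully wrap-aware.
* The internal read matcher is approximate near the coverage boundary
  under indels and is tuned for corrected long reads; for raw,
  high-error reads map externally and feed PAF.
* Intermolecular recombination (between different chromosomes) and
  microhomology-mediated events are out of scope.
* The transfer scanner's per-fragment segmentation differs from
  whole-genome aligners; compare fractions, not counts.
* `nei_gojobori()` assumes its inputs are already codon-aligned.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  molecule_lengths = 200000L, gc = 0.452,
  repeats = list(list(length = 5000L, orientation = "direct",
                      positions = c(20000L, 129000L))),
  seed = 7L)
g <- generate_genome(cfg)
m1 <- g$molecules[[1]]

rp <- find_maximal_repeats(m1, min_len = 1000)
ev <- classify_events(m1, rp)
cset <- enumerate_conformations(m1, ev, max_depth = 1)
assay <- build_junctions(cset, "E1", flank = 1000, min_flank_cov = 100)

sim <- simulate_spanning_reads(cset, "E1", weights = c(0.5, 0.5),
                               n = 200,
                               read_model = list(mean = 7000, sd = 1500,
                                                 min = 500,
                                                 sub_rate = 0.01,
                                                 indel_rate = 0.002),
                               seed = 11)
estimate_frequency(tally_support(sim$reads, assay))
```
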