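---
title: "Designing and evaluating RNAi reagents with rnaidesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating RNAi reagents with rnaidesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaidesign)
```

## The design problem

An RNAi reagent — a long double-stranded RNA diced intracellularly into
siRNAs, or a single synthetic siRNA — should silence exactly one gene,
across all of that gene's splice isoforms, efficiently, and without
side effects attributable to its sequence. `rnaidesign` treats this as a
filtering and ranking problem over the set of all candidate 19-mers of a
target region. The pipeline is fully deterministic: identical inputs and
options produce byte-identical outputs, which the test suite asserts.

The stages, in order:

1. **Common regions.** The query unit is the set of maximal genomic
   intervals contained in the exonic footprint of every transcript of the
   gene, computed by interval intersection (never by sequence alignment —
   the design is annotation-driven and deterministic). Genes whose
   isoforms share no exonic base yield no query and are reported as
   failures. When only transcript sequences are available the package
   runs in a single-isoform mode where each transcript is its own region;
   multi-isoform genes then require exon coordinates.
2. **Splitting.** Common regions longer than 700 nt are split into two
   halves of equal length, once and not recursively; for odd lengths the
   left half takes the extra base. Splitting increases the number of
   independent target sites available per gene; halves longer than the
   threshold remain valid queries.
3. **Dicing.** All k-mer windows (k = 19 nt, offset 1 nt) of the query
   are enumerated. The guide strand is defined as the exact reverse
   complement of the sense window; guide positions are numbered 1-based
   5'→3'. Windows containing N are flagged and excluded from every
   downstream pass — draft assemblies contain N runs and should not crash
   a genome-scale run.
4. **Per-siRNA annotation** (specificity, low complexity, efficiency,
   seed features; details below).
5. **Optimal regions, redesign, primers, ranking.**

## Filters and scores

### Specificity

An exact-match k-mer index over the off-target database (typically the
whole transcriptome, sense strands) answers "which transcripts contain
this 19-mer". Both orientations of each siRNA are queried by default,
because a dsRNA loads guide strands from both of its strands; single-siRNA
design mode queries only the orientation that can base-pair with the
transcript. Matching is perfect-homology only — no mismatches, no G:U
wobble, no gapped alignment. An siRNA is *specific* when all hits fall in
isoforms of one gene; it is *unspecific* when two or more genes are hit;
`no_target` records the absence of any perfect match. The index is an
in-memory postings table keyed by k-mer (data.table); the test suite
checks it against an independent dictionary-matching oracle
(`Biostrings::vcountPDict`) on randomly generated transcriptomes.

### Low complexity

Two detectors mask query intervals:

* **CAN repeats** — maximal runs of at least 6 tandem CA[ACGT]
  trinucleotides, scanned in all three reading frames. Detection is
  applied to the sense strand of the query only; the reverse-strand
  equivalent ([ACGT]TG runs) is deliberately not searched, mirroring a
  filter defined on the target template. This is a documented,
  configurable choice (`can_min_units`), and one test asserts the
  strand-asymmetry on purpose.
* **DUST** — inside every sliding 64-nt window the statistic
  ∑ₜ cₜ(cₜ−1)/2 over triplet counts cₜ, normalized by (number of triplet
  words − 1), is compared against a cutoff of 28; all positions of
  windows exceeding the cutoff are merged into maximal masked intervals.
  Window 64 / word 3 / cutoff 28 are the conventional defaults of the
  classic filter program and are exposed in `design_options()`. Triplets
  containing N contribute nothing. Note the masked interval is the union
  of flagged windows, so it can extend a few bases beyond the repeat that
  triggered it; the fixture tests therefore assert containment for DUST
  (and exact intervals for CAN, which is frame-deterministic).

### Efficiency

Two scores are implemented, both normalized to 0–100 so that cutoffs are
comparable across methods:

* **Rational** — eight classical criteria (G+C within 30–52%; +1 per A/T
  at sense positions 15–19 when at least three of them are A/T; absence
  of internal repeats; A at 19; A at 3; T at 10; −1 for G/C at 19; −1 for
  G at 13). The raw score lies in [−2, 10] and is mapped affinely:
  normalized = (raw + 2)/12 × 100. The affine map (rather than clipping
  negatives) was chosen because it places the conventional raw cutoff of
  6 exactly at 66.7, reproducing the published cutoff on the normalized
  scale; this is the pinning constraint for the normalization.
* **Weighted** — a position×base weight table plus feature terms
  (GC-window, A/T count at 15–19, internal-repeat absence), summed and
  mapped affinely from [min_raw, max_raw] to [0, 100] (values outside the
  declared range are clamped; a table with min_raw = max_raw is
  rejected). The package ships a versioned default table
  (`inst/extdata/weight_table_v1.tsv`) constructed from the same family of
  published position preferences; the file format is documented so users
  can substitute any table verbatim, and all package tests use the
  shipped table. The default efficiency cutoff is 63 for this method.

The internal-repeat criterion is approximated by the longest internal
reverse-complement stem: a stem of ≥ 4 bp (a 4-mer whose reverse
complement occurs at a different position of the 19-mer) fails the
criterion. This is deterministic and dependency-free; a thermodynamic
(nearest-neighbour Tm) variant was considered and rejected for the
default because it adds parameters without changing desk-scale behaviour.
T is treated as U throughout: inputs are DNA, the rules are RNA rules.

By default the efficiency cutoff only drives the *efficient-siRNA count*
used in ranking; it is not an exclusion filter
(`efficiency_filter = FALSE`). Random-sequence siRNAs average well below
either cutoff, so filtering on efficiency by default would fragment most
queries and conflate "efficient" with "designable". Users running
efficiency-filtered designs (as genome-scale runs sometimes do) can
enable it in the options.

### Seed features

The guide seed is positions 2–8 of the guide strand (7-mer default; 2–7
as the 6-mer option). The **seed complement frequency** of a seed is the
number of occurrences — overlapping occurrences counted — of the seed's
reverse complement across a user-supplied database, e.g. annotated
3'UTRs: a proxy for the number of potential miRNA-like off-target sites.
Frequencies are computed once per unique seed and inherited by every
siRNA carrying the seed; a count below 1,000 sets the low-frequency flag.
Counting occurrences (not covered bases) is deliberate: the quantity is a
count of potential sites. The optional miRNA-seed filter excludes siRNAs
whose guide seed exactly equals a listed seed (from a one-column file or
a mature-miRNA FASTA, U→T).

## From filtered siRNAs to reagents

A failing siRNA masks its **full 19-nt span**, not just its start
position — masking only starts would leave amplicons that still contain
part of a failing window. Optimal regions are the maximal unmasked
intervals of at least the window minimum (default 80 nt); intervals
longer than the window maximum (default 250 nt) are kept whole, because
the primer product window enforces the length cap anyway.

When no optimal region reaches the window minimum and redesign is
enabled, the two optimal regions with the smallest intervening gap are
merged into one interval spanning both plus the gap; ties are broken
leftmost for determinism. Merging repeats until an interval reaches the
minimum or a single interval remains; if the total span cannot reach the
minimum the target fails with "insufficient optimal sequence". Each merge
strictly increases length, so at most (n−1) merges occur.

Primer design is handled by a self-contained engine: left/right primers
of 18–24 nt are anchored at every possible product start/end, scored by
deviation of their melting temperature from 60 °C (GC-content formula
Tm = 64.9 + 41·(nGC − 16.4)/len, adequate for 18–24-mers) plus a penalty
outside 35–65% GC; the pair penalty adds the two primer penalties and
the Tm difference. Pairs whose product lies within the window are
returned sorted by penalty. The engine is deliberately simple and fully
deterministic — a golden-pair test pins its output — and its settings
(window) come from the options; laboratories with house primer rules can
design primers externally on the emitted optimal regions.

Ranking is lexicographic and stable. dsRNAs: off-target siRNA count
ascending, then efficient-siRNA count descending, then mean efficiency
descending, then primer pair penalty ascending. The precedence of
efficient count over mean efficiency is a documented package choice (the
two are reported side by side and no ordering between them is canonical);
it is configurable by reordering externally since all metrics are
emitted. siRNA designs rank by specificity bit, then efficiency, then
seed complement frequency. Multiple designs per target are
non-overlapping by default, supporting independent-design confirmation
experiments; `allow_overlap` lifts this.

## Evaluation and comparison of existing libraries

Evaluation dices a reagent and classifies every siRNA against the index.
The **intended transcripts** are those with the most siRNA hits; ties
keep all tied transcripts, and the intended gene set is defined over
them (a reagent with several intended genes is flagged multi-intended).
An siRNA is off-target when it perfectly matches any gene outside the
intended set; total = on + off + no-target always holds. UTR/SNP overlap
is computed on the reagent's mapped footprint — the union of its perfect
19-mer hit intervals per intended transcript — so "no sequence overlap"
between two reagents is evaluated on transcript coordinates, not raw
strings. Absent feature tables yield `NA` fields (absent, not zero), and
an unmapped reagent yields zeros with an "unmapped" note. Homology
scanning delegates to BLAST+ (`blastn`, E < 1e-10, intended transcripts
excluded) and degrades to "not assessed" when the program is missing
rather than failing the run.

Pairwise comparison reports genes targeted by both libraries and, among
those, genes covered by *independent designs*: a gene counts when at
least one reagent pair (one per library) shares no mapped footprint
overlap at all. Coverage here means intended-gene assignment; off-target
counts are reported separately rather than disqualifying a reagent.

## The synthetic fixture generator

`generate_transcriptome()` emulates exactly the features the pipeline
must detect: genes with one or two splice isoforms (exon structure
A|B|C with the second isoform skipping B, so the common regions are A and
C), paralog pairs sharing a planted 19-mer (ground truth for specificity
0), planted CAN runs (with three-base guard flanks so the detected
interval equals the planted interval exactly), planted 64-nt homopolymer
runs (DUST), 5'UTR annotations, SNPs, and miRNA seeds taken from real
windows so seed matching has planted positives. Background sequence is
i.i.d. uniform over ACGT with rejection sampling against accidental CAN
runs and accidental 19-mer sharing across genes, which makes the manifest
exhaustive: any detection outside the manifest is a false positive, and
the tests assert zero misses and zero false positives.

What the generator does **not** emulate: realistic base composition or GC
skew, splice-site motifs, repeat families beyond CAN/homopolymers,
sequencing errors, and genuine paralogy (shared 19-mers stand in for
homology). Passing tests therefore demonstrate the correctness of the
algorithms and bookkeeping, not the biological quality of designs on real
genomes; on real annotations the relative load of the filters will
differ.

Default problem sizes, chosen to exercise every code path while keeping
the full suite fast: the standard fixture has 12 genes with 400–600-nt
loci; the specificity oracle check runs 20 independent 8-gene
transcriptomes; the end-to-end design check uses a clean 50-gene fixture;
score-bound checks draw 10,000 random 19-mers. One documented default
seed (`fixture_spec()`s `seed` argument) pins all fixtures; the same spec
and seed reproduce byte-identical files.

## Numerical and convention choices

* Internal coordinates are 0-based half-open everywhere; all files read
  and written use 1-based inclusive coordinates. The round-trip is the
  identity and is tested.
* The AFF output is not a public standard; this package defines it as a
  6-column tab file (reagent_id, sequence_id, start, end, strand,
  target_gene) and documents it as a repo dialect.
* Score comparisons use ≥ at cutoffs (a score exactly at 66.7 or 63 is
  efficient); seed frequencies use strict < at the low-frequency
  threshold.
* Degenerate inputs: empty FASTA, non-ACGTN residues (reported with
  record and position), duplicate ids, missing header columns (reported
  with the expected schema), non-integer coordinates (reported with line
  number), reagents shorter than k, and weight tables with a degenerate
  normalization range are all hard errors. Per-target design failures
  are never errors: they become rows of the failed-designs report with a
  stage and reason, and the batch continues.
* Seeds derived from the acceptance script's `--seed` stay below 2³¹.

## Limitations

* Specificity is exact-match only; near-perfect (1–2 mismatch) off-target
  homology is visible only through the E-value homology scan of the
  top-ranked designs, not per-siRNA.
* The primer engine optimizes Tm and GC only; it does not model primer
  dimers, hairpins or template secondary structure.
* The weighted efficiency table is a reconstructed default, not a copy of
  any published coefficient set; scores are comparable within a run and
  against the 0–100 scale, but not numerically identical to other
  implementations (the table file exists precisely so users can swap in
  their own).
* Trans-spliced genes and alignment-based common-region inference are out
  of scope; isoforms on different reference sequences yield no common
  region.
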