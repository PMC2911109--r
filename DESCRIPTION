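Package: rnaidesign
Title: Genome-Scale Design and Evaluation of RNAi Reagents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design of RNA interference reagents (long double-stranded
    RNAs and short interfering RNAs) from transcript annotations, and
    re-annotation and pairwise comparison of existing RNAi reagent libraries.
    Computes regions common to all splice isoforms of a gene, dices target
    sequences into candidate 19-mer siRNAs, filters candidates for CAN
    trinucleotide repeats, DUST low-complexity sequence, microRNA seed matches
    and perfect-homology off-targets against an exact k-mer transcriptome
    index, scores predicted silencing efficiency by two published rule sets
    normalized to a 0-100 scale, designs PCR primer pairs for dsRNA amplicons
    within a configurable length window with an iterative redesign routine for
    fragmented target sites, and ranks designs by specificity, efficiency and
    seed complement frequency. Includes a deterministic synthetic-transcriptome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
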