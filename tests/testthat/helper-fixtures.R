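# Shared toy fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# default planted fixture (12 genes, all feature kinds)
default_fixture <- function() {
  cached("fix_default", function() generate_transcriptome(fixture_spec()))
}

# small single-isoform fixture plus designs for round-trip tests
design_bundle <- function() {
  cached("bundle", function() {
    fix <- generate_transcriptome(fixture_spec(
      n_genes = 6L, n_multi_isoform = 0L, n_paralog_pairs = 1L,
      n_can_genes = 1L, n_dust_genes = 1L, n_seed_genes = 1L,
      seed = 101L))
    regions <- transcript_regions(fix$transcripts, fix$transcript_gene)
    index <- build_index(fix$transcripts, fix$transcript_gene, 19L)
    opts <- design_options()
    res <- rnaidesign:::design_all(regions, index, opts)
    list(fix = fix, regions = regions, index = index, opts = opts,
         designs = res$designs, failed = res$failed)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one-row region for direct design calls
toy_region <- function(sequence, gene_id = "gX", region_id = "gX_r1") {
  data.frame(gene_id = gene_id, region_id = region_id,
             sequence_id = NA_character_, start0 = NA_integer_,
             end0 = NA_integer_, strand = NA_character_,
             sequence = sequence, length = nchar(sequence),
             stringsAsFactors = FALSE)
}

# brute-force specificity oracle: substring scan over all transcripts in
# both orientations, independent of the k-mer index
brute_specificity <- function(sense, transcripts, tx2gene) {
  subject <- Biostrings::DNAStringSet(transcripts$residues)
  hits <- Biostrings::vcountPattern(sense, subject) +
    Biostrings::vcountPattern(revcomp(sense), subject)
  genes <- unique(tx2gene[transcripts$id[hits > 0]])
  if (length(genes) == 0L) "no_target" else if (length(genes) == 1L) "1" else "0"
}
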