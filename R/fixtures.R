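# Deterministic synthetic-transcriptome generator with planted ground
# truth: paralog-shared 19-mers, CAN repeat runs, low-complexity runs,
# isoform structure, UTRs, SNPs and miRNA seeds, all recorded in a
# manifest so every detector can be validated without external data.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# background sequence free of CAN runs >= min_units and of 19-mers already
# seen in other genes (rejection sampling keeps the manifest exhaustive)
clean_background <- function(n, can_min_units, seen_kmers, k = 19L,
                             max_tries = 100L) {
  pat <- sprintf("(CA[ACGT]){%d,}", can_min_units)
  for (try in seq_len(max_tries)) {
    s <- rand_dna(n)
    if (grepl(pat, s)) next
    if (n >= k && length(seen_kmers) && any(kmer_windows(s, k) %in% seen_kmers)) next
    return(s)
  }
  stop("could not generate clean background sequence")
}

plant <- function(seq, at0, insert) {
  stopifnot(at0 >= 0L, at0 + nchar(insert) <= nchar(seq))
  paste0(substr(seq, 1L, at0), insert, substr(seq, at0 + nchar(insert) + 1L,
                                              nchar(seq)))
}

#' Fixture specification
#'
#' Parameters of the synthetic transcriptome generator. Defaults give a
#' compact but fully featured toy genome: 12 genes of 400-600 nt loci, two
#' of them with two splice isoforms, one paralog pair sharing a planted
#' 19-mer, one gene with a planted CAN run, one with a planted 64-nt
#' low-complexity run, 20\% UTR at each transcript start, one SNP per
#' transcript, and one planted miRNA seed.
#'
#' @param n_genes number of genes.
#' @param n_multi_isoform genes given two splice isoforms (no plants).
#' @param locus_len_range locus length range, nt.
#' @param n_paralog_pairs gene pairs sharing one planted 19-mer.
#' @param n_can_genes genes with a planted CAN run.
#' @param can_units units in each planted CAN run.
#' @param n_dust_genes genes with a planted 64-nt homopolymer run.
#' @param utr_fraction fraction of each transcript annotated as 5' UTR.
#' @param snps_per_transcript SNPs planted per transcript.
#' @param n_seed_genes genes contributing one planted miRNA seed.
#' @param seed RNG seed (same spec + seed gives byte-identical output).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 12L, n_multi_isoform = 2L,
                         locus_len_range = c(400L, 600L),
                         n_paralog_pairs = 1L, n_can_genes = 1L,
                         can_units = 6L, n_dust_genes = 1L,
                         utr_fraction = 0.2, snps_per_transcript = 1L,
                         n_seed_genes = 1L, seed = 20260923L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_multi_isoform = as.integer(n_multi_isoform),
               locus_len_range = as.integer(locus_len_range),
               n_paralog_pairs = as.integer(n_paralog_pairs),
               n_can_genes = as.integer(n_can_genes),
               can_units = as.integer(can_units),
               n_dust_genes = as.integer(n_dust_genes),
               utr_fraction = utr_fraction,
               snps_per_transcript = as.integer(snps_per_transcript),
               n_seed_genes = as.integer(n_seed_genes),
               seed = as.integer(seed))
  needed <- spec$n_multi_isoform + 2L * spec$n_paralog_pairs +
    spec$n_can_genes + spec$n_dust_genes + spec$n_seed_genes
  if (needed > spec$n_genes) {
    stop("fixture spec plants more features than genes available (",
         needed, " > ", spec$n_genes, ")")
  }
  if (3L * spec$can_units + 10L > spec$locus_len_range[1] ||
      74L > spec$locus_len_range[1]) {
    stop("planted runs longer than the shortest locus")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Emits every input the pipeline consumes — genome sequences, exon table,
#' transcript-to-gene table, UTR table (transcript coordinates), SNP table,
#' miRNA seed list — plus a manifest listing every planted feature with its
#' coordinates and the expected detector outcome. Background sequence is
#' i.i.d. uniform over ACGT with rejection of accidental CAN runs and of
#' accidental 19-mer collisions across genes, so the manifest is exhaustive:
#' any detector call outside the manifest is a false positive.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture`: `genome` (data.frame id/residues),
#'   `exons`, `transcript_gene`, `utr`, `snp`, `seeds` (character),
#'   `transcripts` (spliced transcript sequences), `manifest`, `spec`.
#' @export
generate_transcriptome <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  # role assignment: multi-isoform first, then plants, remainder clean
  idx <- seq_len(spec$n_genes)
  multi <- utils::head(idx, spec$n_multi_isoform)
  rest <- setdiff(idx, multi)
  take <- function(n) { out <- utils::head(rest, n); rest <<- setdiff(rest, out); out }
  paralogs <- take(2L * spec$n_paralog_pairs)
  can_genes <- take(spec$n_can_genes)
  dust_genes <- take(spec$n_dust_genes)
  seed_genes <- take(spec$n_seed_genes)

  seen <- character(0)
  genome <- character(spec$n_genes)
  lens <- integer(spec$n_genes)
  manifest <- list()
  add_manifest <- function(feature, gene_id, sequence_id, start0, end0,
                           expectation, detail = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      feature = feature, gene_id = gene_id, sequence_id = sequence_id,
      start0 = start0, end0 = end0, expectation = expectation,
      detail = detail, stringsAsFactors = FALSE)
  }

  for (i in idx) {
    L <- sample(spec$locus_len_range[1]:spec$locus_len_range[2], 1L)
    lens[i] <- L
    genome[i] <- clean_background(L, spec$can_min_units %||% 6L, seen)
    seen <- c(seen, kmer_windows(genome[i], 19L))
  }
  locus_ids <- paste0("locus_", gene_ids)

  # planted CAN runs (mid-locus)
  for (i in can_genes) {
    unit <- paste0("CA", sample(c("A", "C", "G", "T"), 1L))
    run <- strrep(unit, spec$can_units)
    at0 <- lens[i] %/% 3L
    # TTT guards: background flanks can never extend the run in-frame
    genome[i] <- plant(genome[i], at0, paste0("TTT", run, "TTT"))
    lens[i] <- nchar(genome[i])
    add_manifest("CAN", gene_ids[i], locus_ids[i], at0 + 3L,
                 at0 + 3L + nchar(run), "masked", unit)
  }
  # planted low-complexity (homopolymer) runs
  for (i in dust_genes) {
    base <- sample(c("A", "T"), 1L)
    run <- strrep(base, 64L)
    at0 <- lens[i] %/% 2L
    genome[i] <- plant(genome[i], at0, run)
    lens[i] <- nchar(genome[i])
    add_manifest("DUST", gene_ids[i], locus_ids[i], at0, at0 + 64L,
                 "masked", base)
  }
  # paralog pairs sharing one 19-mer
  if (length(paralogs)) {
    pairs <- matrix(paralogs, ncol = 2L, byrow = TRUE)
    for (p in seq_len(nrow(pairs))) {
      repeat {
        shared <- rand_dna(19L)
        if (!grepl("(CA[ACGT]){6,}", shared) && !(shared %in% seen)) break
      }
      for (i in pairs[p, ]) {
        at0 <- (3L * lens[i]) %/% 4L
        genome[i] <- plant(genome[i], at0, shared)
        add_manifest("shared_19mer", gene_ids[i], locus_ids[i], at0,
                     at0 + 19L, "specificity_0", shared)
      }
      seen <- c(seen, shared)
    }
  }
  # planted miRNA seeds: list the guide seed of one real window per gene
  seeds <- character(0)
  for (i in seed_genes) {
    at0 <- lens[i] %/% 4L
    sense <- substr(genome[i], at0 + 1L, at0 + 19L)
    sd <- guide_seed(revcomp(sense), "7mer")
    seeds <- c(seeds, sd)
    add_manifest("mirna_seed", gene_ids[i], locus_ids[i], at0, at0 + 19L,
                 "seed_match", sd)
  }

  # gene models: multi-isoform genes get exons A|B|C with isoform 2 = A+C
  exon_rows <- list()
  tg_rows <- list()
  tx_seqs <- character(0)
  for (i in idx) {
    gid <- gene_ids[i]; loc <- locus_ids[i]; L <- nchar(genome[i])
    if (i %in% multi) {
      a <- L %/% 3L; b <- (2L * L) %/% 3L
      t1 <- paste0(gid, ".t1"); t2 <- paste0(gid, ".t2")
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = c(t1, t1, t1, t2, t2),
        sequence_id = loc,
        start = c(1L, a + 1L, b + 1L, 1L, b + 1L),
        end = c(a, b, L, a, L), strand = "+", stringsAsFactors = FALSE)
      tg_rows[[length(tg_rows) + 1L]] <- data.frame(
        transcript_id = c(t1, t2), gene_id = gid, stringsAsFactors = FALSE)
      tx_seqs[t1] <- genome[i]
      tx_seqs[t2] <- paste0(substr(genome[i], 1L, a),
                            substr(genome[i], b + 1L, L))
      add_manifest("common_region", gid, loc, 0L, a, "common", "exon A")
      add_manifest("common_region", gid, loc, b, L, "common", "exon C")
    } else {
      t1 <- paste0(gid, ".t1")
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = t1, sequence_id = loc, start = 1L, end = L,
        strand = "+", stringsAsFactors = FALSE)
      tg_rows[[length(tg_rows) + 1L]] <- data.frame(
        transcript_id = t1, gene_id = gid, stringsAsFactors = FALSE)
      tx_seqs[t1] <- genome[i]
    }
  }
  exons <- do.call(rbind, exon_rows)
  conv <- coords_to_internal(exons$start, exons$end)
  exons$start0 <- conv$start; exons$end0 <- conv$end
  attr(exons, "kind") <- "exon"
  transcript_gene <- do.call(rbind, tg_rows)
  attr(transcript_gene, "kind") <- "transcript_gene"

  # UTR (transcript coordinates, 5' end) and SNP tables
  tx_ids <- names(tx_seqs)
  utr_len <- pmax(1L, as.integer(floor(spec$utr_fraction * nchar(tx_seqs))))
  utr <- data.frame(sequence_id = tx_ids, start = 1L, end = utr_len,
                    stringsAsFactors = FALSE)
  conv <- coords_to_internal(utr$start, utr$end)
  utr$start0 <- conv$start; utr$end0 <- conv$end
  attr(utr, "kind") <- "utr"
  snp_rows <- list()
  for (tx in tx_ids) {
    pos <- sort(sample(nchar(tx_seqs[[tx]]), spec$snps_per_transcript))
    ref <- substr(tx_seqs[[tx]], pos, pos)
    alt <- chartr("ACGT", "GTAC", ref)
    snp_rows[[tx]] <- data.frame(sequence_id = tx, position = pos,
                                 alleles = paste0(ref, "/", alt),
                                 stringsAsFactors = FALSE)
  }
  snp <- do.call(rbind, snp_rows)
  rownames(snp) <- NULL
  snp$position0 <- snp$position - 1L
  attr(snp, "kind") <- "snp"

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(feature = character(0), gene_id = character(0),
               sequence_id = character(0), start0 = integer(0),
               end0 = integer(0), expectation = character(0),
               detail = character(0), stringsAsFactors = FALSE)

  structure(list(
    genome = data.frame(id = locus_ids, description = "",
                        residues = genome, length = nchar(genome),
                        stringsAsFactors = FALSE),
    exons = exons, transcript_gene = transcript_gene, utr = utr, snp = snp,
    seeds = seeds,
    transcripts = data.frame(id = tx_ids, description = "",
                             residues = unname(tx_seqs),
                             length = nchar(unname(tx_seqs)),
                             stringsAsFactors = FALSE),
    manifest = manifest, spec = spec), class = "fixture")
}

#' Write fixture input files to a directory
#'
#' Emits the fixture in the exact on-disk formats the readers consume
#' (FASTA; tab tables with 1-based inclusive coordinates; one-column seed
#' list).
#'
#' @param fix a `fixture` from [generate_transcriptome()].
#' @param dir output directory.
#' @return named character vector of file paths.
#' @export
write_fixture_files <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             exons = file.path(dir, "exons.tab"),
             transcript_gene = file.path(dir, "transcript_gene.tab"),
             utr = file.path(dir, "utr.tab"),
             snp = file.path(dir, "snp.tab"),
             seeds = file.path(dir, "seeds.txt"),
             manifest = file.path(dir, "manifest.tab"))
  write_fasta(fix$genome, files[["genome"]])
  write_fasta(fix$transcripts, files[["transcripts"]])
  wt <- function(x, path, cols) {
    utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(fix$exons, files[["exons"]],
     c("transcript_id", "sequence_id", "start", "end", "strand"))
  wt(fix$transcript_gene, files[["transcript_gene"]],
     c("transcript_id", "gene_id"))
  wt(fix$utr, files[["utr"]], c("sequence_id", "start", "end"))
  wt(fix$snp, files[["snp"]], c("sequence_id", "position", "alleles"))
  writeLines(fix$seeds, files[["seeds"]])
  utils::write.table(fix$manifest, files[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files
}

#' Derive a perturbed reagent library from designs
#'
#' Turns design rows into a reagent FASTA, optionally perturbed, with a
#' manifest of expected evaluation outcomes:
#' \describe{
#'   \item{none}{reagents identical to the designs; evaluation must
#'     round-trip the design-time metrics exactly}
#'   \item{shift}{reagent taken `shift` nt downstream within the same
#'     region; a shift of at least the amplicon length yields zero sequence
#'     overlap with the original (an independent-design pair)}
#'   \item{mutate}{one point mutation at the amplicon centre; exactly k
#'     on-target 19-mers are destroyed or retargeted}
#' }
#'
#' @param designs design table from [design_for_target()] (needs
#'   `design_id`, `region_id`, `region_offset0`, `amplicon_length`).
#' @param regions region table the designs came from.
#' @param perturbation `"none"`, `"shift"` or `"mutate"`.
#' @param shift shift in nt for `"shift"`.
#' @return list: `library` (data.frame id/residues), `manifest`.
#' @export
generate_library <- function(designs, regions,
                             perturbation = c("none", "shift", "mutate"),
                             shift = 0L) {
  perturbation <- match.arg(perturbation)
  seq_of <- stats::setNames(regions$sequence, regions$region_id)
  out <- character(nrow(designs))
  expect <- character(nrow(designs))
  for (i in seq_len(nrow(designs))) {
    rseq <- seq_of[[designs$region_id[i]]]
    s0 <- designs$region_offset0[i]
    len <- designs$amplicon_length[i]
    if (perturbation == "none") {
      out[i] <- subseq0(rseq, s0, s0 + len)
      expect[i] <- "roundtrip_exact"
    } else if (perturbation == "shift") {
      if (s0 + shift + len > nchar(rseq)) {
        stop("shift beyond region bounds for design ", designs$design_id[i])
      }
      out[i] <- subseq0(rseq, s0 + shift, s0 + shift + len)
      expect[i] <- if (shift >= len) "no_overlap" else "partial_overlap"
    } else {
      amp <- subseq0(rseq, s0, s0 + len)
      centre <- nchar(amp) %/% 2L
      orig <- substr(amp, centre, centre)
      mut <- chartr("ACGT", "GTAC", orig)
      substr(amp, centre, centre) <- mut
      out[i] <- amp
      expect[i] <- "mutated_centre"
    }
  }
  ids <- paste0(designs$design_id, "_", perturbation)
  list(library = data.frame(id = ids, description = "", residues = out,
                            length = nchar(out), stringsAsFactors = FALSE),
       manifest = data.frame(reagent_id = ids,
                             design_id = designs$design_id,
                             perturbation = perturbation,
                             expectation = expect, stringsAsFactors = FALSE))
}
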