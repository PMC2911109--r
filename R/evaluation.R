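# Library evaluation: re-annotation of existing RNAi reagents against a
# current transcriptome, homology scanning, feature overlap, and pairwise
# library comparison.

#' Re-annotate one RNAi reagent
#'
#' Dices the reagent into k-mer siRNAs, classifies every siRNA against the
#' off-target index, and derives the evaluation record: the intended
#' transcripts are those with the most siRNA hits (ties keep all tied
#' transcripts), the intended gene(s) are defined over the intended
#' transcripts, and an siRNA is off-target when it perfectly matches a gene
#' outside the intended set. All reagent-quality metrics (CAN repeats,
#' low-complexity regions, miRNA seeds, mean efficiency / efficient count,
#' seed frequencies) are recomputed from the reagent sequence.
#'
#' @param reagent list/row with `reagent_id` and `sequence` (optionally
#'   `library_id`).
#' @param index `offtarget_index` over the transcriptome.
#' @param opts [design_options()].
#' @param seeds optional miRNA seed vector.
#' @param utr_db optional UTR FASTA data.frame for seed frequencies.
#' @param features optional list with `utr` and/or `snp` feature tables in
#'   transcript coordinates (enables overlap metrics on the mapped
#'   footprint of the intended transcript).
#' @param homology_db optional data.frame of transcript sequences for the
#'   E-value homology scan (see [homology_scan()]).
#' @return list of class `evaluation_record`.
#' @export
evaluate_reagent <- function(reagent, index, opts = design_options(),
                             seeds = NULL, utr_db = NULL, features = NULL,
                             homology_db = NULL) {
  seq <- toupper(reagent$sequence)
  if (nchar(seq) < opts$k) {
    stop("reagent '", reagent$reagent_id, "' shorter than siRNA length k = ",
         opts$k)
  }
  region <- list(region_id = reagent$reagent_id, sequence = seq,
                 gene_id = NA_character_, start0 = NA_integer_,
                 end0 = NA_integer_, sequence_id = NA_character_,
                 strand = NA_character_)
  masks <- find_can_repeats(seq, opts$can_min_units)
  dust <- if (opts$dust) dust_mask(seq, opts$dust_window, opts$dust_word,
                                   opts$dust_cutoff) else NULL
  masks_all <- rbind(masks, dust)
  cands <- dice(region, opts$k, opts$offset)
  cands <- score_efficiency(cands, opts$efficiency_method)
  if (!is.null(seeds)) cands <- flag_mirna_seeds(cands, seeds, opts$seed_mode)
  if (!is.null(utr_db)) {
    cands <- seed_frequency(cands, utr_db, opts$seed_mode,
                            opts$seed_frequency_threshold)
  }

  # per-siRNA transcript hits (both orientations, as a dsRNA is diced into
  # guides from both strands)
  queries <- unique(c(cands$sense, revcomp(cands$sense)))
  hits <- query_index(index, queries[!grepl("N", queries, fixed = TRUE)])
  tx_of <- split(hits$transcript_id, hits$kmer)
  rc <- revcomp(cands$sense)
  per_sirna_tx <- lapply(seq_len(nrow(cands)), function(i) {
    unique(c(tx_of[[cands$sense[i]]], tx_of[[rc[i]]]))
  })

  # intended transcripts: argmax of per-transcript siRNA hit counts
  tx_counts <- table(unlist(per_sirna_tx))
  if (length(tx_counts)) {
    intended_tx <- names(tx_counts)[tx_counts == max(tx_counts)]
    intended_genes <- sort(unique(unname(index$tx2gene[intended_tx])))
  } else {
    intended_tx <- character(0)
    intended_genes <- character(0)
  }
  per_sirna_genes <- lapply(per_sirna_tx, function(tx)
    unique(unname(index$tx2gene[tx])))
  n_hits <- vapply(per_sirna_genes, length, integer(1))
  is_off <- vapply(per_sirna_genes, function(g)
    length(setdiff(g, intended_genes)) > 0L, logical(1))
  sirna_none <- sum(n_hits == 0L)
  sirna_off <- sum(is_off & n_hits > 0L)
  sirna_on <- nrow(cands) - sirna_none - sirna_off
  unintended_tx <- setdiff(unique(unlist(per_sirna_tx)), intended_tx)
  unintended_genes <- setdiff(unique(unlist(per_sirna_genes)), intended_genes)

  eff <- summarize_efficiency(cands$efficiency, opts$efficiency_cutoff)

  # footprint of perfect 19-mer hits on each intended transcript
  footprints <- list()
  if (length(intended_tx)) {
    fp_hits <- hits[hits$transcript_id %in% intended_tx]
    if (nrow(fp_hits)) {
      footprints <- lapply(split(fp_hits, fp_hits$transcript_id), function(h) {
        ir <- IRanges::reduce(IRanges::IRanges(start = h$pos0 + 1L,
                                               width = opts$k))
        data.frame(start0 = IRanges::start(ir) - 1L, end0 = IRanges::end(ir))
      })
    }
  }

  rec <- list(
    reagent_id = reagent$reagent_id,
    library_id = reagent$library_id %||% NA_character_,
    length = nchar(seq),
    intended_transcripts = intended_tx,
    intended_genes = intended_genes,
    multi_intended = length(intended_genes) > 1L,
    unintended_transcripts = unintended_tx,
    unintended_genes = unintended_genes,
    sirna_total = nrow(cands),
    sirna_on_target = sirna_on,
    sirna_off_target = sirna_off,
    sirna_no_target = sirna_none,
    can_repeats = sum(masks$cause == "CAN"),
    low_complexity_regions = if (is.null(dust)) NA_integer_ else nrow(dust),
    mirna_seeds = if (!is.null(seeds)) sum(cands$has_mirna_seed) else NA_integer_,
    mean_efficiency = eff$mean_efficiency,
    efficient_sirnas = eff$efficient_count,
    seed_low_frequency = if (!is.null(utr_db))
      sum(cands$seed_low_frequency, na.rm = TRUE) else NA_integer_,
    footprints = footprints
  )

  if (!is.null(features)) {
    ov <- overlap_features(footprints, features$utr, features$snp)
    rec <- c(rec, ov)
  }
  if (!is.null(homology_db)) {
    hs <- homology_scan(reagent, homology_db, opts$evalue_max,
                        exclude = intended_tx)
    rec$homology_hits <- if (is.null(hs)) NA_integer_ else nrow(hs)
  }
  structure(rec, class = "evaluation_record")
}

#' @export
print.evaluation_record <- function(x, ...) {
  cat(sprintf("reagent %s (%d nt): intended gene(s) %s\n", x$reagent_id,
              x$length,
              if (length(x$intended_genes)) paste(x$intended_genes, collapse = ",")
              else "NA"))
  cat(sprintf("  siRNAs: %d total, %d on-target, %d off-target, %d no-target\n",
              x$sirna_total, x$sirna_on_target, x$sirna_off_target,
              x$sirna_no_target))
  cat(sprintf("  mean efficiency %.2f, %d efficient; CAN %d, low-complexity %s\n",
              x$mean_efficiency, x$efficient_sirnas, x$can_repeats,
              as.character(x$low_complexity_regions)))
  invisible(x)
}

#' Homology scan of a reagent against a transcript database
#'
#' Delegates local alignment to the BLAST+ suite (`makeblastdb`/`blastn`)
#' when available, reporting hits with E-value below `evalue_max` to
#' transcripts outside the intended set. When BLAST is not on the PATH the
#' scan returns `NULL` ("homology not assessed") rather than failing.
#'
#' @param reagent list/row with `reagent_id` and `sequence`.
#' @param db data.frame of transcript sequences from [read_fasta()].
#' @param evalue_max E-value threshold (default 1e-10).
#' @param exclude transcript ids to exclude (the intended transcripts).
#' @return data.frame of hits (`transcript_id`, `evalue`, `bitscore`,
#'   `pident`, `length`) or `NULL` when not assessed.
#' @export
homology_scan <- function(reagent, db, evalue_max = 1e-10,
                          exclude = character(0)) {
  if (!nrow(db)) stop("empty homology database")
  if (evalue_max <= 0) {
    return(data.frame(transcript_id = character(0), evalue = numeric(0),
                      bitscore = numeric(0), pident = numeric(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (blastn == "" || makedb == "") return(NULL)
  tmp <- tempfile("homology")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  db_fa <- file.path(tmp, "db.fa")
  q_fa <- file.path(tmp, "q.fa")
  write_fasta(db, db_fa)
  write_fasta(data.frame(id = reagent$reagent_id, residues = toupper(reagent$sequence),
                         stringsAsFactors = FALSE), q_fa)
  system2(makedb, c("-in", db_fa, "-dbtype", "nucl", "-out",
                    file.path(tmp, "db")), stdout = FALSE, stderr = FALSE)
  out <- system2(blastn, c("-query", q_fa, "-db", file.path(tmp, "db"),
                           "-evalue", format(evalue_max, scientific = TRUE),
                           "-outfmt", shQuote("6 sseqid evalue bitscore pident length"),
                           "-task", "blastn"),
                 stdout = TRUE, stderr = FALSE)
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), evalue = numeric(0),
                      bitscore = numeric(0), pident = numeric(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(out, "\t", fixed = TRUE))
  hits <- data.frame(transcript_id = parts[, 1],
                     evalue = as.numeric(parts[, 2]),
                     bitscore = as.numeric(parts[, 3]),
                     pident = as.numeric(parts[, 4]),
                     length = as.integer(parts[, 5]),
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue < evalue_max & !(hits$transcript_id %in% exclude), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$transcript_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Overlap of a mapped reagent with UTR and SNP annotations
#'
#' Computes, over the reagent's mapped transcript footprints, the number of
#' UTR bases overlapped (`utr_overlap_bases`), whether the reagent touches
#' an annotated UTR by at least one base (`utr_overlap_flag`), and the
#' number of SNP positions inside the footprints (`snp_overlap`). When a
#' feature table is not supplied the corresponding fields are `NA` (absent,
#' not zero); an unmapped reagent yields zeros with a note.
#'
#' @param footprints named list (by transcript id) of data.frames with
#'   `start0`, `end0` — the mapped intervals from [evaluate_reagent()].
#' @param utr optional UTR feature table (kind `"utr"`).
#' @param snp optional SNP feature table (kind `"snp"`).
#' @return list with `utr_overlap_bases`, `utr_overlap_flag`,
#'   `snp_overlap`, and `mapped` (logical).
#' @export
overlap_features <- function(footprints, utr = NULL, snp = NULL) {
  mapped <- length(footprints) > 0L
  out <- list(utr_overlap_bases = NA_integer_, utr_overlap_flag = NA,
              snp_overlap = NA_integer_, mapped = mapped)
  if (!mapped) {
    if (!is.null(utr)) { out$utr_overlap_bases <- 0L; out$utr_overlap_flag <- FALSE }
    if (!is.null(snp)) out$snp_overlap <- 0L
    out$note <- "unmapped"
    return(out)
  }
  if (!is.null(utr)) {
    bases <- 0L
    for (tx in names(footprints)) {
      u <- utr[utr$sequence_id == tx, , drop = FALSE]
      if (!nrow(u)) next
      fp <- footprints[[tx]]
      fp_ir <- IRanges::IRanges(start = fp$start0 + 1L, end = fp$end0)
      u_ir <- IRanges::reduce(IRanges::IRanges(start = u$start0 + 1L, end = u$end0))
      bases <- bases + sum(IRanges::width(IRanges::intersect(fp_ir, u_ir)))
    }
    out$utr_overlap_bases <- bases
    out$utr_overlap_flag <- bases >= 1L
  }
  if (!is.null(snp)) {
    count <- 0L
    for (tx in names(footprints)) {
      s <- snp[snp$sequence_id == tx, , drop = FALSE]
      if (!nrow(s)) next
      fp <- footprints[[tx]]
      count <- count + sum(vapply(s$position0, function(p)
        any(fp$start0 <= p & p < fp$end0), logical(1)))
    }
    out$snp_overlap <- count
  }
  out
}

#' Evaluate a reagent library
#'
#' @param library_fasta data.frame from [read_fasta()] (reagent id and
#'   sequence per record).
#' @param library_id label attached to every record.
#' @inheritParams evaluate_reagent
#' @return list of `evaluation_record` objects, named by reagent id.
#' @export
evaluate_library <- function(library_fasta, index, opts = design_options(),
                             library_id = "lib", seeds = NULL, utr_db = NULL,
                             features = NULL, homology_db = NULL) {
  recs <- lapply(seq_len(nrow(library_fasta)), function(i) {
    evaluate_reagent(list(reagent_id = library_fasta$id[i],
                          sequence = library_fasta$residues[i],
                          library_id = library_id),
                     index, opts, seeds, utr_db, features, homology_db)
  })
  stats::setNames(recs, library_fasta$id)
}

# do two footprint lists share any mapped base on any transcript?
footprints_overlap <- function(fa, fb) {
  common_tx <- intersect(names(fa), names(fb))
  for (tx in common_tx) {
    a <- fa[[tx]]; b <- fb[[tx]]
    for (i in seq_len(nrow(a))) {
      if (any(b$start0 < a$end0[i] & b$end0 > a$start0[i])) return(TRUE)
    }
  }
  FALSE
}

#' Pairwise library comparison
#'
#' Counts the genes targeted by both libraries (intersection of the
#' intended-gene sets) and, among those, the genes covered by independent
#' designs: a gene counts as independently covered when some reagent pair
#' (one reagent per library, both intending that gene) shares no mapped
#' sequence overlap at all — evaluated on the transcript-coordinate
#' footprints of the perfect 19-mer hits, not on raw strings.
#'
#' @param evalsA,evalsB lists of `evaluation_record`s computed against the
#'   same transcriptome.
#' @param libA,libB labels for the output.
#' @return list of class `library_comparison`: `libA`, `libB`,
#'   `genes_common`, `genes_independent`, plus the per-gene id vectors
#'   `common_genes`, `independent_genes`.
#' @export
compare_libraries <- function(evalsA, evalsB, libA = "A", libB = "B") {
  genes_of <- function(evals) {
    g <- lapply(evals, function(r) r$intended_genes)
    stats::setNames(g, vapply(evals, function(r) r$reagent_id, character(1)))
  }
  ga <- genes_of(evalsA); gb <- genes_of(evalsB)
  common <- intersect(unique(unlist(ga)), unique(unlist(gb)))
  independent <- character(0)
  for (gene in common) {
    ra <- evalsA[vapply(ga, function(g) gene %in% g, logical(1))]
    rb <- evalsB[vapply(gb, function(g) gene %in% g, logical(1))]
    found <- FALSE
    for (a in ra) {
      for (b in rb) {
        if (!footprints_overlap(a$footprints, b$footprints)) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) independent <- c(independent, gene)
  }
  structure(list(libA = libA, libB = libB,
                 genes_common = length(common),
                 genes_independent = length(independent),
                 common_genes = sort(common),
                 independent_genes = sort(independent)),
            class = "library_comparison")
}

#' @export
print.library_comparison <- function(x, ...) {
  cat(sprintf("library comparison %s vs %s: %d genes targeted by both, %d by independent designs\n",
              x$libA, x$libB, x$genes_common, x$genes_independent))
  invisible(x)
}
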