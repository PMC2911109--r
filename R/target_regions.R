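# Common-region computation: the design query unit is the set of maximal
# genomic intervals contained in the exonic footprint of every splice
# isoform of a gene, optionally split when longer than 700 nt.

#' Build gene models from an exon table
#'
#' Groups an exon feature table (see [read_feature_table()], kind `"exon"`,
#' joined with a transcript-to-gene table) into per-gene models.
#'
#' @param exons exon table with internal coordinates (`start0`, `end0`).
#' @param transcript_gene transcript-to-gene table.
#' @return named list of gene models; each has `gene_id` and `transcripts`,
#'   a named list of exon data.frames sorted by start.
#' @export
gene_models <- function(exons, transcript_gene) {
  g_of <- stats::setNames(transcript_gene$gene_id, transcript_gene$transcript_id)
  unknown <- setdiff(unique(exons$transcript_id), names(g_of))
  if (length(unknown)) {
    stop("exon table references transcripts absent from transcript_gene: ",
         paste(unknown, collapse = ", "))
  }
  exons$gene_id <- unname(g_of[exons$transcript_id])
  models <- list()
  for (gid in unique(exons$gene_id)) {
    ge <- exons[exons$gene_id == gid, , drop = FALSE]
    txs <- split(ge, ge$transcript_id)
    txs <- lapply(txs, function(tx) {
      tx <- tx[order(tx$start0), , drop = FALSE]
      if (length(unique(tx$sequence_id)) != 1L) {
        stop("transcript ", tx$transcript_id[1], " has exons on multiple sequences")
      }
      if (length(unique(tx$strand)) != 1L) {
        stop("transcript ", tx$transcript_id[1], " has exons on multiple strands")
      }
      if (nrow(tx) > 1L && any(tx$start0[-1] < tx$end0[-nrow(tx)])) {
        stop("transcript ", tx$transcript_id[1], " has overlapping exons")
      }
      tx
    })
    models[[gid]] <- list(gene_id = gid, transcripts = txs)
  }
  models
}

#' Regions common to all splice isoforms of a gene
#'
#' Intersects the exonic footprints of every transcript of a gene on the
#' genome, returning the maximal intervals covered by all isoforms together
#' with their extracted sequences. Genes whose isoforms share no exonic
#' base yield zero regions.
#'
#' @param model a gene model from [gene_models()].
#' @param genome named character vector (or data.frame from [read_fasta()])
#'   of genome sequences.
#' @return data.frame with one row per common region: `gene_id`,
#'   `region_id`, `sequence_id`, `start0`, `end0`, `strand`, `sequence`,
#'   `length`.
#' @export
common_regions <- function(model, genome) {
  if (is.data.frame(genome)) {
    genome <- stats::setNames(genome$residues, genome$id)
  }
  txs <- model$transcripts
  stopifnot(length(txs) >= 1L)
  seq_ids <- unique(vapply(txs, function(tx) tx$sequence_id[1], character(1)))
  strands <- unique(vapply(txs, function(tx) tx$strand[1], character(1)))
  if (length(seq_ids) != 1L) {
    # isoforms on different sequences share nothing
    return(empty_region_table())
  }
  seq_id <- seq_ids
  strand <- if (length(strands) == 1L) strands else "."
  if (!(seq_id %in% names(genome))) stop("genome sequence not found: ", seq_id)
  glen <- nchar(genome[[seq_id]])
  common <- NULL
  for (tx in txs) {
    if (any(tx$end0 > glen) || any(tx$start0 < 0L)) {
      stop("exon of transcript ", tx$transcript_id[1],
           " outside genome sequence ", seq_id)
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = tx$start0 + 1L, end = tx$end0))
    common <- if (is.null(common)) ir else IRanges::intersect(common, ir)
  }
  if (length(common) == 0L) return(empty_region_table())
  start0 <- IRanges::start(common) - 1L
  end0 <- IRanges::end(common)
  seqs <- substring(genome[[seq_id]], start0 + 1L, end0)
  data.frame(gene_id = model$gene_id,
             region_id = sprintf("%s_r%d", model$gene_id, seq_along(start0)),
             sequence_id = seq_id, start0 = start0, end0 = end0,
             strand = strand, sequence = seqs, length = end0 - start0,
             stringsAsFactors = FALSE)
}

empty_region_table <- function() {
  data.frame(gene_id = character(0), region_id = character(0),
             sequence_id = character(0), start0 = integer(0),
             end0 = integer(0), strand = character(0),
             sequence = character(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' Common regions from transcript sequences only
#'
#' Single-isoform mode: when no genome/exon annotation is supplied, each
#' transcript is its own common region. Genes with more than one isoform
#' require exon coordinates and are rejected.
#'
#' @param transcripts data.frame from [read_fasta()].
#' @param transcript_gene transcript-to-gene table.
#' @return region table as in [common_regions()] (no genome coordinates).
#' @export
transcript_regions <- function(transcripts, transcript_gene) {
  g_of <- stats::setNames(transcript_gene$gene_id, transcript_gene$transcript_id)
  gid <- unname(g_of[transcripts$id])
  gid[is.na(gid)] <- transcripts$id[is.na(gid)]
  multi <- names(which(table(gid) > 1L))
  if (length(multi)) {
    stop("genes with multiple isoforms need exon coordinates: ",
         paste(multi, collapse = ", "))
  }
  data.frame(gene_id = gid,
             region_id = sprintf("%s_r1", gid),
             sequence_id = NA_character_, start0 = NA_integer_,
             end0 = NA_integer_, strand = NA_character_,
             sequence = transcripts$residues, length = transcripts$length,
             stringsAsFactors = FALSE)
}

#' Split long common regions
#'
#' Regions longer than `max_len` nt are split once into two contiguous
#' halves of equal length (the left half takes the extra base for odd
#' lengths); shorter regions pass through unchanged. Splitting is not
#' recursive: halves longer than `max_len` remain valid design inputs.
#'
#' @param regions region table (one or more rows).
#' @param max_len split threshold in nt (default 700).
#' @return region table; split rows get region ids suffixed `.1`/`.2`.
#' @export
split_regions <- function(regions, max_len = 700L) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, , drop = FALSE]
    if (r$length <= max_len) {
      out[[i]] <- r
      next
    }
    left_len <- ceiling(r$length / 2)
    a <- r; b <- r
    a$region_id <- paste0(r$region_id, ".1")
    b$region_id <- paste0(r$region_id, ".2")
    a$sequence <- substr(r$sequence, 1L, left_len)
    b$sequence <- substr(r$sequence, left_len + 1L, r$length)
    a$length <- nchar(a$sequence)
    b$length <- nchar(b$sequence)
    if (!is.na(r$start0)) {
      a$end0 <- r$start0 + left_len
      b$start0 <- r$start0 + left_len
    }
    out[[i]] <- rbind(a, b)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
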