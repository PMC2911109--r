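# Exact-match k-mer index over the off-target database (typically the
# whole transcriptome) and siRNA specificity classification; seed
# complement frequencies against a 3'UTR database.

#' Build an exact-match k-mer index of an off-target database
#'
#' Indexes every k-mer start position of every database sequence (sense
#' orientation). Windows containing N are skipped; sequences shorter than k
#' contribute nothing (with a warning). Database ids absent from the
#' transcript-to-gene table are assigned their own singleton gene with a
#' warning.
#'
#' @param db data.frame of sequences from [read_fasta()].
#' @param transcript_gene transcript-to-gene table (`transcript_id`,
#'   `gene_id`).
#' @param k k-mer length (must match the siRNA length queried later).
#' @return object of class `offtarget_index`.
#' @export
build_index <- function(db, transcript_gene, k = 19L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  tx2gene <- stats::setNames(transcript_gene$gene_id, transcript_gene$transcript_id)
  unmapped <- setdiff(db$id, names(tx2gene))
  if (length(unmapped)) {
    warning("off-target database ids without gene mapping treated as singleton genes: ",
            paste(unmapped, collapse = ", "))
    tx2gene <- c(tx2gene, stats::setNames(unmapped, unmapped))
  }
  short <- db$id[db$length < k]
  if (length(short)) {
    warning("sequences shorter than k contribute no k-mers: ",
            paste(short, collapse = ", "))
  }
  parts <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    kmers <- kmer_windows(db$residues[i], k)
    if (!length(kmers)) next
    keep <- !grepl("N", kmers, fixed = TRUE)
    if (!any(keep)) next
    parts[[i]] <- data.table::data.table(kmer = kmers[keep],
                                         transcript_id = db$id[i],
                                         pos0 = which(keep) - 1L)
  }
  postings <- data.table::rbindlist(parts)
  if (nrow(postings) == 0L) {
    postings <- data.table::data.table(kmer = character(0),
                                       transcript_id = character(0),
                                       pos0 = integer(0))
  }
  data.table::setkeyv(postings, "kmer")
  structure(list(k = k, postings = postings, tx2gene = tx2gene),
            class = "offtarget_index")
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat(sprintf("off-target k-mer index: k=%d, %d postings, %d transcripts, %d genes\n",
              x$k, nrow(x$postings), length(unique(x$postings$transcript_id)),
              length(unique(x$tx2gene))))
  invisible(x)
}

#' Query the index for exact k-mer matches
#'
#' @param index an `offtarget_index`.
#' @param kmers character vector of k-mers (each of length `index$k`).
#' @return data.table of postings (`kmer`, `transcript_id`, `pos0`) for the
#'   queried k-mers (zero rows when none match).
#' @export
query_index <- function(index, kmers) {
  stopifnot(inherits(index, "offtarget_index"))
  if (!length(kmers)) return(index$postings[0])
  if (any(nchar(kmers) != index$k)) {
    stop("query k-mer length does not match index k = ", index$k)
  }
  hits <- index$postings[data.table::data.table(kmer = unique(kmers)),
                         on = "kmer", nomatch = NULL]
  hits
}

#' Classify siRNA specificity against the off-target database
#'
#' For each candidate, all perfect exact matches of the sense k-mer (and,
#' by default, of its reverse complement: a dsRNA yields guide strands from
#' both) are collected from the index and resolved to genes. An siRNA is
#' specific (`"1"`) when all hit transcripts are isoforms of a single gene,
#' unspecific (`"0"`) when multiple genes are hit, and `"no_target"` when
#' the database contains no perfect match.
#'
#' @param cands candidate table from [dice()] (or any data.frame with a
#'   `sense` column).
#' @param index an `offtarget_index`.
#' @param both_strands query both orientations (default `TRUE`).
#' @return `cands` with added columns `specificity` (`"1"`, `"0"`,
#'   `"no_target"`), `n_hit_genes`, `hit_genes` (comma-collapsed string).
#' @export
classify_specificity <- function(cands, index, both_strands = TRUE) {
  stopifnot(inherits(index, "offtarget_index"))
  sense <- cands$sense
  queries <- sense
  if (both_strands) queries <- c(queries, revcomp(sense))
  uq <- unique(queries)
  hits <- query_index(index, uq)
  # genes per queried k-mer
  genes_of <- hits[, list(genes = list(unique(index$tx2gene[transcript_id]))),
                   by = "kmer"]
  gmap <- stats::setNames(genes_of$genes, genes_of$kmer)
  rc <- revcomp(sense)
  per_cand <- lapply(seq_along(sense), function(i) {
    g <- gmap[[sense[i]]]
    if (both_strands) g <- unique(c(g, gmap[[rc[i]]]))
    g[!is.na(g)]
  })
  n_genes <- vapply(per_cand, length, integer(1))
  cands$specificity <- ifelse(n_genes == 0L, "no_target",
                              ifelse(n_genes == 1L, "1", "0"))
  cands$n_hit_genes <- n_genes
  cands$hit_genes <- vapply(per_cand, function(g) paste(sort(g), collapse = ","),
                            character(1))
  cands
}

#' Seed complement frequencies against a UTR database
#'
#' For each unique guide seed, counts the occurrences (overlapping
#' occurrences allowed) of the reverse complement of the seed across all
#' database sequences — i.e. the number of potential miRNA-like target
#' sites in, for example, a 3'UTR collection. Computed once per set of
#' unique seeds; each siRNA inherits the count of its seed.
#'
#' @param seeds character vector of guide seeds (from [guide_seed()]).
#' @param utr_db data.frame of sequences from [read_fasta()].
#' @return named integer vector: seed -> match count.
#' @export
seed_frequency_table <- function(seeds, utr_db) {
  uq <- unique(seeds)
  if (!length(uq)) return(stats::setNames(integer(0), character(0)))
  subject <- Biostrings::DNAStringSet(utr_db$residues)
  counts <- vapply(uq, function(s) {
    site <- revcomp(s)
    sum(Biostrings::vcountPattern(site, subject))
  }, integer(1))
  stats::setNames(counts, uq)
}

#' Annotate candidates with seed complement frequency
#'
#' @param cands candidate table with a `guide` column.
#' @param utr_db data.frame of sequences from [read_fasta()].
#' @param mode `"7mer"` or `"6mer"`.
#' @param threshold counts below this set the low-frequency flag (default
#'   1000).
#' @return `cands` with columns `seed_frequency` and `seed_low_frequency`.
#' @export
seed_frequency <- function(cands, utr_db, mode = c("7mer", "6mer"),
                           threshold = 1000L) {
  mode <- match.arg(mode)
  seeds <- guide_seed(cands$guide, mode)
  tab <- seed_frequency_table(seeds, utr_db)
  cands$seed_frequency <- unname(tab[seeds])
  cands$seed_low_frequency <- cands$seed_frequency < threshold
  cands
}
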