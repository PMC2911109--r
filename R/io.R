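# FASTA and tab-delimited feature-table I/O, plus the result writers
# (tab / FASTA / GFF3 / AFF / failed-designs report).
#
# Internal coordinates are 0-based half-open; every emitted file uses
# 1-based inclusive coordinates.

#' Read a DNA FASTA file
#'
#' Parses a (possibly wrapped) multi-record FASTA file into a data.frame of
#' sequence records. Residues are uppercased; only A/C/G/T/N are accepted.
#' The record id is the first whitespace-delimited token of the header; the
#' remainder is kept as the description.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `description`, `residues`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  residues <- toupper(as.character(set))
  bad <- vapply(residues, first_bad_residue, integer(1), USE.NAMES = FALSE)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("record '%s': invalid residue '%s' at position %d",
                 ids[i], substr(residues[i], bad[i], bad[i]), bad[i]))
  }
  data.frame(id = ids, description = desc, residues = residues,
             length = nchar(residues), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records data.frame with columns `id` and `residues` (and
#'   optionally `description`).
#' @param path output file path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  headers <- records$id
  if (!is.null(records$description)) {
    headers <- ifelse(nzchar(records$description),
                      paste(records$id, records$description), records$id)
  }
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Required header columns per feature-table kind (file coordinates are
# 1-based inclusive).
FEATURE_SCHEMAS <- list(
  transcript_gene = c("transcript_id", "gene_id"),
  exon  = c("transcript_id", "sequence_id", "start", "end", "strand"),
  utr   = c("sequence_id", "start", "end"),
  snp   = c("sequence_id", "position", "alleles"),
  mirna_seed = c("seed")
)

#' Read a tab-delimited feature table
#'
#' Reads one of the annotation tables the pipeline consumes:
#' \describe{
#'   \item{transcript_gene}{columns `transcript_id`, `gene_id`}
#'   \item{exon}{columns `transcript_id`, `sequence_id`, `start`, `end`,
#'     `strand` (1-based inclusive in the file)}
#'   \item{utr}{columns `sequence_id`, `start`, `end` (1-based inclusive)}
#'   \item{snp}{columns `sequence_id`, `position` (1-based), `alleles`}
#'   \item{mirna_seed}{one column `seed`}
#' }
#' Interval columns are converted to the internal 0-based half-open
#' convention (`start0`, `end0`); SNP positions to 0-based `position0`.
#'
#' @param path file path; must have a header row with the names above.
#' @param kind table kind.
#' @return data.frame; attribute `kind` records the table kind.
#' @export
read_feature_table <- function(path, kind = names(FEATURE_SCHEMAS)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  required <- FEATURE_SCHEMAS[[kind]]
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("feature table '%s' (kind %s) is missing column(s) %s; expected header: %s",
                 path, kind, paste(missing, collapse = ", "),
                 paste(required, collapse = ", ")))
  }
  int_cols <- intersect(c("start", "end", "position"), required)
  for (col in int_cols) {
    vals <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(vals) & nrow(tab) > 0) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("feature table '%s': non-integer '%s' in column '%s' at data line %d",
                   path, tab[[col]][bad], col, bad))
    }
    tab[[col]] <- vals
  }
  if (all(c("start", "end") %in% names(tab))) {
    if (nrow(tab) > 0 && any(tab$start > tab$end)) {
      stop("feature table '", path, "': interval with start > end")
    }
    conv <- coords_to_internal(tab$start, tab$end)
    tab$start0 <- conv$start
    tab$end0 <- conv$end
  }
  if ("position" %in% names(tab)) tab$position0 <- tab$position - 1L
  attr(tab, "kind") <- kind
  tab
}

# GFF3 escape for column 9 values
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

# Write a GFF3 file for reagents with genomic/transcript coordinates.
write_gff3 <- function(designs, path, source = "rnaidesign",
                       type = "RNAi_reagent") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(designs) == 0L) return(invisible(path))
  has_coords <- !is.na(designs$sequence_id) & !is.na(designs$start0)
  dropped <- designs$design_id[!has_coords]
  if (length(dropped)) {
    warning("designs without coordinates omitted from GFF3: ",
            paste(dropped, collapse = ", "))
  }
  d <- designs[has_coords, , drop = FALSE]
  if (nrow(d)) {
    fc <- coords_to_file(d$start0, d$end0)
    strand <- ifelse(is.na(d$strand) | d$strand == "", ".", d$strand)
    attrs <- sprintf("ID=%s;target_gene=%s", gff3_escape(d$design_id),
                     gff3_escape(as.character(d$target_gene)))
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       d$sequence_id, source, type, fc$start, fc$end,
                       strand, attrs), con)
  }
  invisible(path)
}

# Fixed column order of the main tab-delimited result file.
MAIN_RESULT_COLUMNS <- c(
  "design_id", "target_gene", "region_id", "rank", "sequence_id", "start",
  "end", "strand", "amplicon_length", "sirna_total", "sirna_on_target",
  "sirna_off_target", "sirna_no_target", "efficient_sirnas",
  "mean_efficiency", "can_repeats", "low_complexity_regions", "mirna_seeds",
  "seed_low_frequency", "utr_overlap_bases", "snp_overlap", "homology_hits",
  "primer_left", "primer_right", "primer_left_tm", "primer_right_tm",
  "primer_left_gc", "primer_right_gc", "primer_pair_penalty", "sequence")

#' Write design results
#'
#' Emits the five result files of a design run into `out_dir`:
#' `results.tab` (one line per design, fixed column order), `designs.fasta`,
#' `designs.gff3` (1-based inclusive coordinates), `designs.aff` and
#' `failed.tab` (target_id, stage, reason).
#'
#' The AFF table is a 6-column tab-delimited dialect of this package:
#' reagent_id, sequence_id, start, end, strand, target_gene.
#'
#' @param designs data.frame of designs (possibly 0 rows) as produced by
#'   [design_for_target()] / [run_pipeline()].
#' @param failed data.frame with columns `target_id`, `stage`, `reason`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_design_outputs <- function(designs, failed, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (is.null(designs) || nrow(designs) == 0L) {
    designs <- empty_design_table()
  }
  if (is.null(failed) || nrow(failed) == 0L) {
    failed <- data.frame(target_id = character(0), stage = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  }
  files <- c(tab = file.path(out_dir, "results.tab"),
             fasta = file.path(out_dir, "designs.fasta"),
             gff = file.path(out_dir, "designs.gff3"),
             aff = file.path(out_dir, "designs.aff"),
             failed = file.path(out_dir, "failed.tab"))

  out <- designs
  fc <- coords_to_file(out$start0, out$end0)
  out$start <- fc$start
  out$end <- fc$end
  out <- out[, MAIN_RESULT_COLUMNS, drop = FALSE]
  utils::write.table(out, files[["tab"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  if (nrow(designs)) {
    write_fasta(data.frame(id = designs$design_id,
                           description = paste0("target_gene=", designs$target_gene),
                           residues = designs$sequence,
                           stringsAsFactors = FALSE),
                files[["fasta"]])
  } else {
    cat("", file = files[["fasta"]])
  }

  write_gff3(designs, files[["gff"]])

  aff <- data.frame(reagent_id = designs$design_id,
                    sequence_id = designs$sequence_id,
                    start = fc$start, end = fc$end,
                    strand = designs$strand,
                    target_gene = designs$target_gene,
                    stringsAsFactors = FALSE)
  utils::write.table(aff, files[["aff"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  utils::write.table(failed, files[["failed"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  files
}

# Zero-row design table with the full main-result schema (internal coords).
empty_design_table <- function() {
  cols <- setdiff(MAIN_RESULT_COLUMNS, c("start", "end"))
  out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out$start0 <- integer(0)
  out$end0 <- integer(0)
  out
}
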